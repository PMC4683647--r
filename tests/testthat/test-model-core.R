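# Three-locus epistatic model: phenotyping, gamete and progeny
# distributions, expected ratios, viability selection.

test_that("phenotype rule reproduces the inferred parental phenotypes", {
  # dominant sterility, recessive restorer loss, recessive third locus
  expect_equal(phenotype_of(mlg("MSmf", "RR", "TT", cytotype = "C")), "F")
  expect_equal(phenotype_of(mlg("mfmf", "rr", "TT", cytotype = "F")), "F")
  expect_equal(phenotype_of(mlg("mfmf", "Rr", "TT", cytotype = "F")), "H")
  expect_equal(phenotype_of(mlg("mfmf", "RR", "Tt", cytotype = "B")), "H")
  expect_equal(phenotype_of(mlg("mfmf", "RR", "tt", cytotype = "C")), "F")
  # without a sterilising cytoplasm no nuclear route is expressed
  no_cms <- cytotype("X", cms_present = FALSE)
  expect_equal(phenotype_of(mlg("MSmf", "rr", "tt", cytotype = no_cms)), "H")
  expect_equal(phenotype_of(mlg("mfmf", "RR", "TT", cytotype = no_cms)), "H")
})

test_that("unknown allele symbols raise an error naming the locus", {
  expect_error(mlg("MSmf", "Qr", "TT"), "LG6")
  expect_error(mlg("XX", "Rr", "TT"), "LG4")
})

test_that("gamete distributions follow independent assortment exactly", {
  g <- gamete_distribution(mlg("mfmf", "Rr", "TT"))
  expect_equal(nrow(g), 2)
  expect_true(all(g$num == 1 & g$den == 2))
  expect_setequal(g$LG6, c("R", "r"))

  g2 <- gamete_distribution(mlg("mfmf", "Rr", "Tt"))
  expect_equal(nrow(g2), 4)
  expect_true(all(g2$num == 1 & g2$den == 4))

  g3 <- gamete_distribution(mlg("mfmf", "rr", "TT"))
  expect_equal(nrow(g3), 1)
  expect_equal(g3$num / g3$den, 1)

  g4 <- gamete_distribution(mlg("MSmf", "Rr", "Tt"))
  expect_equal(nrow(g4), 8)
  expect_equal(sum(g4$num / g4$den), 1)
})

test_that("progeny distributions reproduce the expected ratios exactly", {
  rr_self <- function(lg6, lgx) {
    g <- mlg("mfmf", lg6, lgx, cytotype = "F")
    expected_ratio(g, g)
  }
  # restorer heterozygote selfed: 1 female : 3 hermaphrodites
  er <- rr_self("Rr", "TT")
  expect_identical(er$label, "1:3")
  expect_true(rat_num(er$female) == 1 && rat_den(er$female) == 4)
  # double heterozygote selfed: 7:9 females (the classic two-locus
  # complementary ratio, printed 9:7 hermaphrodite:female)
  er2 <- rr_self("Rr", "Tt")
  expect_identical(er2$label, "7:9")
  expect_true(rat_num(er2$female) == 7 && rat_den(er2$female) == 16)
  # female x homozygous restorer: no females
  er3 <- expected_ratio(mlg("mfmf", "rr", "TT", cytotype = "F"),
                        mlg("mfmf", "RR", "TT", cytotype = "C"))
  expect_identical(er3$label, "0:1")
  # female x heterozygous restorer: 1:1
  er4 <- expected_ratio(mlg("mfmf", "rr", "TT", cytotype = "F"),
                        mlg("mfmf", "Rr", "TT", cytotype = "F"))
  expect_identical(er4$label, "1:1")
  # dominant-sterility carrier dam x heterozygous sire: 1:1
  er5 <- expected_ratio(mlg("MSmf", "RR", "TT", cytotype = "C"),
                        mlg("mfmf", "Rr", "TT", cytotype = "F"))
  expect_identical(er5$label, "1:1")
  # homozygous-fertile x third-locus heterozygote: no sterile classes
  er6 <- expected_ratio(mlg("mfmf", "RR", "TT", cytotype = "F"),
                        mlg("mfmf", "RR", "Tt", cytotype = "F"))
  expect_identical(er6$label, "0:1")
})

test_that("viability selection reproduces the 2:1 lethality ratio exactly", {
  dam <- mlg("mfmf", "rr", "TT", cytotype = "F")
  sire <- mlg("mfmf", "Rr", "TT", cytotype = "B")
  er <- expected_ratio(dam, sire, rr_lethality_rules())
  expect_identical(er$label, "2:1")
  expect_true(rat_num(er$female) == 2 && rat_den(er$female) == 3)
  # survival 0 on the only surviving class errors
  dead <- list(viability_rule(list(LG6 = "Rr"), 0),
               viability_rule(list(LG6 = "rr"), 0))
  expect_error(progeny_distribution(dam, sire, dead), "no viable progeny")
})

test_that("probability mass is conserved exactly and dam/sire swap is neutral", {
  set.seed(42)
  toks6 <- c("RR", "Rr", "rr")
  toksx <- c("TT", "Tt", "tt")
  toks4 <- c("MSmf", "mfmf")
  for (i in 1:12) {
    dam <- mlg(sample(toks4, 1), sample(toks6, 1), sample(toksx, 1), cytotype = "C")
    sire <- mlg(sample(toks4, 1), sample(toks6, 1), sample(toksx, 1), cytotype = "C")
    pd <- progeny_distribution(dam, sire)
    total <- Reduce(rat_add, Map(rat, pd$num, pd$den))
    expect_identical(unclass(total), c(1, 1))
    # symmetry: same cytoplasm, no viability rules
    f1 <- female_fraction(dam, sire)
    f2 <- female_fraction(sire, dam)
    expect_true(rat_eq(f1, f2))
  }
})

test_that("female fractions match brute-force transmission enumeration", {
  set.seed(7)
  toks6 <- c("RR", "Rr", "rr")
  toksx <- c("TT", "Tt", "tt")
  toks4 <- c("MSMS", "MSmf", "mfmf")
  for (i in 1:15) {
    d <- c(sample(toks4, 1), sample(toks6, 1), sample(toksx, 1))
    s <- c(sample(toks4, 1), sample(toks6, 1), sample(toksx, 1))
    got <- rat_value(female_fraction(mlg(d[1], d[2], d[3], cytotype = "C"),
                                     mlg(s[1], s[2], s[3], cytotype = "C")))
    want <- oracle_female_fraction(oracle_alleles(d[1], d[2], d[3]),
                                   oracle_alleles(s[1], s[2], s[3]))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # and once with the viability rule active
  got <- rat_value(female_fraction(mlg("mfmf", "Rr", "Tt", cytotype = "F"),
                                   mlg("mfmf", "Rr", "TT", cytotype = "F"),
                                   rr_lethality_rules()))
  want <- oracle_female_fraction(
    oracle_alleles("mfmf", "Rr", "Tt"), oracle_alleles("mfmf", "Rr", "TT"),
    survival_fun = function(gt) if (setequal(gt$LG6, c("R", "r"))) 0.5 else 1)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("fixing two loci reduces the model to single-locus recessive sterility", {
  het <- mlg("mfmf", "Rr", "TT", cytotype = "F")
  hom <- mlg("mfmf", "rr", "TT", cytotype = "F")
  expect_identical(expected_ratio(het, het)$label, "1:3")
  expect_identical(expected_ratio(hom, het)$label, "1:1")
})

test_that("the alternative second-CMS rule moves the third locus to its own cytoplasm", {
  model2 <- sex_model(phenotype_rule = phenotype_rule_second_cms())
  cy1 <- cytotype("C", cms_present = TRUE, cms2_present = FALSE)
  cy2 <- cytotype("C", cms_present = TRUE, cms2_present = TRUE)
  g_tt <- mlg("mfmf", "RR", "tt", cytotype = cy1, model = model2)
  expect_equal(phenotype_of(g_tt, model2), "H")  # no second CMS: tt inert
  g_tt2 <- mlg("mfmf", "RR", "tt", cytotype = cy2, model = model2)
  expect_equal(phenotype_of(g_tt2, model2), "F")
  g_rr <- mlg("mfmf", "rr", "TT", cytotype = cy1, model = model2)
  expect_equal(phenotype_of(g_rr, model2), "F")
})
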