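# Seeded simulation of panels, crosses and linked markers.

test_that("panel simulation honours frequencies, constraints and determinism", {
  spec <- population_preset("NM-LNF", n_parents = 200)
  panel <- simulate_panel(spec, seed = 1)
  # expected r-allele count: 9 of 12 parental alleles in the preset
  r_count <- sum(vapply(panel, function(g) sum(g$genotype$LG6 == "r"), 0))
  expect_equal(r_count / (2 * length(panel)), 9 / 12, tolerance = 0.08)
  expect_true(all(vapply(panel, function(g) g$cytotype$label, "") == "F"))
  # all-zero sterility frequencies give only hermaphrodites
  all_h <- simulate_panel(panel_spec("x", 50,
                                     allele_freq = list(LG4 = 0, LG6 = 0, LGx = 0)),
                          seed = 2)
  expect_true(all(vapply(all_h, phenotype_of, "") == "H"))
  # a female is then unsatisfiable
  expect_error(simulate_panel(panel_spec("x", 1,
                                         allele_freq = list(LG4 = 0, LG6 = 0, LGx = 0),
                                         sex_constraint = "F"),
                              seed = 3, max_attempts = 50),
               "unsatisfiable")
  # northern mitotype mixture is drawn 9:1
  or <- simulate_panel(population_preset("OR-MRD", n_parents = 400), seed = 4)
  mito <- table(vapply(or, function(g) g$cytotype$label, ""))
  expect_equal(unname(mito["C"] / length(or)), 0.9, tolerance = 0.05)
  # same spec and seed reproduce byte-identical panels
  p1 <- simulate_panel(spec, seed = 99)
  p2 <- simulate_panel(spec, seed = 99)
  expect_identical(vapply(p1, geno_key, ""), vapply(p2, geno_key, ""))
})

test_that("cross simulation respects the model, viability and determinism", {
  dam_rr <- mlg("mfmf", "rr", "TT", cytotype = "F")
  sire_RR <- mlg("mfmf", "RR", "TT", cytotype = "C")
  fam <- simulate_cross(cross_spec(dam_rr, sire_RR, n = 500, family_id = "f0"),
                        seed = 1)
  expect_equal(sum(fam$sex == "F"), 0)  # forced by the model
  expect_true(all(fam$cytotype == "F"))  # cytoplasm from the dam
  # heterozygote self: female fraction within 3 binomial SE of 1/4
  het <- mlg("mfmf", "Rr", "TT", cytotype = "F")
  self <- simulate_cross(cross_spec(het, het, n = 10000, family_id = "f1"),
                         seed = 2)
  expect_equal(mean(self$sex == "F"), 0.25,
               tolerance = 3 * sqrt(0.25 * 0.75 / 10000) / 0.25)
  # lethality preset shifts a 1:1 cross to 2:1 among survivors
  sire_Rr <- mlg("mfmf", "Rr", "TT", cytotype = "B")
  lethal <- simulate_cross(cross_spec(dam_rr, sire_Rr, n = 10000,
                                      family_id = "f2",
                                      rules = rr_lethality_rules()),
                           seed = 3)
  expect_equal(mean(lethal$sex == "F"), 2 / 3,
               tolerance = 3 * sqrt((2 / 9) / 7500) / (2 / 3))
  # n = 0 is an empty frame, not an error
  expect_equal(nrow(simulate_cross(cross_spec(het, het, n = 0), seed = 1)), 0)
  # determinism: identical spec and seed give identical records
  a <- simulate_cross(cross_spec(het, het, n = 50, family_id = "d"), seed = 7)
  b <- simulate_cross(cross_spec(het, het, n = 50, family_id = "d"), seed = 7)
  expect_identical(a, b)
  # phenotypes always agree with the model phenotype of the genotype
  expect_true(all(vapply(seq_len(nrow(a)), function(i)
    phenotype_of(mlg(a$LG4[i], a$LG6[i], a$LGx[i],
                     cytotype = a$cytotype[i])) == a$sex[i], TRUE)))
})

test_that("linked markers cosegregate perfectly at r = 0 and freely at r = 0.5", {
  het <- mlg("mfmf", "Rr", "TT", cytotype = "F")
  map0 <- marker_map(data.frame(marker = "Fvb6_35142280", chrom = "Fvb6",
                                pos = 35142280),
                     anchor = list(locus = "LG6", chrom = "Fvb6", pos = 35142280))
  fam <- simulate_cross(cross_spec(het, het, n = 60, family_id = "ld0",
                                   missing_rate = 0),
                        map0, seed = 5)
  mm <- progeny_to_marker_matrix(fam, map0)
  res <- marker_sex_association(mm, "Fvb6_35142280")
  expect_true(res$coseg)  # zero distance: perfect cosegregation
  # an unlinked marker (other chromosome -> r = 0.5): Fisher test
  # non-significant in >= 90% of families at n = 40
  map5 <- marker_map(data.frame(marker = "Fvb1_1000000", chrom = "Fvb1",
                                pos = 1000000),
                     anchor = list(locus = "LG6", chrom = "Fvb6", pos = 35142280))
  sig <- vapply(1:40, function(k) {
    fam <- simulate_cross(cross_spec(het, het, n = 40,
                                     family_id = paste0("ld", k),
                                     missing_rate = 0),
                          map5, seed = 11)
    mm <- progeny_to_marker_matrix(fam, map5)
    res <- marker_sex_association(mm, "Fvb1_1000000")
    isTRUE(res$applied) && res$p_value < 0.05
  }, TRUE)
  expect_lte(mean(sig), 0.10)
})

test_that("chi-square rejection of simulated heterozygote selfs is calibrated", {
  # type-I error control of the 1:3 test over many simulated families
  het <- mlg("mfmf", "Rr", "TT", cytotype = "F")
  reject <- vapply(1:300, function(k) {
    fam <- simulate_cross(cross_spec(het, het, n = 50,
                                     family_id = paste0("cal", k)),
                          seed = 100)
    chisq_gof(c(sum(fam$sex == "F"), sum(fam$sex == "H")), "1:3")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.09)
})

test_that("fixture emission round-trips through the readers", {
  het <- mlg("mfmf", "Rr", "TT", cytotype = "F")
  map <- marker_map(data.frame(marker = c("Fvb6_35000000", "Fvb6_36000000"),
                               chrom = "Fvb6", pos = c(35000000, 36000000)),
                    anchor = list(locus = "LG6", chrom = "Fvb6", pos = 35142280))
  sp <- cross_spec(het, het, n = 12, family_id = "emit1", missing_rate = 0.1)
  fam <- simulate_cross(sp, map, seed = 21)
  td <- withr::local_tempdir()
  paths <- emit_fixture_tables(list(emit1 = fam), list(emit1 = sp),
                               cross_path = file.path(td, "c.tsv"),
                               marker_path = file.path(td, "m.tsv"), map = map)
  ct <- read_cross_table(file.path(td, "c.tsv"))
  expect_equal(ct$n_female, sum(fam$sex == "F"))
  expect_equal(ct$n_herm, sum(fam$sex == "H"))
  mm <- read_marker_matrix(file.path(td, "m.tsv"))
  expect_identical(unname(mm$calls), unname(as.matrix(fam[, map$markers$marker])))
  expect_equal(mm$markers$pos, map$markers$pos)
  # empty family list yields header-only files
  emit_fixture_tables(list(), cross_path = file.path(td, "e.tsv"),
                      marker_path = file.path(td, "em.tsv"), map = map)
  expect_equal(nrow(read_cross_table(file.path(td, "e.tsv"))), 0)
  # seeded runs are byte-identical
  f1 <- simulate_cross(sp, map, seed = 21)
  emit_fixture_tables(list(emit1 = f1), list(emit1 = sp),
                      cross_path = file.path(td, "c2.tsv"),
                      marker_path = file.path(td, "m2.tsv"), map = map)
  expect_identical(readLines(file.path(td, "c.tsv")),
                   readLines(file.path(td, "c2.tsv")))
  expect_identical(readLines(file.path(td, "m.tsv")),
                   readLines(file.path(td, "m2.tsv")))
})

test_that("per-family substreams are stable when families are added", {
  het <- mlg("mfmf", "Rr", "TT", cytotype = "F")
  a <- simulate_cross(cross_spec(het, het, n = 30, family_id = "famA"), seed = 9)
  # simulating another family first must not perturb famA
  invisible(simulate_cross(cross_spec(het, het, n = 30, family_id = "famB"), seed = 9))
  a2 <- simulate_cross(cross_spec(het, het, n = 30, family_id = "famA"), seed = 9)
  expect_identical(a, a2)
})
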