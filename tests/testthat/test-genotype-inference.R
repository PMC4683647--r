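# Joint parental-genotype inference.

test_that("hypothesis spaces have the enumerated sizes and respect constraints", {
  # hermaphrodite: no dominant sterility allele, no homozygous-sterile locus
  h <- enumerate_parent_hypotheses("H")
  expect_length(h, 4)
  expect_true(all(vapply(h, function(g) phenotype_of(g) == "H", TRUE)))
  # female without the dominant allele: rr x {TT,Tt,tt} union {RR,Rr} x tt
  f_mf <- enumerate_parent_hypotheses("F", constraints = list(LG4 = "mfmf"))
  expect_length(f_mf, 5)
  # unconstrained female adds the 9 MSmf combinations
  f <- enumerate_parent_hypotheses("F")
  expect_length(f, 14)
  expect_true(all(vapply(f, function(g) phenotype_of(g) == "F", TRUE)))
  # MS homozygotes only on request
  f_ms <- enumerate_parent_hypotheses("F", include_ms_hom = TRUE)
  expect_length(f_ms, 23)
  expect_error(enumerate_parent_hypotheses("H", constraints = list(LG6 = "rr")),
               "no genotype hypothesis")
})

toy_panel <- function() {
  data.frame(id = c("D", "S"), population = c("P1", "P1"), sex = c("F", "H"),
             mitotype = c("C", "C"), stringsAsFactors = FALSE)
}

test_that("assignment scoring combines binomial likelihood and diagnostics", {
  panel <- toy_panel()
  crosses <- data.frame(cross_type = "FxH", dam = "D", sire = "S",
                        n_female = 0L, n_herm = 18L, stringsAsFactors = FALSE)
  # a dam wrongly carrying the dominant allele predicts 1:1 and is rejected
  bad <- score_assignment(list(D = "MSmf RR TT", S = "mfmf Rr TT"),
                          crosses, panel)
  expect_equal(bad$per_cross$chisq, 18, tolerance = 1e-9)
  expect_lt(bad$per_cross$p_value, 1e-4)
  good <- score_assignment(list(D = "mfmf rr TT", S = "mfmf RR TT"),
                           crosses, panel)
  expect_gt(good$loglik, bad$loglik)
  # empty informative cross list scores zero
  none <- score_assignment(list(D = "mfmf rr TT", S = "mfmf RR TT"),
                           crosses[0, ], panel)
  expect_equal(none$loglik, 0)
  # strict mode zeroes the likelihood of an anomalous female
  crosses2 <- crosses
  crosses2$n_female <- 1L
  strict <- score_assignment(list(D = "mfmf rr TT", S = "mfmf RR TT"),
                             crosses2, panel, epsilon = 0)
  expect_identical(strict$loglik, -Inf)
  tol <- score_assignment(list(D = "mfmf rr TT", S = "mfmf RR TT"),
                          crosses2, panel, epsilon = 0.01)
  expect_true(is.finite(tol$loglik))
})

test_that("a lone double-heterozygote self family is inferred from its 15:15 ratio", {
  panel <- data.frame(id = "P", population = "NM-LNF", sex = "H",
                      mitotype = "F", stringsAsFactors = FALSE)
  crosses <- data.frame(cross_type = "H-SELF", dam = "P", sire = "P",
                        n_female = 15L, n_herm = 15L, stringsAsFactors = FALSE)
  rep <- infer_genotypes(panel, crosses)
  expect_equal(unname(rep$assignments[[1]]["P"]), "mfmf Rr Tt")
  expect_length(rep$assignments, 1)
})

test_that("an uninformative all-hermaphrodite family is reported as tied", {
  panel <- data.frame(id = c("A", "B"), population = "P", sex = "H",
                      mitotype = "C", stringsAsFactors = FALSE)
  crosses <- data.frame(cross_type = "HxH", dam = "A", sire = "B",
                        n_female = 0L, n_herm = 20L, stringsAsFactors = FALSE)
  rep <- infer_genotypes(panel, crosses)
  # every assignment predicting zero females is tied at the maximum
  expect_gt(length(rep$assignments), 1)
  expect_true("mfmf RR TT" %in% rep$per_parent_ties$A)
  expect_true("mfmf RR TT" %in% rep$per_parent_ties$B)
  # no tied assignment predicts females: all involve a homozygous restorer
  pairs <- vapply(rep$assignments, function(a) paste(a["A"], a["B"]), "")
  expect_false(any(grepl("Rr .. mfmf Rr", pairs)))
})

test_that("the published design recovers the reported genotypes except the skewed dam", {
  panel <- parent_panel_fixture()
  crosses <- crossing_table_fixture()
  rep <- infer_genotypes(panel, crosses, preset = lethality_preset())
  reported <- stats::setNames(paste(panel$LG4, panel$LG6, panel$LGx), panel$id)
  best <- rep$assignments[[1]]
  agree <- best[panel$id] == reported[panel$id]
  # 11 of the 12 reported genotypes are the joint maximum-likelihood ones;
  # the female-skewed dam is pulled to a restorer-heterozygous genotype by
  # the same families the study flags as deviating from 1:1
  expect_equal(sum(agree), 11)
  expect_identical(names(agree)[!agree], "MRD27")
  expect_identical(unname(best["MRD27"]), "MSmf Rr Tt")
  # the reported assignment scores within a few log units of the maximum
  sc <- score_assignment(as.list(reported), crosses, panel,
                         preset = lethality_preset())
  expect_gt(sc$loglik, rep$loglik - 4)
  # the lethality preset is strongly preferred over the no-lethality model
  expect_gt(rep$loglik, rep$loglik_no_preset + 4)
  # determinism of the full report
  rep2 <- infer_genotypes(panel, crosses, preset = lethality_preset())
  expect_identical(rep$assignments, rep2$assignments)
  expect_equal(rep$loglik, rep2$loglik)
})

test_that("all returned assignments phenotype parents consistently", {
  panel <- parent_panel_fixture()
  crosses <- crossing_table_fixture()
  rep <- infer_genotypes(panel, crosses, preset = lethality_preset())
  for (a in rep$assignments) {
    for (i in seq_len(nrow(panel))) {
      g <- mlg(strsplit(a[[panel$id[i]]], " ")[[1]],
               cytotype = cytotype(panel$mitotype[i]))
      expect_identical(phenotype_of(g), panel$sex[i])
    }
  }
})

test_that("the search is globally optimal and misses are data-driven, not search errors", {
  # simulate diallels and verify (i) the reported maximum likelihood is
  # never below the generating assignment's likelihood (global optimality
  # against the truth), (ii) whenever the generating assignment is absent
  # from the ML-tied set, some alternative fits the data strictly better,
  # and (iii) in expectation the generating assignment dominates any fixed
  # phenotype-consistent alternative
  run_one <- function(seed) {
    herms <- simulate_panel(population_preset("NM-LNF", 3, sex_constraint = "H"),
                            seed = seed)
    fems <- simulate_panel(population_preset("NM-LNF", 3, sex_constraint = "F"),
                           seed = seed + 1000)
    parents <- c(herms, fems)
    ids <- c(paste0("H", 1:3), paste0("F", 1:3))
    panel <- data.frame(id = ids, population = "NM-LNF",
                        sex = c(rep("H", 3), rep("F", 3)),
                        mitotype = "F", stringsAsFactors = FALSE)
    rows <- list()
    for (d in 1:6) for (s in 1:3) {
      fam <- simulate_cross(cross_spec(parents[[d]], parents[[s]], n = 50,
                                       family_id = paste(ids[d], ids[s])),
                            seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        cross_type = if (d == s) "H-SELF" else "X",
        dam = ids[d], sire = ids[s],
        n_female = sum(fam$sex == "F"), n_herm = sum(fam$sex == "H"),
        stringsAsFactors = FALSE)
    }
    crosses <- do.call(rbind, rows)
    rep <- infer_genotypes(panel, crosses)
    truth <- stats::setNames(vapply(parents, geno_key, ""), ids)
    ll_truth <- score_assignment(as.list(truth), crosses, panel)$loglik
    hit <- any(vapply(rep$assignments, function(a) all(a[ids] == truth[ids]), TRUE))
    # a fixed distorted alternative: flip one heterozygous locus of H1
    alt <- truth
    alt["H1"] <- if (grepl("Tt", alt["H1"])) sub("Tt", "TT", alt["H1"]) else
      sub("TT", "Tt", alt["H1"])
    ll_alt <- score_assignment(as.list(alt), crosses, panel)$loglik
    list(opt_ok = rep$loglik >= ll_truth - 1e-6,
         miss_ok = hit || rep$loglik > ll_truth + 1e-6,
         hit = hit, dom = ll_truth - ll_alt)
  }
  out <- lapply(1:20, run_one)
  expect_true(all(vapply(out, `[[`, TRUE, "opt_ok")))
  expect_true(all(vapply(out, `[[`, TRUE, "miss_ok")))
  # the truth dominates the fixed alternative on average across replicates
  expect_gt(mean(vapply(out, `[[`, 0, "dom")), 0)
  # and the truth is recovered in a clear majority of replicates
  expect_gt(mean(vapply(out, `[[`, TRUE, "hit")), 0.5)
})
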