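# Goodness-of-fit and marker-trait association statistics for progeny
# sex-ratio data: Pearson chi-square against hypothesised ratios (no
# continuity correction, df = 1), an exact test for degenerate 0:1 / 1:0
# hypotheses, two-sided Fisher's exact tests on 2x2 tables, best-fit ratio
# selection, and marker-sex association with a perfect-cosegregation flag.

#' Observed progeny sex counts
#' @param n_female,n_herm non-negative integer counts.
#' @export
observed_counts <- function(n_female, n_herm) {
  stopifnot(length(n_female) == 1, length(n_herm) == 1,
            n_female >= 0, n_herm >= 0,
            n_female == round(n_female), n_herm == round(n_herm))
  structure(list(n_female = as.integer(n_female), n_herm = as.integer(n_herm)),
            class = "observed_counts")
}

test_result <- function(statistic, df, p_value, applied = TRUE, note = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 applied = applied, note = note),
            class = "seg_test_result")
}

#' @export
format.seg_test_result <- function(x, ...) {
  if (!x$applied) return(paste0("not applied", if (!is.null(x$note)) paste0(" (", x$note, ")")))
  paste0("chi2 = ", format(round(x$statistic, 4)), ", df = ", x$df,
         ", p = ", format(signif(x$p_value, 4)),
         if (!is.null(x$note)) paste0(" [", x$note, "]"))
}

#' @export
print.seg_test_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Pearson chi-square goodness of fit of observed sex counts to a ratio
#'
#' No continuity correction; df = 1; p from the continuous chi-square
#' distribution. Families smaller than `n_min` (default 10, the study's
#' "too few progeny" rule) are returned with `applied = FALSE` and no
#' statistic. Degenerate hypotheses with a zero-probability class must go
#' through [exact_zero_class_test()].
#'
#' @param obs an [observed_counts()] (or a length-2 numeric
#'   `c(female, herm)`).
#' @param hyp a [ratio_hypothesis()] or ratio label such as `"1:3"`.
#' @param n_min minimum family size for the test to be applied.
#' @return A `seg_test_result`.
#' @examples
#' chisq_gof(observed_counts(17, 36), "1:3")  # chi2 = 1.42
#' @export
chisq_gof <- function(obs, hyp, n_min = 10) {
  obs <- as_observed(obs)
  hyp <- as_hypothesis(hyp)
  n <- obs$n_female + obs$n_herm
  if (n == 0) stop("no progeny observed")
  pf <- rat_value(hyp$female)
  if (pf == 0 || pf == 1)
    stop("hypothesis has a zero expected class; use exact_zero_class_test()",
         call. = FALSE)
  if (n < n_min)
    return(test_result(NA_real_, 1L, NA_real_, applied = FALSE,
                       note = sprintf("family size %d < %d", n, n_min)))
  res <- suppressWarnings(
    stats::chisq.test(c(obs$n_female, obs$n_herm), p = c(pf, 1 - pf),
                      correct = FALSE))
  test_result(unname(res$statistic), 1L, unname(res$p.value))
}

#' Exact test for degenerate (0:1 or 1:0) ratio hypotheses
#'
#' Under an all-one-class hypothesis the fit is perfect (statistic 0) iff
#' every observation falls in the nonzero class; any observation in the
#' zero class rejects the hypothesis exactly (p = 0) and is flagged as an
#' anomaly (the crossing data contain one such anomalous female).
#'
#' @inheritParams chisq_gof
#' @return A `seg_test_result`; `note` carries the anomaly flag.
#' @export
exact_zero_class_test <- function(obs, hyp) {
  obs <- as_observed(obs)
  hyp <- as_hypothesis(hyp)
  pf <- rat_value(hyp$female)
  if (!(pf == 0 || pf == 1))
    stop("exact_zero_class_test is only for degenerate hypotheses")
  n_zero <- if (pf == 0) obs$n_female else obs$n_herm
  if (n_zero == 0) {
    test_result(0, NA_integer_, 1)
  } else {
    test_result(Inf, NA_integer_, 0,
                note = sprintf("%d anomalous %s in zero-expectation class",
                               n_zero, if (pf == 0) "female(s)" else "hermaphrodite(s)"))
  }
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided by the minimum-likelihood rule: the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(8, 0, 0, 33), 2))  # ~1.05e-8
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) stop("all-zero table", call. = FALSE)
  stats::fisher.test(table)$p.value
}

as_observed <- function(obs) {
  if (inherits(obs, "observed_counts")) return(obs)
  if (is.numeric(obs) && length(obs) == 2) return(observed_counts(obs[1], obs[2]))
  stop("cannot interpret observed counts")
}

as_hypothesis <- function(hyp) {
  if (inherits(hyp, "ratio_hypothesis")) return(hyp)
  if (is.character(hyp) && length(hyp) == 1) return(ratio_from_label(hyp))
  stop("cannot interpret ratio hypothesis")
}

n_het_loci <- function(prov) {
  if (is.null(prov)) return(NA_integer_)
  count_one <- function(key) {
    toks <- strsplit(key, " ", fixed = TRUE)[[1]]
    sum(vapply(toks, function(tk) {
      n <- nchar(tk)
      first <- substr(tk, 1, n / 2)
      # heterozygous unless the token is a doubled symbol
      !identical(paste0(first, first), tk)
    }, TRUE))
  }
  sum(vapply(unlist(prov), count_one, 0L))
}

#' Rank candidate ratio hypotheses by goodness of fit
#'
#' Each hypothesis is tested with [chisq_gof()] (or the exact degenerate
#' test) and the results are ranked by descending p-value; ties are broken
#' by fewer heterozygous loci in the hypothesis provenance (parsimony),
#' then by label order.
#'
#' @param obs observed counts.
#' @param hypotheses list of [ratio_hypothesis()] objects or ratio labels.
#' @param n_min minimum family size passed to [chisq_gof()].
#' @return A data frame of all hypotheses with statistics, ranked; the best
#'   fit first.
#' @export
best_fit_ratio <- function(obs, hypotheses, n_min = 10) {
  stopifnot(length(hypotheses) >= 1)
  hyps <- lapply(hypotheses, as_hypothesis)
  rows <- lapply(hyps, function(h) {
    pf <- rat_value(h$female)
    res <- if (pf == 0 || pf == 1) exact_zero_class_test(obs, h) else
      chisq_gof(obs, h, n_min = n_min)
    data.frame(label = h$label,
               female_fraction = pf,
               statistic = res$statistic,
               p_value = res$p_value,
               applied = res$applied,
               n_het = n_het_loci(h$provenance),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ord <- order(-df$p_value, df$n_het, df$label, na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Marker-sex association test with perfect-cosegregation flag
#'
#' Builds the 2x2 table female/hermaphrodite x homozygous-coupling/other
#' for one marker of a [read_marker_matrix()] matrix under a
#' recessive-coupling coding (the marker allele travelling with the
#' sterility allele is taken as the allele whose homozygote class is most
#' enriched in females), runs [fisher_exact_2x2()], and flags perfect
#' cosegregation when there are zero mismatches among non-missing calls.
#'
#' @param matrix a marker genotype matrix (see [read_marker_matrix()]).
#' @param marker marker id (column name).
#' @return A list: `table`, `p_value`, `coseg` flag, `coupling_allele`,
#'   `applied` (FALSE for monomorphic markers), `n_used`.
#' @export
marker_sex_association <- function(matrix, marker) {
  calls <- matrix$calls[, marker]
  sex <- matrix$sex
  keep <- calls != "."
  calls <- calls[keep]
  sex <- sex[keep]
  if (!length(calls)) return(list(applied = FALSE, note = "no non-missing calls"))
  alleles <- unique(unlist(strsplit(calls, "/", fixed = TRUE)))
  if (length(alleles) < 2)
    return(list(applied = FALSE, note = "monomorphic marker"))
  if (!any(sex == SEX_FEMALE) || !any(sex == SEX_HERM))
    return(list(applied = FALSE, note = "one phenotype class absent"))
  best <- NULL
  for (a in alleles) {
    hom <- calls == a
    tab <- rbind(female = c(hom = sum(sex == SEX_FEMALE & hom),
                            other = sum(sex == SEX_FEMALE & !hom)),
                 herm = c(hom = sum(sex == SEX_HERM & hom),
                          other = sum(sex == SEX_HERM & !hom)))
    mism <- tab["female", "other"] + tab["herm", "hom"]
    if (is.null(best) || mism < best$mismatches) {
      best <- list(coupling_allele = a, table = tab, mismatches = mism)
    }
  }
  p <- fisher_exact_2x2(best$table)
  list(applied = TRUE,
       coupling_allele = best$coupling_allele,
       table = best$table,
       mismatches = unname(best$mismatches),
       coseg = best$mismatches == 0,
       p_value = p,
       n_used = length(calls))
}

#' Chi-square tests for every family of a cross table
#'
#' Applies [chisq_gof()] / [exact_zero_class_test()] row-wise against the
#' expected ratios implied by a genotype assignment (or against supplied
#' ratio labels), mirroring the published crossing-table layout.
#'
#' @param crosses a cross table data frame (see [read_cross_table()]).
#' @param ratios character vector of expected ratio labels, one per row
#'   (`NA` rows are skipped).
#' @param n_min minimum family size.
#' @return The cross table with `expected_ratio`, `chisq`, `p_value` and
#'   `applied` columns appended.
#' @export
test_cross_table <- function(crosses, ratios, n_min = 10) {
  stopifnot(nrow(crosses) == length(ratios))
  out <- crosses
  out$expected_ratio <- ratios
  out$chisq <- NA_real_
  out$p_value <- NA_real_
  out$applied <- FALSE
  for (i in seq_len(nrow(out))) {
    if (is.na(ratios[i])) next
    n <- out$n_female[i] + out$n_herm[i]
    if (n == 0) next
    hyp <- ratio_from_label(ratios[i])
    pf <- rat_value(hyp$female)
    res <- if (pf == 0 || pf == 1)
      exact_zero_class_test(c(out$n_female[i], out$n_herm[i]), hyp)
    else chisq_gof(c(out$n_female[i], out$n_herm[i]), hyp, n_min = n_min)
    out$chisq[i] <- res$statistic
    out$p_value[i] <- res$p_value
    out$applied[i] <- res$applied
  }
  out
}
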