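# Single-family two-point LOD mapping of binary male sterility in a selfed
# F2 family, and the perfect-cosegregation candidate interval bounded by
# the nearest mismatching markers.
#
# Male sterility is coded as a recessive Mendelian locus (sterile rr,
# fertile R-). For a codominant marker in coupling phase, the selfed
# parent's gametes carry (marker allele, trait allele) combinations with
# frequencies {(1-r)/2, (1-r)/2, r/2, r/2}; squaring through selfing and
# collapsing by trait dominance gives the joint class probabilities, and
# LOD(r) = sum over individuals of log10 P(class | r) / P(class | 1/2).

#' Code a binary sex phenotype as a Mendelian trait class
#'
#' @param phenotypes character vector of `"F"` / `"H"`.
#' @param trait_model `"recessive"` (female = homozygous sterile, the LG6
#'   coding) or `"dominant"` (female = carrier of a dominant sterility
#'   allele, the LG4 coding).
#' @return Character vector with classes `"hom_sterile"`/`"carrier"`
#'   (recessive) or `"carrier_sterile"`/`"hom_fertile"` (dominant).
#' @export
code_trait <- function(phenotypes, trait_model = c("recessive", "dominant")) {
  trait_model <- match.arg(trait_model)
  stopifnot(all(phenotypes %in% c(SEX_FEMALE, SEX_HERM)))
  if (trait_model == "recessive") {
    ifelse(phenotypes == SEX_FEMALE, "hom_sterile", "carrier")
  } else {
    ifelse(phenotypes == SEX_FEMALE, "carrier_sterile", "hom_fertile")
  }
}

# Joint probabilities of (marker genotype class, trait class) in a selfed
# F2 with the marker's first allele in coupling with the recessive sterile
# allele. Rows: hom_coupling, het, hom_repulsion; columns: hom_sterile,
# carrier.
f2_joint_class_probs <- function(r) {
  # gametes: (a, s) and (A, S) at (1-r)/2 each; (a, S) and (A, s) at r/2
  gam <- data.frame(mk = c("a", "A", "a", "A"),
                    tr = c("s", "S", "S", "s"),
                    p = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2))
  probs <- matrix(0, 3, 2,
                  dimnames = list(c("hom_coupling", "het", "hom_repulsion"),
                                  c("hom_sterile", "carrier")))
  for (i in 1:4) {
    for (j in 1:4) {
      n_a <- sum(c(gam$mk[i], gam$mk[j]) == "a")
      mclass <- c("hom_repulsion", "het", "hom_coupling")[n_a + 1]
      tclass <- if (all(c(gam$tr[i], gam$tr[j]) == "s")) "hom_sterile" else "carrier"
      probs[mclass, tclass] <- probs[mclass, tclass] + gam$p[i] * gam$p[j]
    }
  }
  probs
}

marker_class_counts <- function(calls, trait, alleles = NULL) {
  keep <- calls != "."
  calls <- calls[keep]
  trait <- trait[keep]
  seen <- sort(unique(unlist(strsplit(calls, "/", fixed = TRUE))))
  if (is.null(alleles)) alleles <- seen
  else if (!all(seen %in% alleles))
    stop("call allele(s) outside the declared allele set: ",
         paste(setdiff(seen, alleles), collapse = ", "), call. = FALSE)
  list(alleles = alleles, calls = calls, trait = trait, n = length(calls))
}

#' Two-point LOD profile of one marker against the sterility trait
#'
#' @param matrix a `marker_matrix` from a selfed-F2 family
#'   ([read_marker_matrix()] or [progeny_to_marker_matrix()]).
#' @param marker marker id.
#' @param trait trait classes from [code_trait()] (defaults to recessive
#'   coding of `matrix$sex`).
#' @param grid recombination-fraction grid (default `seq(0, 0.5, 0.005)`).
#' @param alleles optional explicit allele pair for the marker (e.g. known
#'   from the parent); by default the alleles observed among the calls.
#' @return List: `max_lod`, `r_hat` (argmax over the grid), `n_informative`,
#'   `lod` (vector over the grid at the best phase), `applied` (FALSE with
#'   a `note` for monomorphic or all-missing markers).
#' @export
two_point_lod <- function(matrix, marker, trait = code_trait(matrix$sex),
                          grid = seq(0, 0.5, by = 0.005), alleles = NULL) {
  calls <- matrix$calls[, marker]
  mc <- marker_class_counts(calls, trait, alleles)
  if (mc$n == 0) return(list(applied = FALSE, note = "no non-missing calls"))
  if (length(mc$alleles) < 2)
    return(list(applied = FALSE, note = "monomorphic marker"))
  if (length(mc$alleles) > 2)
    return(list(applied = FALSE, note = "more than two alleles"))
  count_classes <- function(coupling) {
    other <- setdiff(mc$alleles, coupling)
    mclass <- ifelse(mc$calls == coupling, "hom_coupling",
                     ifelse(mc$calls == other, "hom_repulsion", "het"))
    table(factor(mclass, c("hom_coupling", "het", "hom_repulsion")),
          factor(mc$trait, c("hom_sterile", "carrier")))
  }
  null_probs <- f2_joint_class_probs(0.5)
  best <- NULL
  for (coupling in mc$alleles) {
    counts <- count_classes(coupling)
    lod <- vapply(grid, function(r) {
      probs <- f2_joint_class_probs(r)
      occ <- counts > 0  # empty classes contribute nothing (avoids 0 * -Inf)
      sum(counts[occ] * (log10(probs[occ]) - log10(null_probs[occ])))
    }, 0)
    if (is.null(best) || max(lod) > max(best$lod)) {
      best <- list(lod = lod, coupling = coupling, counts = counts)
    }
  }
  i <- which.max(best$lod)
  list(applied = TRUE, max_lod = best$lod[i], r_hat = grid[i],
       n_informative = mc$n, lod = best$lod, grid = grid,
       coupling_allele = best$coupling)
}

#' LOD profile along a chromosome
#'
#' Applies [two_point_lod()] to every marker; markers exceeding the LOD
#' significance threshold (default 3) are flagged.
#'
#' @inheritParams two_point_lod
#' @param lod_threshold significance threshold.
#' @return Data frame: `marker`, `chrom`, `pos`, `n_informative`,
#'   `max_lod`, `r_hat`, `significant`, `applied`.
#' @export
scan_chromosome <- function(matrix, trait = code_trait(matrix$sex),
                            grid = seq(0, 0.5, by = 0.005), lod_threshold = 3) {
  rows <- lapply(seq_len(nrow(matrix$markers)), function(j) {
    m <- matrix$markers$marker[j]
    res <- two_point_lod(matrix, m, trait, grid)
    data.frame(marker = m, chrom = matrix$markers$chrom[j],
               pos = matrix$markers$pos[j],
               n_informative = if (res$applied) res$n_informative else 0L,
               max_lod = if (res$applied) res$max_lod else NA_real_,
               r_hat = if (res$applied) res$r_hat else NA_real_,
               significant = res$applied && res$max_lod > lod_threshold,
               applied = res$applied,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# Mismatches of a marker with the trait at r = 0 under the best phase: at
# complete linkage the homozygous-coupling class coincides exactly with the
# homozygous-sterile class, so any female not homozygous coupling, or any
# carrier that is, is impossible. Missing calls are skipped.
marker_mismatches <- function(calls, trait) {
  mc <- marker_class_counts(calls, trait)
  if (mc$n == 0 || length(mc$alleles) != 2) return(NA_integer_)
  best <- Inf
  for (coupling in mc$alleles) {
    hom <- mc$calls == coupling
    mism <- sum(mc$trait == "hom_sterile" & !hom) +
      sum(mc$trait == "carrier" & hom)
    best <- min(best, mism)
  }
  as.integer(best)
}

#' Perfect-cosegregation candidate interval
#'
#' Counts, per marker, the individuals whose (marker class, trait class)
#' pair is impossible at recombination fraction 0 under the best phase.
#' The maximal run of zero-mismatch markers containing the maximum-LOD
#' marker is the perfect-match span; its bounds are the nearest flanking
#' markers with at least one mismatch (or the chromosome ends, flagged
#' unbounded). Interval length is the simple position difference of the
#' bounds, in Mb to 3 decimals.
#'
#' @inheritParams two_point_lod
#' @param chrom chromosome to evaluate (default: chromosome of the
#'   maximum-LOD marker).
#' @param tolerance mismatch count still treated as "perfect" (default 0).
#' @return List: `chrom`, `span` (first/last perfect marker positions),
#'   `bounds` (flanking mismatch positions), `length_mb`, `unbounded`,
#'   `mismatches` (per-marker table).
#' @export
cosegregation_interval <- function(matrix, trait = code_trait(matrix$sex),
                                   chrom = NULL, tolerance = 0) {
  scan <- scan_chromosome(matrix, trait)
  if (is.null(chrom)) {
    ok <- scan[scan$applied & !is.na(scan$max_lod), , drop = FALSE]
    if (!nrow(ok)) stop("no marker usable for interval calling", call. = FALSE)
    chrom <- ok$chrom[which.max(ok$max_lod)]
  }
  idx <- which(matrix$markers$chrom == chrom)
  idx <- idx[order(matrix$markers$pos[idx])]
  pos <- matrix$markers$pos[idx]
  mism <- vapply(idx, function(j)
    marker_mismatches(matrix$calls[, j], trait), 0L)
  usable <- !is.na(mism)
  peak <- scan[scan$chrom == chrom & scan$applied, , drop = FALSE]
  if (!nrow(peak)) stop("no candidate interval", call. = FALSE)
  peak_pos <- peak$pos[which.max(peak$max_lod)]
  perfect <- usable & mism <= tolerance
  if (!any(perfect)) stop("no candidate interval", call. = FALSE)
  k <- which(pos == peak_pos)
  if (!length(k) || !perfect[k]) k <- which(perfect)[1]
  lo <- k
  while (lo > 1 && (perfect[lo - 1] || !usable[lo - 1])) lo <- lo - 1
  hi <- k
  while (hi < length(idx) && (perfect[hi + 1] || !usable[hi + 1])) hi <- hi + 1
  while (!perfect[lo]) lo <- lo + 1
  while (!perfect[hi]) hi <- hi - 1
  # nearest flanking markers that actually mismatch (skip unusable ones)
  j <- lo - 1
  while (j >= 1 && !(usable[j] && mism[j] > tolerance)) j <- j - 1
  up <- if (j >= 1) pos[j] else NA_real_
  j <- hi + 1
  while (j <= length(idx) && !(usable[j] && mism[j] > tolerance)) j <- j + 1
  down <- if (j <= length(idx)) pos[j] else NA_real_
  unbounded <- is.na(up) || is.na(down)
  length_mb <- if (!unbounded) round((down - up) / 1e6, 3) else NA_real_
  list(chrom = chrom,
       span = c(first_perfect = pos[lo], last_perfect = pos[hi]),
       bounds = c(upstream = up, downstream = down),
       length_mb = length_mb,
       unbounded = unbounded,
       mismatches = data.frame(marker = matrix$markers$marker[idx],
                               pos = pos, mismatches = mism,
                               stringsAsFactors = FALSE))
}

#' Plot a LOD profile along chromosomes
#' @param scan result of [scan_chromosome()].
#' @param lod_threshold horizontal significance line.
#' @return A ggplot object.
#' @export
plot_lod_profile <- function(scan, lod_threshold = 3) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(scan[scan$applied, ],
                  ggplot2::aes(x = pos / 1e6, y = max_lod)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = lod_threshold, linetype = 2, colour = "grey40") +
    ggplot2::facet_grid(cols = ggplot2::vars(chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "LOD") +
    ggplot2::theme_minimal()
}
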