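# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's own code paths: progeny sex ratios are
# obtained by enumerating all 4^3 x 4^3 parental allele transmissions, and
# Fisher p-values by direct hypergeometric enumeration over tables with
# fixed margins.

# Female fraction of a cross by brute-force enumeration of every
# equally-likely transmission choice (which of the two alleles each parent
# passes at each of 3 loci), with optional survival weights.
oracle_female_fraction <- function(dam_alleles, sire_alleles, cms = TRUE,
                                   survival_fun = NULL) {
  # dam_alleles / sire_alleles: list(LG4 = c(a1, a2), LG6 = ..., LGx = ...)
  choices <- expand.grid(d4 = 1:2, d6 = 1:2, dx = 1:2,
                         s4 = 1:2, s6 = 1:2, sx = 1:2)
  num <- 0
  den <- 0
  for (i in seq_len(nrow(choices))) {
    ch <- choices[i, ]
    gt <- list(
      LG4 = c(dam_alleles$LG4[ch$d4], sire_alleles$LG4[ch$s4]),
      LG6 = c(dam_alleles$LG6[ch$d6], sire_alleles$LG6[ch$s6]),
      LGx = c(dam_alleles$LGx[ch$dx], sire_alleles$LGx[ch$sx]))
    w <- if (is.null(survival_fun)) 1 else survival_fun(gt)
    female <- cms && (any(gt$LG4 == "MS") || all(gt$LG6 == "r") || all(gt$LGx == "t"))
    den <- den + w
    num <- num + w * female
  }
  num / den
}

# Allele pairs of a genotype-token triple, for feeding the oracle.
oracle_alleles <- function(lg4, lg6, lgx) {
  split_tok <- function(tok, syms) {
    for (i in seq_along(syms)) for (j in seq_along(syms)) {
      if (paste0(syms[i], syms[j]) == tok) return(c(syms[i], syms[j]))
    }
    stop("bad token ", tok)
  }
  list(LG4 = split_tok(lg4, c("MS", "mf")),
       LG6 = split_tok(lg6, c("R", "r")),
       LGx = split_tok(lgx, c("T", "t")))
}

# Two-sided Fisher p by enumerating all 2x2 tables with the observed
# margins and summing hypergeometric probabilities <= the observed table's
# (minimum-likelihood rule).
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  obs_p <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs_p * (1 + 1e-7)])
}

# Closed-form joint (marker class, trait class) probabilities for a selfed
# F2 with a codominant marker at recombination fraction r from a recessive
# trait locus, coupling phase.
oracle_f2_probs <- function(r) {
  m <- matrix(0, 3, 2, dimnames = list(
    c("hom_coupling", "het", "hom_repulsion"), c("hom_sterile", "carrier")))
  m["hom_coupling", "hom_sterile"] <- ((1 - r) / 2)^2
  m["hom_coupling", "carrier"] <- 1 / 4 - ((1 - r) / 2)^2
  m["het", "hom_sterile"] <- r * (1 - r) / 2
  m["het", "carrier"] <- 1 / 2 - r * (1 - r) / 2
  m["hom_repulsion", "hom_sterile"] <- (r / 2)^2
  m["hom_repulsion", "carrier"] <- 1 / 4 - (r / 2)^2
  m
}

# Build an in-memory marker matrix from per-individual call vectors.
make_marker_matrix <- function(sex, calls_by_marker, chrom = "Fvb6",
                               pos = NULL) {
  markers <- names(calls_by_marker)
  if (is.null(pos)) pos <- seq(1e6, by = 1e6, length.out = length(markers))
  calls <- do.call(cbind, calls_by_marker)
  colnames(calls) <- markers
  structure(list(markers = data.frame(marker = markers, chrom = chrom,
                                      pos = pos, stringsAsFactors = FALSE),
                 calls = calls, sex = sex,
                 family = rep("fam", length(sex)),
                 id = paste0("i", seq_along(sex)),
                 design = "selfed_f2"),
            class = "marker_matrix")
}
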