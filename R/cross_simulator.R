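# Seeded synthetic-data stage: parent panels drawn under Hardy-Weinberg,
# crosses with independent assortment at the model loci, linked markers
# recombining with an anchored locus under the Haldane map function,
# genotype-dependent viability, germination dropout and missing calls.
# One master seed; each family draws from a substream derived by stable
# hashing of its family id, so adding a family never perturbs the others.

# Deterministic 31-bit string hash (polynomial rolling hash); used to derive
# per-family substream seeds from the master seed.
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

derive_seed <- function(master, id) {
  as.integer((as.numeric(master) * 48271 + stable_hash(id)) %% 2147483629 + 1)
}

#' Specify a parent panel to simulate
#'
#' @param population population label.
#' @param n_parents number of parents to draw.
#' @param allele_freq named list of recessive/sterility-allele frequencies
#'   per locus: frequency of `MS` at LG4, of `r` at LG6, of `t` at LGx.
#' @param mitotype_freq named numeric vector of mitotype frequencies
#'   (summing to 1); all listed mitotypes are treated as CMS-carrying
#'   unless named in `non_cms`.
#' @param sex_constraint optional `"F"` or `"H"`: rejection-sample until
#'   each parent has this phenotype.
#' @param non_cms character vector of mitotype labels without CMS.
#' @return A `panel_spec`.
#' @export
panel_spec <- function(population, n_parents,
                       allele_freq = list(LG4 = 0, LG6 = 0.25, LGx = 0.05),
                       mitotype_freq = c(C = 1),
                       sex_constraint = NULL, non_cms = character()) {
  stopifnot(n_parents >= 0)
  af <- unlist(allele_freq)
  if (any(af < 0 | af > 1)) stop("allele frequencies must lie in [0, 1]")
  if (abs(sum(mitotype_freq) - 1) > 1e-9) stop("mitotype frequencies must sum to 1")
  if (!is.null(sex_constraint)) stopifnot(sex_constraint %in% c("F", "H"))
  structure(list(population = population, n_parents = n_parents,
                 allele_freq = allele_freq, mitotype_freq = mitotype_freq,
                 sex_constraint = sex_constraint, non_cms = non_cms),
            class = "panel_spec")
}

#' Population presets matching the study's parental allele counts
#'
#' The southern population carries no dominant sterility allele, a high
#' frequency of the non-restoring r allele (9 of 12 parental alleles) and a
#' rare t (1/12), on a fixed F mitotype. The northern population carries MS
#' at 3/12, r at 1/12 and t at 1/12, with mitotypes 90% C and 10% B.
#'
#' @param population `"NM-LNF"` or `"OR-MRD"`.
#' @param n_parents panel size.
#' @param sex_constraint optional phenotype constraint.
#' @return A [panel_spec()].
#' @export
population_preset <- function(population = c("NM-LNF", "OR-MRD"), n_parents = 6,
                              sex_constraint = NULL) {
  population <- match.arg(population)
  if (population == "NM-LNF") {
    panel_spec(population, n_parents,
               allele_freq = list(LG4 = 0, LG6 = 9 / 12, LGx = 1 / 12),
               mitotype_freq = c(F = 1), sex_constraint = sex_constraint)
  } else {
    panel_spec(population, n_parents,
               allele_freq = list(LG4 = 3 / 12, LG6 = 1 / 12, LGx = 1 / 12),
               mitotype_freq = c(C = 0.9, B = 0.1), sex_constraint = sex_constraint)
  }
}

draw_genotype_once <- function(spec, model) {
  toks <- vapply(names(model$loci), function(nm) {
    loc <- model$loci[[nm]]
    # allele_freq gives the frequency of the *sterility-associated* allele:
    # dominant MS at LG4, recessive r / t elsewhere
    q <- spec$allele_freq[[nm]]
    if (is.null(q)) q <- 0
    special <- if (nm == "LG4") loc$alleles[1] else loc$alleles[2]
    other <- setdiff(loc$alleles, special)
    pair <- ifelse(stats::runif(2) < q, special, other)
    paste0(canonical_pair(pair, loc), collapse = "")
  }, "")
  mito <- sample(names(spec$mitotype_freq), 1, prob = spec$mitotype_freq)
  mlg(toks, cytotype = cytotype(mito, cms_present = !(mito %in% spec$non_cms)),
      model = model)
}

#' Simulate a parent panel under Hardy-Weinberg
#'
#' @param spec a [panel_spec()].
#' @param seed integer seed.
#' @param model a [sex_model()].
#' @param max_attempts bound on rejection sampling per parent when a sex
#'   constraint is set.
#' @return List of [mlg()] genotypes of length `spec$n_parents`.
#' @export
simulate_panel <- function(spec, seed, model = sex_model(), max_attempts = 10000) {
  set.seed(seed)
  out <- vector("list", spec$n_parents)
  for (i in seq_len(spec$n_parents)) {
    for (attempt in seq_len(max_attempts)) {
      g <- draw_genotype_once(spec, model)
      if (is.null(spec$sex_constraint) ||
          phenotype_of(g, model) == spec$sex_constraint) break
      if (attempt == max_attempts)
        stop("sex constraint '", spec$sex_constraint,
             "' unsatisfiable at the given frequencies after ",
             max_attempts, " attempts", call. = FALSE)
    }
    out[[i]] <- g
  }
  out
}

#' Define a linked-marker map anchored to a model locus
#'
#' @param markers data frame with columns `marker`, `chrom`, `pos`
#'   (1-based; strictly increasing within a chromosome).
#' @param anchor list: `locus` (model locus name), `chrom`, `pos` - the
#'   chromosome carrying that locus and its physical position.
#' @param cm_per_mb genetic-to-physical scale (default 3.5 cM/Mb).
#' @return A `marker_map`; recombination fractions to the anchor follow the
#'   Haldane (no-interference) map function.
#' @export
marker_map <- function(markers, anchor = list(locus = "LG6", chrom = "Fvb6", pos = 35142280),
                       cm_per_mb = 3.5) {
  stopifnot(all(c("marker", "chrom", "pos") %in% names(markers)))
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing on ", ch, call. = FALSE)
  }
  structure(list(markers = markers, anchor = anchor, cm_per_mb = cm_per_mb),
            class = "marker_map")
}

#' Haldane map function: physical distance to recombination fraction
#' @param bp physical distance in base pairs.
#' @param cm_per_mb map scale.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(bp, cm_per_mb = 3.5) {
  morgans <- abs(bp) / 1e6 * cm_per_mb / 100
  0.5 * (1 - exp(-2 * morgans))
}

map_recomb_fractions <- function(map) {
  ifelse(map$markers$chrom == map$anchor$chrom,
         haldane_r(map$markers$pos - map$anchor$pos, map$cm_per_mb),
         0.5)
}

#' Specify a single cross to simulate
#'
#' @param dam,sire parental [mlg()] genotypes; pass the same object for a
#'   self (same plant, same marker phase).
#' @param n number of zygotes to produce (survivors of viability selection
#'   are returned, so output size can be smaller).
#' @param family_id family label; also keys the per-family random substream.
#' @param rules list of [viability_rule()]s applied before phenotyping.
#' @param dropout probability that an individual is lost before phenotyping
#'   (germination/phenotyping failure).
#' @param missing_rate i.i.d. probability that a single marker call is
#'   missing.
#' @return A `cross_spec`.
#' @export
cross_spec <- function(dam, sire, n, family_id = "fam1", rules = list(),
                       dropout = 0, missing_rate = 0.05) {
  stopifnot(n >= 0, dropout >= 0, dropout <= 1, missing_rate >= 0, missing_rate <= 1)
  structure(list(dam = dam, sire = sire, n = n, family_id = family_id,
                 rules = rules, dropout = dropout, missing_rate = missing_rate),
            class = "cross_spec")
}

# Random phase for a parent: two marker haplotypes, each aligned with one of
# the parent's two alleles at the anchored locus.  Marker alleles are drawn
# as biallelic SNPs; heterozygous markers get a random phase.
random_parent_phase <- function(map, het_prob = 1) {
  n <- nrow(map$markers)
  snp_alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * n, replace = TRUE), ncol = 2)
  # force distinct allele symbols per marker
  same <- snp_alleles[, 1] == snp_alleles[, 2]
  snp_alleles[same, 2] <- vapply(snp_alleles[same, 1], function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
  het <- stats::runif(n) < het_prob
  hap1 <- ifelse(stats::runif(n) < 0.5, snp_alleles[, 1], snp_alleles[, 2])
  hap2 <- ifelse(het, ifelse(hap1 == snp_alleles[, 1], snp_alleles[, 2],
                             snp_alleles[, 1]), hap1)
  rbind(hap1, hap2)
}

# One gamete from a parent: independent assortment at model loci; markers on
# the anchored chromosome follow the anchored-locus allele's haplotype,
# switching with the per-marker Haldane recombination fraction.
parent_gamete <- function(g, phase, rfrac, model) {
  alleles <- vapply(names(model$loci), function(nm) {
    pair <- g$genotype[[nm]]
    pair[sample.int(2, 1)]
  }, "")
  anchor_locus <- attr(phase, "anchor_locus")
  pair <- g$genotype[[anchor_locus]]
  hap_idx <- sample.int(2, 1)
  alleles[anchor_locus] <- pair[hap_idx]
  marker_alleles <- vapply(seq_along(rfrac), function(j) {
    idx <- if (stats::runif(1) < rfrac[j]) 3 - hap_idx else hap_idx
    phase[idx, j]
  }, "")
  list(alleles = alleles, markers = marker_alleles)
}

#' Simulate one cross with linked markers
#'
#' Model loci assort independently; markers on the anchored chromosome
#' recombine with the anchored locus at the Haldane fraction implied by
#' their physical distance; the cytotype is copied from the dam; viability
#' rules are applied before output; missing marker calls are inserted
#' i.i.d.
#'
#' @param spec a [cross_spec()].
#' @param map a [marker_map()] (or `NULL` for no markers).
#' @param seed master seed (the family substream is derived from it and the
#'   family id).
#' @param model a [sex_model()].
#' @param dam_phase,sire_phase optional fixed 2 x n_marker haplotype
#'   matrices; randomised (and recorded in the result attributes) when
#'   omitted. For a self (dam identical to sire) one shared phase is used.
#' @return A data frame of progeny records: `id`, `family`, genotype token
#'   per locus, `cytotype`, `sex`, then one call column per marker.
#' @export
simulate_cross <- function(spec, map = NULL, seed = 1, model = sex_model(),
                           dam_phase = NULL, sire_phase = NULL) {
  set.seed(derive_seed(seed, spec$family_id))
  n_mark <- if (is.null(map)) 0 else nrow(map$markers)
  rfrac <- if (is.null(map)) numeric() else map_recomb_fractions(map)
  anchor_locus <- if (is.null(map)) names(model$loci)[1] else map$anchor$locus
  is_self <- identical(geno_key(spec$dam), geno_key(spec$sire)) &&
    identical(spec$dam$cytotype$label, spec$sire$cytotype$label)
  if (n_mark > 0) {
    if (is.null(dam_phase)) dam_phase <- random_parent_phase(map)
    if (is.null(sire_phase)) sire_phase <- if (is_self) dam_phase else random_parent_phase(map)
    attr(dam_phase, "anchor_locus") <- anchor_locus
    attr(sire_phase, "anchor_locus") <- anchor_locus
  } else {
    dam_phase <- sire_phase <- structure(matrix(character(), 2, 0),
                                         anchor_locus = anchor_locus)
  }
  recs <- list()
  for (k in seq_len(spec$n)) {
    gd <- parent_gamete(spec$dam, dam_phase, rfrac, model)
    gs <- parent_gamete(spec$sire, sire_phase, rfrac, model)
    gt <- lapply(names(model$loci), function(nm)
      canonical_pair(c(gd$alleles[[nm]], gs$alleles[[nm]]), model$loci[[nm]]))
    names(gt) <- names(model$loci)
    surv <- survival_of(gt, spec$rules, model)
    if (stats::runif(1) >= rat_value(surv)) next
    if (spec$dropout > 0 && stats::runif(1) < spec$dropout) next
    g <- structure(list(genotype = gt, cytotype = spec$dam$cytotype),
                   class = "multilocus_genotype")
    calls <- character(n_mark)
    if (n_mark > 0) {
      pair_mat <- rbind(gd$markers, gs$markers)
      calls <- vapply(seq_len(n_mark), function(j) {
        a <- sort(pair_mat[, j])
        if (a[1] == a[2]) a[1] else paste(a, collapse = "/")
      }, "")
      miss <- stats::runif(n_mark) < spec$missing_rate
      calls[miss] <- "."
    }
    rec <- c(list(id = sprintf("%s_%04d", spec$family_id, k),
                  family = spec$family_id),
             stats::setNames(lapply(gt, paste0, collapse = ""), names(model$loci)),
             list(cytotype = spec$dam$cytotype$label,
                  sex = phenotype_of(g, model)))
    if (n_mark > 0) rec <- c(rec, stats::setNames(as.list(calls), map$markers$marker))
    recs[[length(recs) + 1]] <- as.data.frame(rec, stringsAsFactors = FALSE,
                                              check.names = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else {
    cols <- c("id", "family", names(model$loci), "cytotype", "sex",
              if (n_mark > 0) map$markers$marker)
    stats::setNames(as.data.frame(matrix(character(), 0, length(cols)),
                                  stringsAsFactors = FALSE), cols)
  }
  attr(out, "dam_phase") <- dam_phase
  attr(out, "sire_phase") <- sire_phase
  out
}

#' Convert simulated progeny records into a marker matrix
#' @param progeny a [simulate_cross()] result (with marker columns).
#' @param map the [marker_map()] used.
#' @return A `marker_matrix` as from [read_marker_matrix()].
#' @export
progeny_to_marker_matrix <- function(progeny, map) {
  calls <- as.matrix(progeny[, map$markers$marker, drop = FALSE])
  structure(list(markers = data.frame(marker = map$markers$marker,
                                      chrom = map$markers$chrom,
                                      pos = map$markers$pos,
                                      stringsAsFactors = FALSE),
                 calls = calls, sex = progeny$sex, family = progeny$family,
                 id = progeny$id, design = "selfed_f2"),
            class = "marker_matrix")
}

#' Emit cross-table and marker-matrix fixture files from simulated families
#'
#' @param families named list of [simulate_cross()] results; names are
#'   family ids.
#' @param specs named list of the matching [cross_spec()]s (for dam/sire
#'   labels); optional.
#' @param cross_path,marker_path output TSV paths.
#' @param map the [marker_map()] used (needed when marker columns exist).
#' @return Invisibly, the two paths. Files round-trip losslessly through
#'   [read_cross_table()] / [read_marker_matrix()].
#' @export
emit_fixture_tables <- function(families, specs = NULL,
                                cross_path = "crosses.tsv",
                                marker_path = "markers.tsv", map = NULL) {
  cross_rows <- lapply(names(families), function(fid) {
    fam <- families[[fid]]
    sp <- if (!is.null(specs)) specs[[fid]] else NULL
    data.frame(
      cross_type = if (!is.null(sp) &&
                       identical(geno_key(sp$dam), geno_key(sp$sire))) "H-SELF" else "CROSS",
      dam = if (!is.null(sp)) geno_key(sp$dam) else paste0(fid, "_dam"),
      sire = if (!is.null(sp)) geno_key(sp$sire) else paste0(fid, "_sire"),
      n_female = sum(fam$sex == SEX_FEMALE),
      n_herm = sum(fam$sex == SEX_HERM),
      stringsAsFactors = FALSE)
  })
  header_only <- !length(cross_rows)
  ct <- if (header_only) {
    data.frame(cross_type = character(), dam = character(), sire = character(),
               n_female = integer(), n_herm = integer())
  } else do.call(rbind, cross_rows)
  write_cross_table(ct, cross_path)
  if (!is.null(map)) {
    all_prog <- if (header_only) NULL else do.call(rbind, unname(families))
    df <- if (is.null(all_prog)) {
      stats::setNames(as.data.frame(matrix(character(), 0, 3 + nrow(map$markers))),
                      c("id", "family", "sex", map$markers$marker))
    } else {
      cbind(all_prog[, c("id", "family", "sex")],
            all_prog[, map$markers$marker, drop = FALSE])
    }
    utils::write.table(df, marker_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(cross_path, marker_path))
}
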