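# Joint inference of parental three-locus genotypes from a crossing
# design's progeny sex ratios. The published analysis reasons cross by
# cross; here the same logic is formalised as joint maximum likelihood: the
# likelihood of a full assignment is the product over informative families
# of the binomial probability of the observed female/hermaphrodite counts
# at the model-predicted female fraction, with per-cross chi-square
# diagnostics. Ties are enumerated and reported, never broken silently.

#' Enumerate genotype hypotheses for one parent
#'
#' Hermaphrodites cannot carry the dominant sterility allele and cannot be
#' homozygous sterile at either restorer-type locus, so their space is
#' mfmf x \{RR, Rr\} x \{TT, Tt\}. Females are any genotype the model
#' phenotypes FEMALE; MS homozygotes are excluded by default (under the
#' model MS transmits only maternally, so MSMS is unreachable from any
#' hermaphrodite sire). User constraints intersect the set.
#'
#' @param sex `"F"` or `"H"`.
#' @param cytotype a [cytotype()] or mitotype label (CMS assumed).
#' @param constraints optional named list of fixed genotype tokens, e.g.
#'   `list(LG4 = "mfmf")`.
#' @param include_ms_hom also allow the MSMS class for females.
#' @param model a [sex_model()].
#' @return List of [mlg()] genotypes (possibly empty -> error).
#' @export
enumerate_parent_hypotheses <- function(sex, cytotype = "C", constraints = NULL,
                                        include_ms_hom = FALSE,
                                        model = sex_model()) {
  stopifnot(sex %in% c(SEX_FEMALE, SEX_HERM))
  if (is.character(cytotype)) cytotype <- cytotype(cytotype)
  per_locus <- lapply(names(model$loci), function(nm) {
    al <- model$loci[[nm]]$alleles
    classes <- c(paste0(al[1], al[1]), paste0(al[1], al[2]), paste0(al[2], al[2]))
    if (nm == "LG4" && !include_ms_hom) classes <- classes[-1]
    if (!is.null(constraints) && !is.null(constraints[[nm]])) {
      want <- paste0(parse_genotype_token(constraints[[nm]], model$loci[[nm]]),
                     collapse = "")
      classes <- intersect(classes, want)
    }
    classes
  })
  names(per_locus) <- names(model$loci)
  grid <- expand.grid(per_locus, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    g <- mlg(unlist(grid[i, ]), cytotype = cytotype, model = model)
    if (phenotype_of(g, model) == sex) out[[length(out) + 1]] <- g
  }
  if (!length(out))
    stop("no genotype hypothesis is consistent with the phenotype and constraints",
         call. = FALSE)
  out
}

#' Lethality preset: interpopulation families sired by the biased sire
#'
#' The female-biased 2:1 interpopulation families share one sire; the
#' lethality hypothesis is that half of the Rr progeny class of those
#' families dies. The preset bundles the viability rule with a predicate
#' selecting the crosses it applies to.
#'
#' @param sire_id sire whose interpopulation families are affected
#'   (default `"MRD93"`, the study's biased sire).
#' @param survival survival of the Rr class in affected families.
#' @param interpopulation_only apply only when dam and sire populations
#'   differ.
#' @return A `lethality_preset`: list with `rules` and
#'   `applies(dam_id, sire_id, dam_pop, sire_pop)`.
#' @export
lethality_preset <- function(sire_id = "MRD93", survival = 0.5,
                             interpopulation_only = TRUE) {
  rules <- rr_lethality_rules(survival)
  force(sire_id); force(interpopulation_only)
  structure(list(
    name = sprintf("half of Rr progeny die in %s-sired%s families", sire_id,
                   if (interpopulation_only) " interpopulation" else ""),
    rules = rules,
    applies = function(dam, sire, dam_pop, sire_pop) {
      sire == sire_id && (!interpopulation_only ||
                            (!is.na(dam_pop) && !is.na(sire_pop) && dam_pop != sire_pop))
    }
  ), class = "lethality_preset")
}

rules_for_cross <- function(preset, dam, sire, dam_pop, sire_pop) {
  if (is.null(preset)) return(list())
  if (preset$applies(dam, sire, dam_pop, sire_pop)) preset$rules else list()
}

# Cached exact female fraction for a genotype pair under a rule set.
female_fraction_cached <- function(dam, sire, rules, model, cache) {
  key <- paste(geno_key(dam), geno_key(sire), length(rules), sep = "|")
  val <- cache[[key]]
  if (is.null(val)) {
    val <- rat_value(female_fraction(dam, sire, rules, model))
    cache[[key]] <- val
  }
  val
}

adjust_fraction <- function(p, epsilon) p * (1 - epsilon) + (1 - p) * epsilon

#' Score one full genotype assignment against a cross table
#'
#' Joint log-likelihood = sum over informative families (n >= `n_min`) of
#' the binomial log-probability of the observed counts at the
#' model-predicted female fraction; plus per-family chi-square diagnostics.
#' The anomaly tolerance `epsilon` is a phenotype misclassification
#' probability mixed into the predicted fraction so that a single anomalous
#' female in an all-hermaphrodite family does not zero the likelihood; set
#' it to 0 for strict mode.
#'
#' @param assignment named list/vector: parent id -> genotype token string
#'   (`"mfmf Rr TT"`) or [mlg()].
#' @param crosses cross-table data frame ([read_cross_table()]).
#' @param panel parent panel data frame (for populations and mitotypes).
#' @param preset optional [lethality_preset()].
#' @param n_min minimum family size for inclusion.
#' @param epsilon anomaly tolerance (default 0.01).
#' @param model a [sex_model()].
#' @return List: `loglik`, `per_cross` data frame (predicted fraction,
#'   chi-square p), `excluded` (row indices below `n_min`).
#' @export
score_assignment <- function(assignment, crosses, panel, preset = NULL,
                             n_min = 10, epsilon = 0.01, model = sex_model()) {
  cyto_of <- stats::setNames(panel$mitotype, panel$id)
  pop_of <- stats::setNames(panel$population, panel$id)
  as_geno <- function(id) {
    g <- assignment[[id]]
    if (is.null(g)) stop("parent ", id, " not assigned")
    if (inherits(g, "multilocus_genotype")) return(g)
    mlg(strsplit(g, " ", fixed = TRUE)[[1]],
        cytotype = cytotype(cyto_of[[id]]), model = model)
  }
  cache <- new.env(parent = emptyenv())
  n <- crosses$n_female + crosses$n_herm
  excluded <- which(n < n_min)
  ll <- 0
  rows <- list()
  for (i in seq_len(nrow(crosses))) {
    if (n[i] < n_min) next
    dam <- as_geno(crosses$dam[i])
    sire <- as_geno(crosses$sire[i])
    rules <- rules_for_cross(preset, crosses$dam[i], crosses$sire[i],
                             pop_of[crosses$dam[i]], pop_of[crosses$sire[i]])
    p <- female_fraction_cached(dam, sire, rules, model, cache)
    p_adj <- adjust_fraction(p, epsilon)
    ll_i <- stats::dbinom(crosses$n_female[i], n[i], p_adj, log = TRUE)
    ll <- ll + ll_i
    res <- if (p == 0 || p == 1) {
      exact_zero_class_test(c(crosses$n_female[i], crosses$n_herm[i]),
                            ratio_hypothesis(if (p == 0) "0:1" else "1:0", p))
    } else {
      chisq_gof(c(crosses$n_female[i], crosses$n_herm[i]),
                ratio_hypothesis(sprintf("%.4g", p), as_rational(p)),
                n_min = n_min)
    }
    rows[[length(rows) + 1]] <- data.frame(
      dam = crosses$dam[i], sire = crosses$sire[i],
      n_female = crosses$n_female[i], n_herm = crosses$n_herm[i],
      predicted_female_fraction = p, loglik = ll_i,
      chisq = res$statistic, p_value = res$p_value,
      stringsAsFactors = FALSE)
  }
  list(loglik = ll,
       per_cross = if (length(rows)) do.call(rbind, rows) else NULL,
       excluded = excluded)
}

# Union-find over parent ids for connected components of the design.
design_components <- function(ids, dam, sire) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(dam)) {
    a <- find(match(dam[k], ids))
    b <- find(match(sire[k], ids))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(ids), find, 0)
  split(ids, roots)
}

#' Jointly infer parental genotypes from a crossing design
#'
#' Exhaustive branch-and-bound search over the per-parent hypothesis
#' product within each connected component of the design, maximising the
#' joint binomial log-likelihood of all informative families. All
#' assignments tied (within `tie_tol`) with the maximum are returned; ties
#' are surfaced, not broken. When a [lethality_preset()] is supplied the
#' design is also scored without it so both model fits can be compared.
#'
#' @param panel parent panel data frame: `id`, `population`, `sex`,
#'   `mitotype` (see [read_parent_panel()]).
#' @param crosses cross-table data frame (see [read_cross_table()]).
#' @param preset optional [lethality_preset()].
#' @param constraints optional named list: parent id -> named list of fixed
#'   genotype tokens.
#' @param n_min minimum family size for likelihood inclusion and
#'   chi-square diagnostics (default 10, the study's rule).
#' @param alpha significance level for flagging badly fitting families.
#' @param epsilon anomaly (phenotype misclassification) tolerance.
#' @param tie_tol log-likelihood tolerance within which assignments count
#'   as tied.
#' @param max_ties cap on enumerated tied assignments per component.
#' @param max_product cap on the hypothesis-product size of a component
#'   (error above it, suggesting constraints).
#' @param model a [sex_model()].
#' @return A `fit_report`: `assignments` (list of named genotype-key
#'   vectors, all ML-tied), `loglik`, `loglik_no_preset` (when a preset was
#'   used), `per_parent_ties`, `per_cross` diagnostics for the first ML
#'   assignment, `failing_crosses` (p < alpha), `excluded_crosses`,
#'   `truncated` flag.
#' @export
infer_genotypes <- function(panel, crosses, preset = NULL, constraints = NULL,
                            n_min = 10, alpha = 0.05, epsilon = 0.01,
                            tie_tol = 1e-6, max_ties = 5000, max_product = 1e12,
                            model = sex_model()) {
  n <- crosses$n_female + crosses$n_herm
  informative <- crosses[n >= n_min, , drop = FALSE]
  unknown <- setdiff(unique(c(informative$dam, informative$sire)), panel$id)
  if (length(unknown))
    stop("cross table references parents absent from the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hyp <- lapply(seq_len(nrow(panel)), function(i) {
    enumerate_parent_hypotheses(panel$sex[i], cytotype(panel$mitotype[i]),
                                constraints = constraints[[panel$id[i]]],
                                model = model)
  })
  names(hyp) <- panel$id
  comps <- design_components(panel$id, informative$dam, informative$sire)
  pop_of <- stats::setNames(panel$population, panel$id)
  cache <- new.env(parent = emptyenv())

  solve_component <- function(ids, use_preset) {
    cr <- informative[informative$dam %in% ids & informative$sire %in% ids, ,
                      drop = FALSE]
    if (prod(vapply(hyp[ids], length, 0L)) > max_product)
      stop("hypothesis product too large for component; supply genotype constraints",
           call. = FALSE)
    # order parents by decreasing progeny total so the search is pinned early
    weight <- vapply(ids, function(id)
      sum(cr$n_female[cr$dam == id | cr$sire == id] +
            cr$n_herm[cr$dam == id | cr$sire == id]), 0)
    ids <- ids[order(-weight)]
    k <- length(ids)
    keep_h <- lapply(hyp[ids], function(h) seq_along(h))  # surviving hyp indices
    di <- match(cr$dam, ids)
    si <- match(cr$sire, ids)
    build_table <- function(ci) {
      rules <- rules_for_cross(if (use_preset) preset else NULL,
                               cr$dam[ci], cr$sire[ci],
                               pop_of[cr$dam[ci]], pop_of[cr$sire[ci]])
      hd <- hyp[[cr$dam[ci]]][keep_h[[di[ci]]]]
      hs <- hyp[[cr$sire[ci]]][keep_h[[si[ci]]]]
      tab <- matrix(-Inf, length(hd), length(hs))
      for (a in seq_along(hd)) {
        for (b in seq_along(hs)) {
          if (di[ci] == si[ci] && a != b) next  # self: diagonal only
          p <- female_fraction_cached(hd[[a]], hs[[b]], rules, model, cache)
          tab[a, b] <- stats::dbinom(cr$n_female[ci],
                                     cr$n_female[ci] + cr$n_herm[ci],
                                     adjust_fraction(p, epsilon), log = TRUE)
        }
      }
      tab
    }
    tables <- lapply(seq_len(nrow(cr)), build_table)

    # dominance pruning: drop hypothesis h1 of a parent when another h2 is
    # pointwise at least as good in every cross against every counterpart
    # and strictly better by more than tie_tol however the counterparts are
    # assigned (so h1 can never enter the ML-tied set)
    oriented <- function(ci, pi) if (di[ci] == pi) tables[[ci]] else t(tables[[ci]])
    repeat {
      changed <- FALSE
      for (pi in seq_len(k)) {
        nh <- length(keep_h[[pi]])
        if (nh <= 1) next
        touching <- which(di == pi | si == pi)
        if (!length(touching)) next
        mats <- lapply(touching, function(ci) {
          # a self depends on this parent's hypothesis only: compare diagonals
          if (di[ci] == si[ci]) cbind(diag(tables[[ci]])) else oriented(ci, pi)
        })
        drop <- rep(FALSE, nh)
        for (h1 in seq_len(nh)) {
          if (drop[h1]) next
          for (h2 in seq_len(nh)) {
            if (h1 == h2 || drop[h2]) next
            le_all <- TRUE
            gap <- 0
            for (m in mats) {
              d <- m[h2, ] - m[h1, ]
              d[is.nan(d)] <- 0  # -Inf vs -Inf: equally impossible
              if (any(d < -1e-9)) { le_all <- FALSE; break }
              gap <- gap + min(d)
            }
            if (le_all && gap > tie_tol) { drop[h1] <- TRUE; break }
          }
        }
        if (any(drop)) {
          keep <- which(!drop)
          keep_h[[pi]] <- keep_h[[pi]][keep]
          for (ci in touching) {
            tables[[ci]] <- if (di[ci] == si[ci]) {
              tables[[ci]][keep, keep, drop = FALSE]
            } else if (di[ci] == pi) {
              tables[[ci]][keep, , drop = FALSE]
            } else {
              tables[[ci]][, keep, drop = FALSE]
            }
          }
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    sizes <- vapply(keep_h, length, 0L)

    eval_full <- function(idx) {
      s <- 0
      for (ci in seq_len(nrow(cr))) s <- s + tables[[ci]][idx[di[ci]], idx[si[ci]]]
      s
    }
    # coordinate-ascent warm start for a strong initial incumbent
    icm <- function() {
      idx <- vapply(seq_len(k), function(pi) {
        touching <- which(di == pi | si == pi)
        if (!length(touching)) return(1L)
        tot <- rep(0, sizes[pi])
        for (ci in touching) {
          m <- oriented(ci, pi)
          tot <- tot + apply(m, 1, max)
        }
        which.max(tot)
      }, 0L)
      for (sweep in 1:20) {
        moved <- FALSE
        for (pi in seq_len(k)) {
          touching <- which(di == pi | si == pi)
          if (!length(touching)) next
          tot <- rep(0, sizes[pi])
          for (ci in touching) {
            m <- oriented(ci, pi)
            other <- if (di[ci] == pi) si[ci] else di[ci]
            tot <- tot + if (di[ci] == si[ci]) diag(m) else m[, idx[other]]
          }
          h <- which.max(tot)
          if (h != idx[pi]) { idx[pi] <- h; moved <- TRUE }
        }
        if (!moved) break
      }
      idx
    }
    # per-cross optimistic values for the bound
    row_max <- lapply(tables, function(t) apply(t, 1, max))
    col_max <- lapply(tables, function(t) apply(t, 2, max))
    cross_max <- vapply(tables, max, 0)
    done_at <- pmax(di, si)
    by_level <- split(seq_len(nrow(cr)), factor(done_at, levels = seq_len(k)))

    icm_idx <- icm()
    best <- eval_full(icm_idx)
    ties <- list(icm_idx)
    truncated <- FALSE
    assign_idx <- integer(k)
    recurse <- function(level, ll) {
      if (level > k) {
        if (ll > best + tie_tol) {
          best <<- ll
          ties <<- list(assign_idx)
        } else if (ll >= best - tie_tol) {
          if (length(ties) < max_ties) ties[[length(ties) + 1]] <<- assign_idx
          else truncated <<- TRUE
        }
        return(invisible())
      }
      # exact contribution of crosses completed at this level, per candidate
      cand <- rep(ll, sizes[level])
      for (ci in by_level[[level]]) {
        cand <- cand + if (di[ci] == si[ci] && di[ci] == level) {
          diag(tables[[ci]])
        } else if (di[ci] == level && si[ci] == level) {
          diag(tables[[ci]])
        } else if (di[ci] == level) {
          tables[[ci]][, assign_idx[si[ci]]]
        } else {
          tables[[ci]][assign_idx[di[ci]], ]
        }
      }
      # optimistic bound for crosses still incomplete after this level
      bound <- rep(0, sizes[level])
      for (ci in seq_len(nrow(cr))) {
        if (done_at[ci] <= level) next
        fixed_d <- di[ci] < level
        fixed_s <- si[ci] < level
        bound <- bound + if (di[ci] == level) {
          row_max[[ci]]
        } else if (si[ci] == level) {
          col_max[[ci]]
        } else if (fixed_d) {
          row_max[[ci]][assign_idx[di[ci]]]
        } else if (fixed_s) {
          col_max[[ci]][assign_idx[si[ci]]]
        } else {
          cross_max[ci]
        }
      }
      score <- cand + bound
      ord <- order(-score)
      for (h in ord) {
        if (!(score[h] >= best - tie_tol)) break
        assign_idx[level] <<- h
        recurse(level + 1, cand[h])
      }
      invisible()
    }
    recurse(1, 0)
    # rescan: ties accumulated before the final best may fall outside the
    # tolerance of the eventual maximum; also dedupe the warm start
    tie_ll <- vapply(ties, eval_full, 0)
    ties <- ties[tie_ll >= best - tie_tol]
    ties <- unique(ties)
    assignments <- lapply(ties, function(idx) {
      stats::setNames(vapply(seq_len(k), function(i)
        geno_key(hyp[[ids[i]]][[keep_h[[i]][idx[i]]]]), ""), ids)
    })
    list(ids = ids, loglik = best, assignments = assignments, truncated = truncated)
  }

  use_preset <- !is.null(preset)
  sol <- lapply(comps, solve_component, use_preset = use_preset)
  loglik <- sum(vapply(sol, `[[`, 0, "loglik"))
  # cross-product of per-component tied assignments, capped
  assignments <- list(stats::setNames(character(0), character(0)))
  truncated <- any(vapply(sol, `[[`, TRUE, "truncated"))
  for (s in sol) {
    new <- list()
    for (a in assignments) {
      for (b in s$assignments) {
        if (length(new) >= max_ties) { truncated <- TRUE; break }
        new[[length(new) + 1]] <- c(a, b)
      }
      if (length(new) >= max_ties) break
    }
    assignments <- new
  }
  loglik_no_preset <- if (use_preset) {
    sum(vapply(lapply(comps, solve_component, use_preset = FALSE),
               `[[`, 0, "loglik"))
  } else NULL
  per_parent <- lapply(stats::setNames(panel$id, panel$id), function(id) {
    sort(unique(vapply(assignments, function(a) a[[id]], "")))
  })
  diag <- score_assignment(as.list(assignments[[1]]), crosses, panel,
                           preset = preset, n_min = n_min, epsilon = epsilon,
                           model = model)
  failing <- if (!is.null(diag$per_cross)) {
    diag$per_cross[!is.na(diag$per_cross$p_value) &
                     diag$per_cross$p_value < alpha, , drop = FALSE]
  } else NULL
  structure(list(assignments = assignments, loglik = loglik,
                 loglik_no_preset = loglik_no_preset,
                 preset = if (use_preset) preset$name else NULL,
                 per_parent_ties = per_parent,
                 per_cross = diag$per_cross,
                 failing_crosses = failing,
                 excluded_crosses = diag$excluded,
                 truncated = truncated),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Joint genotype inference\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  if (!is.null(x$loglik_no_preset))
    cat("  without lethality preset:", format(x$loglik_no_preset),
        " (preset: ", x$preset, ")\n", sep = "")
  cat("  ML-tied assignments:", length(x$assignments),
      if (x$truncated) "(truncated)" else "", "\n")
  best <- x$assignments[[1]]
  for (id in names(best)) {
    ties <- x$per_parent_ties[[id]]
    cat(sprintf("  %-8s %s%s\n", id, best[[id]],
                if (length(ties) > 1)
                  paste0("  [", length(ties), " tied: ",
                         paste(ties, collapse = "; "), "]") else ""))
  }
  if (!is.null(x$failing_crosses) && nrow(x$failing_crosses)) {
    cat("  families failing fit:",
        paste(paste0(x$failing_crosses$dam, "x", x$failing_crosses$sire),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an inferred-genotype table
#' @param report a `fit_report`.
#' @param panel the parent panel used.
#' @param path output TSV path.
#' @export
write_fit_report_table <- function(report, panel, path) {
  best <- report$assignments[[1]]
  toks <- do.call(rbind, strsplit(unname(best[panel$id]), " ", fixed = TRUE))
  df <- data.frame(id = panel$id, population = panel$population,
                   sex = panel$sex, mitotype = panel$mitotype,
                   LG4 = toks[, 1], LG6 = toks[, 2], LGx = toks[, 3],
                   n_tied = vapply(report$per_parent_ties[panel$id], length, 0L),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
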