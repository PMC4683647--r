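# Three-locus epistatic model of cyto-nuclear sex determination.
#
# The model carries three unlinked nuclear loci plus a maternally inherited
# cytotype:
#   * LG4 (MS/mf): a dominant male-sterility ("inhibitor") locus; a single
#     MS allele blocks restoration.
#   * LG6 (R/r): a dominant restorer-of-fertility locus; rr individuals are
#     male sterile.
#   * LGx (T/t): an unmapped locus; tt individuals are male sterile.
# A sterilising cytoplasm (CMS) is required for any of the nuclear routes to
# male sterility to be expressed: an individual is FEMALE iff its cytotype
# carries CMS and it (i) carries at least one MS, or (ii) is rr at LG6, or
# (iii) is tt at LGx; otherwise it is a HERMAPHRODITE.

SEX_FEMALE <- "F"
SEX_HERM <- "H"

#' Define a biallelic locus
#'
#' @param name locus identifier, e.g. `"LG6"`.
#' @param alleles character vector of exactly two allele symbols, dominant
#'   listed first (e.g. `c("R", "r")`).
#' @return A `locus` object.
#' @export
locus <- function(name, alleles) {
  stopifnot(is.character(name), nzchar(name), length(alleles) == 2)
  if (anyDuplicated(alleles)) stop("allele symbols must be unique within locus ", name)
  structure(list(name = name, alleles = alleles), class = "locus")
}

#' Default loci of the strawberry sex-determination model
#'
#' LG4 carries MS (dominant male sterility) over mf; LG6 carries R (dominant
#' restorer) over r; LGx carries T (fertility) over t.
#' @return Named list of [locus()] objects.
#' @export
default_loci <- function() {
  list(
    LG4 = locus("LG4", c("MS", "mf")),
    LG6 = locus("LG6", c("R", "r")),
    LGx = locus("LGx", c("T", "t"))
  )
}

#' Define a cytotype (mitochondrial haplotype class)
#'
#' @param label mitotype code, e.g. `"B"`, `"C"`, `"F"`.
#' @param cms_present does this cytoplasm carry a sterilising CMS factor?
#'   All mitotypes observed in the two study populations behave as
#'   CMS-carrying; a non-CMS cytoplasm phenotypes every nuclear genotype as
#'   hermaphrodite.
#' @param cms2_present optional second CMS factor, used only by the
#'   alternative phenotype rule in which LGx restores a second cytoplasm.
#' @return A `cytotype` object.
#' @export
cytotype <- function(label, cms_present = TRUE, cms2_present = FALSE) {
  stopifnot(is.character(label), nzchar(label))
  structure(list(label = label, cms_present = isTRUE(cms_present),
                 cms2_present = isTRUE(cms2_present)),
            class = "cytotype")
}

#' Default phenotype rule: one CMS, three nuclear sterility routes
#'
#' FEMALE iff the cytotype carries CMS and the nuclear genotype carries at
#' least one dominant sterility allele at LG4, or is homozygous recessive at
#' LG6, or homozygous recessive at LGx.
#' @return A function of a `multilocus_genotype` returning `"F"` or `"H"`.
#' @export
phenotype_rule_default <- function() {
  function(g) {
    cy <- g$cytotype
    if (!cy$cms_present) return(SEX_HERM)
    gt <- g$genotype
    if (any(gt$LG4 == "MS")) return(SEX_FEMALE)
    if (all(gt$LG6 == "r")) return(SEX_FEMALE)
    if (all(gt$LGx == "t")) return(SEX_FEMALE)
    SEX_HERM
  }
}

#' Alternative phenotype rule: LGx as restorer of a second CMS
#'
#' Under this variant T restores a second sterilising cytoplasm (flagged by
#' `cms2_present` on the cytotype) rather than acting in the primary CMS
#' pathway: FEMALE iff (CMS1 and (MS or rr)) or (CMS2 and tt).
#' @return A phenotype rule function.
#' @export
phenotype_rule_second_cms <- function() {
  function(g) {
    cy <- g$cytotype
    gt <- g$genotype
    if (cy$cms_present &&
        (any(gt$LG4 == "MS") || all(gt$LG6 == "r"))) return(SEX_FEMALE)
    if (cy$cms2_present && all(gt$LGx == "t")) return(SEX_FEMALE)
    SEX_HERM
  }
}

#' Construct the sex-determination model
#'
#' @param loci named list of [locus()] objects; defaults to [default_loci()].
#' @param phenotype_rule a function mapping a `multilocus_genotype` to
#'   `"F"`/`"H"`; defaults to [phenotype_rule_default()].
#' @return A `sex_model` object.
#' @export
sex_model <- function(loci = default_loci(), phenotype_rule = phenotype_rule_default()) {
  stopifnot(is.list(loci), length(loci) >= 1, is.function(phenotype_rule))
  names(loci) <- vapply(loci, `[[`, "", "name")
  structure(list(loci = loci, phenotype_rule = phenotype_rule),
            class = "sex_model")
}

# Split a diploid genotype token such as "MSmf" or "Rr" into its two allele
# symbols for a given locus; canonical order is dominant first.
parse_genotype_token <- function(token, loc) {
  al <- loc$alleles
  for (i in seq_along(al)) {
    for (j in seq_along(al)) {
      if (paste0(al[i], al[j]) == token) {
        pair <- c(al[i], al[j])
        return(pair[order(match(pair, al))])
      }
    }
  }
  stop(sprintf("unknown allele symbol in genotype '%s' at locus %s (alleles: %s)",
               token, loc$name, paste(al, collapse = "/")),
       call. = FALSE)
}

canonical_pair <- function(pair, loc) pair[order(match(pair, loc$alleles))]

#' Construct a multilocus genotype
#'
#' @param ... one diploid genotype token per model locus, in the model's
#'   locus order or named by locus (e.g. `mlg("mfmf", "Rr", "TT")`).
#' @param cytotype a [cytotype()] object or a mitotype label (CMS assumed
#'   present).
#' @param model a [sex_model()].
#' @return A `multilocus_genotype` object.
#' @export
mlg <- function(..., cytotype = "C", model = sex_model()) {
  toks <- c(...)
  loci <- model$loci
  if (is.null(names(toks)) || !any(nzchar(names(toks)))) {
    if (length(toks) != length(loci))
      stop("expected one genotype token per locus (", length(loci), ")")
    names(toks) <- names(loci)
  }
  if (!setequal(names(toks), names(loci)))
    stop("genotype must cover all model loci: ", paste(names(loci), collapse = ", "))
  gt <- lapply(names(loci), function(nm) parse_genotype_token(toks[[nm]], loci[[nm]]))
  names(gt) <- names(loci)
  if (is.character(cytotype)) cytotype <- cytotype(cytotype)
  stopifnot(inherits(cytotype, "cytotype"))
  structure(list(genotype = gt, cytotype = cytotype), class = "multilocus_genotype")
}

#' Canonical string key for a multilocus genotype, e.g. `"mfmf Rr TT"`
#' @param g a `multilocus_genotype`.
#' @export
geno_key <- function(g) {
  paste(vapply(g$genotype, paste0, "", collapse = ""), collapse = " ")
}

#' @export
format.multilocus_genotype <- function(x, ...) {
  paste0(geno_key(x), " [", x$cytotype$label,
         if (x$cytotype$cms_present) "/CMS" else "", "]")
}

#' @export
print.multilocus_genotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Sex phenotype of a multilocus genotype
#'
#' @param g a [mlg()] genotype.
#' @param model a [sex_model()].
#' @return `"F"` (female) or `"H"` (hermaphrodite).
#' @examples
#' phenotype_of(mlg("MSmf", "RR", "TT", cytotype = "C"))  # "F"
#' phenotype_of(mlg("mfmf", "Rr", "TT", cytotype = "F"))  # "H"
#' @export
phenotype_of <- function(g, model = sex_model()) {
  stopifnot(inherits(g, "multilocus_genotype"))
  for (nm in names(model$loci)) {
    al <- model$loci[[nm]]$alleles
    bad <- setdiff(g$genotype[[nm]], al)
    if (length(bad))
      stop(sprintf("unknown allele symbol '%s' at locus %s", bad[1], nm),
           call. = FALSE)
  }
  model$phenotype_rule(g)
}

#' Exact gamete distribution of a genotype under independent assortment
#'
#' Model loci are unlinked, so a heterozygous locus contributes each allele
#' with probability exactly 1/2. Linked-marker gametes are handled by the
#' cross simulator, not here.
#'
#' @inheritParams phenotype_of
#' @return A data frame with one allele column per locus plus exact `num` /
#'   `den` probability columns; probabilities sum to exactly 1.
#' @export
gamete_distribution <- function(g, model = sex_model()) {
  per_locus <- lapply(names(model$loci), function(nm) {
    pair <- g$genotype[[nm]]
    if (pair[1] == pair[2]) {
      data.frame(allele = pair[1], num = 1, den = 1, stringsAsFactors = FALSE)
    } else {
      data.frame(allele = pair, num = c(1, 1), den = c(2, 2), stringsAsFactors = FALSE)
    }
  })
  names(per_locus) <- names(model$loci)
  out <- data.frame(num = 1, den = 1)
  for (nm in names(per_locus)) {
    pl <- per_locus[[nm]]
    idx <- expand.grid(a = seq_len(nrow(out)), b = seq_len(nrow(pl)))
    new <- out[idx$a, , drop = FALSE]
    new[[nm]] <- pl$allele[idx$b]
    new$num <- new$num * pl$num[idx$b]
    new$den <- new$den * pl$den[idx$b]
    out <- new
  }
  rownames(out) <- NULL
  out[, c(names(model$loci), "num", "den")]
}

#' Define a viability rule
#'
#' A rule matches genotypes by per-locus diploid genotype class
#' (conjunctively over the named loci) and assigns a survival probability.
#' Rules are applied before phenotyping; genotypes matched by no rule
#' survive with probability 1.
#'
#' @param when named list of genotype tokens, e.g. `list(LG6 = "Rr")`.
#' @param survival survival probability in `[0, 1]` (rationalised exactly).
#' @return A `viability_rule` object.
#' @export
viability_rule <- function(when, survival) {
  s <- as_rational(survival)
  sv <- rat_num(s) / rat_den(s)
  if (sv < 0 || sv > 1) stop("survival must be in [0, 1]")
  stopifnot(is.list(when), length(when) >= 1, !is.null(names(when)))
  structure(list(when = when, survival = s), class = "viability_rule")
}

rule_matches <- function(rule, gt, model) {
  for (nm in names(rule$when)) {
    loc <- model$loci[[nm]]
    if (is.null(loc)) stop("viability rule names unknown locus ", nm)
    want <- parse_genotype_token(rule$when[[nm]], loc)
    if (!identical(unname(canonical_pair(gt[[nm]], loc)), unname(want)))
      return(FALSE)
  }
  TRUE
}

survival_of <- function(gt, rules, model) {
  s <- rat(1)
  for (rule in rules) {
    if (rule_matches(rule, gt, model)) s <- rat_mul(s, rule$survival)
  }
  s
}

#' Exact progeny genotype-and-phenotype distribution of a cross
#'
#' Combines the parental gamete distributions under independent assortment,
#' applies viability rules, renormalises among survivors, and phenotypes
#' each surviving genotype class. The cytoplasm is inherited from the dam
#' only.
#'
#' @param dam,sire [mlg()] genotypes (use the same object twice for a self).
#' @param rules list of [viability_rule()]s (default none).
#' @param model a [sex_model()].
#' @return A data frame with one genotype-token column per locus, a
#'   `phenotype` column, and exact `num`/`den` probability columns summing
#'   to exactly 1.
#' @export
progeny_distribution <- function(dam, sire, rules = list(), model = sex_model()) {
  gd <- gamete_distribution(dam, model)
  gs <- gamete_distribution(sire, model)
  loci <- model$loci
  classes <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(gd))) {
    for (j in seq_len(nrow(gs))) {
      gt <- lapply(names(loci), function(nm) {
        canonical_pair(c(gd[[nm]][i], gs[[nm]][j]), loci[[nm]])
      })
      names(gt) <- names(loci)
      p <- rat_mul(rat(gd$num[i], gd$den[i]), rat(gs$num[j], gs$den[j]))
      p <- rat_mul(p, survival_of(gt, rules, model))
      if (rat_num(p) == 0) next
      key <- paste(vapply(gt, paste0, "", collapse = ""), collapse = " ")
      if (is.null(classes[[key]])) {
        classes[[key]] <- list(gt = gt, p = p)
      } else {
        classes[[key]]$p <- rat_add(classes[[key]]$p, p)
      }
    }
  }
  keys <- ls(classes)
  if (!length(keys)) stop("no viable progeny class", call. = FALSE)
  total <- rat(0)
  for (k in keys) total <- rat_add(total, classes[[k]]$p)
  rows <- lapply(keys, function(k) {
    cl <- classes[[k]]
    p <- rat_div(cl$p, total)
    g <- structure(list(genotype = cl$gt, cytotype = dam$cytotype),
                   class = "multilocus_genotype")
    toks <- vapply(cl$gt, paste0, "", collapse = "")
    out <- as.list(toks)
    out$phenotype <- phenotype_of(g, model)
    out$num <- rat_num(p)
    out$den <- rat_den(p)
    out
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df[order(df[[1]], df[[2]], df[[3]]), , drop = FALSE]
}

#' Exact female fraction of a cross
#'
#' @inheritParams progeny_distribution
#' @return A `rat` rational: P(FEMALE) among surviving progeny.
#' @export
female_fraction <- function(dam, sire, rules = list(), model = sex_model()) {
  pd <- progeny_distribution(dam, sire, rules, model)
  f <- rat(0)
  for (i in which(pd$phenotype == SEX_FEMALE)) {
    f <- rat_add(f, rat(pd$num[i], pd$den[i]))
  }
  f
}

#' Expected female:hermaphrodite ratio of a cross
#'
#' The hypothesised progeny sex ratio implied by a parental genotype pair
#' under the model, as a reduced integer pair (e.g. 1:3, 9:7, 2:1) plus the
#' exact female fraction.
#'
#' @inheritParams progeny_distribution
#' @return A `ratio_hypothesis`: list with `label` (e.g. `"1:3"`), integer
#'   `ratio = c(female, herm)`, exact `female` fraction (`rat`), and the
#'   generating genotype pair as `provenance`.
#' @export
expected_ratio <- function(dam, sire, rules = list(), model = sex_model()) {
  f <- female_fraction(dam, sire, rules, model)
  fr <- rat_num(f)
  hr <- rat_den(f) - rat_num(f)
  g <- max(.gcd2(fr, hr), 1)
  pair <- c(fr / g, hr / g)
  ratio_hypothesis(paste0(pair[1], ":", pair[2]), f,
                   provenance = list(dam = geno_key(dam), sire = geno_key(sire)))
}

#' Construct a ratio hypothesis
#'
#' @param label display label such as `"1:3"`.
#' @param female_fraction exact female fraction as a `rat` or a numeric in
#'   `[0, 1]` (rationalised).
#' @param provenance optional record of the genotype pair that generated the
#'   hypothesis.
#' @export
ratio_hypothesis <- function(label, female_fraction, provenance = NULL) {
  f <- as_rational(female_fraction)
  fv <- rat_num(f) / rat_den(f)
  if (fv < 0 || fv > 1) stop("female fraction must be in [0, 1]")
  structure(list(label = label, female = f, provenance = provenance),
            class = "ratio_hypothesis")
}

#' Parse a ratio label such as "1:3" into a ratio hypothesis
#' @param label character like `"1:3"` (female:hermaphrodite).
#' @export
ratio_from_label <- function(label) {
  parts <- as.numeric(strsplit(label, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2 || anyNA(parts)) stop("malformed ratio label: ", label)
  ratio_hypothesis(label, rat(parts[1], parts[1] + parts[2]))
}

#' @export
format.ratio_hypothesis <- function(x, ...) {
  paste0(x$label, " (female fraction ", format(x$female), ")")
}

#' @export
print.ratio_hypothesis <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Viability preset: half of the restorer-heterozygous progeny die
#'
#' Named preset for the lethality hypothesis raised by the female-biased
#' 2:1 families: an unlinked factor kills 25% of offspring, all of them Rr
#' hermaphrodites - equivalently, half of the Rr class of an rr x Rr cross.
#'
#' @param survival survival probability of the Rr class (default 1/2).
#' @return A list of one [viability_rule()].
#' @export
rr_lethality_rules <- function(survival = 0.5) {
  list(viability_rule(list(LG6 = "Rr"), survival))
}
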