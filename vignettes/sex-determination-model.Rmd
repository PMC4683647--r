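---
title: "A three-locus cyto-nuclear model of sex determination in gynodioecious strawberry"
author: "gynodet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-locus cyto-nuclear model of sex determination in gynodioecious strawberry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gynodet)
```

## The model

Gynodioecious populations contain females (male-sterile plants) alongside
hermaphrodites. In cyto-nuclear gynodioecy a mitochondrially encoded
cytoplasmic male sterility (CMS) factor disrupts pollen development and is
counteracted by dominant alleles at nuclear restorer-of-fertility (*Rf*)
loci. `gynodet` implements a three-locus epistatic model for diploid wild
strawberry:

* **LG4 (*MS*/*mf*)** — a dominant male-sterility locus. A single *MS*
  allele blocks restoration regardless of the genotype at the other loci
  (*MS* is dominant to *mf* and epistatically dominant to *R*).
* **LG6 (*R*/*r*)** — a restorer locus. One dominant *R* allele restores
  pollen fertility; *rr* plants are male sterile.
* **LG*x* (*T*/*t*)** — an unmapped third locus; *tt* plants are male
  sterile.
* **Cytotype** — maternally inherited. All mitotypes observed in the two
  study populations (B, C, F) behave as CMS-carrying; a non-CMS cytoplasm
  phenotypes every nuclear genotype as hermaphrodite.

The default phenotype rule is the disjunction

> FEMALE ⇔ CMS ∧ (*MS*– ∨ *rr* ∨ *tt*),

which reproduces every progeny ratio the crossing data exhibit (1:3, 1:1,
0:1, the 9:7 two-locus ratio, and the 2:1 ratio under viability
selection). The mechanism of LG*x* is genuinely open: it may be a second
restorer acting on a second CMS rather than an independent recessive
sterility locus. Both readings are available — the default rule treats it
as an independent recessive route, and `phenotype_rule_second_cms()`
gates *tt* on a second CMS flag of the cytotype — because the crossing
data alone cannot separate them; we default to the disjunction purely
because it needs no second cytoplasmic factor.

All segregation probabilities are computed in exact rational arithmetic
(numerator/denominator pairs), so `expected_ratio()` returns reduced
integer ratios like `1:3` or `7:16` bit-exactly; floating point enters
only in the statistics layer. Note the package prints ratios as
female:hermaphrodite throughout, so the classic "9:7" two-locus ratio
(hermaphrodite:female) appears as `7:9`.

```{r ratios}
self <- mlg("mfmf", "Rr", "Tt", cytotype = "F")
expected_ratio(self, self)
```

### Viability selection

Viability rules are genotype predicates with a survival probability,
applied before phenotyping and renormalised among survivors. The single
case the crossing data demand — the female-biased interpopulation
families, explainable by the death of half the *Rr* progeny class — is
shipped as `rr_lethality_rules()` and, bundled with the predicate
selecting the affected families (one specific sire, interpopulation
only), as `lethality_preset()`.

```{r lethality}
expected_ratio(mlg("mfmf", "rr", "TT", cytotype = "F"),
               mlg("mfmf", "Rr", "TT", cytotype = "B"),
               rr_lethality_rules())
```

## The synthetic-data generator

`simulate_panel()` draws parents under Hardy–Weinberg from per-locus
frequencies of the sterility-associated alleles; the shipped
`population_preset()`s use the parental allele counts reported for the
two study populations (southern: *r* at 9/12, *t* at 1/12, no *MS*, fixed
F mitotype; northern: *MS* at 3/12, *r* and *t* at 1/12, mitotypes 90% C
/ 10% B). `simulate_cross()` assorts the model loci independently,
copies the cytoplasm from the dam, applies viability rules before
phenotyping, and genotypes progeny at markers linked to an anchored model
locus, with recombination fractions from physical distance under the
Haldane (no-interference) map function at a configurable scale (default
3.5 cM/Mb, a typical plant genome-wide average; only relative distances
matter for the statistics tested). Missing marker calls are inserted
i.i.d. at a configurable rate (default 5%, emulating the scattered
missing Sanger calls in the real genotype tables, whose mechanism is
unrecorded). One master seed is combined with a stable hash of each
family id, so adding a family to a design never perturbs the others and
fixed inputs give byte-identical outputs.

What the generator does **not** emulate: genotyping error (missingness is
the only data corruption), cross-compatibility/seed-set variation (the
real design's empty families arise from low seed set; the generator
exposes only a dropout probability), marker interference (markers are
conditionally independent given the anchored locus), and multi-generation
pedigrees. Tests passing on simulated data therefore validate the
statistical machinery under a clean Mendelian world, not robustness to
genotyping artefacts.

## Statistics

Family sex ratios are tested with Pearson's chi-square against the
hypothesised ratio, **without** continuity correction and with df = 1 —
this is the convention that reproduces the published family statistics
(e.g. 1.42 for 17:36 vs 1:3, 14.33 for 0:43) — and the test is not
applied below 10 progeny (`n_min = 10`). Degenerate 0:1 hypotheses go
through an exact test: a perfect fit scores 0, and any observation in the
zero-probability class rejects exactly and is flagged as an anomaly.
Marker–sex association uses the two-sided Fisher exact test
(minimum-likelihood rule for two-sidedness, the convention of
`stats::fisher.test`; stated because two-sided conventions differ), with
perfect cosegregation flagged only at zero mismatches among non-missing
calls. No multiple-testing correction is applied, matching the original
analysis; `p.adjust` can of course be applied to any returned column.

## Joint genotype inference

The original analysis infers parental genotypes cross by cross with ad
hoc reasoning. `infer_genotypes()` formalises it: hypothesis spaces per
parent (hermaphrodites: *mfmf* × {*RR*, *Rr*} × {*TT*, *Tt*}, 4
genotypes; females: the 14 phenotype-consistent genotypes with *MSMS*
excluded, since under the model *MS* can only transmit maternally and so
can never reach homozygosity through a hermaphrodite sire), joint
log-likelihood as the sum of binomial log-probabilities of the observed
family counts at the model-predicted female fractions, and exhaustive
maximisation over the hypothesis product within each connected component
of the design. The search uses dominance pruning (a hypothesis is removed
only when an alternative is pointwise at least as good against every
possible counterpart and strictly better in total), a coordinate-ascent
warm start, and vectorised best-first branch-and-bound; exact ties (within
`tie_tol = 1e-6` log units) are enumerated and reported, never broken
silently. An anomaly tolerance `epsilon = 0.01` (a phenotype
misclassification probability mixed into predicted fractions) keeps one
anomalous female in an all-hermaphrodite family from zeroing the joint
likelihood; `epsilon = 0` restores strict mode. Families below `n_min`
progeny are excluded from both the likelihood and the chi-square
diagnostics, mirroring the published NA rule.

The lethality preset participates in model selection: the engine fits the
design with and without it and reports both log-likelihoods (on the
bundled data the preset improves the joint fit by ~8 log units, which is
the likelihood form of the published 2:1 argument).

Two behaviours of this formalisation deserve emphasis, both computed by
`analysis/03_infer_genotypes.R` and asserted in the test suite. First, 11
of the 12 published parental genotypes are exactly the joint
maximum-likelihood assignment. Second, for the one remaining parent — the
female dam whose families the original study itself flags as
female-skewed — joint ML prefers a restorer-heterozygous genotype by ~2.3
log-likelihood units over the published one, because a heterozygous dam
predicts a female fraction of 5/8 against heterozygous sires, which fits
the pooled 52:33 female excess of those families better than 1:1. The
package reports this honestly rather than forcing agreement: it is a
point where a single joint criterion and cross-by-cross reasoning
genuinely part ways, and the skew itself is unexplained in the source
data.

## LOD mapping and the cosegregation interval

Male sterility is coded as a recessive Mendelian trait (sterile *rr*,
fertile *R*–; a dominant coding is available for the LG4-style analysis).
For each codominant marker in a selfed F2 family, coupling-phase gametes
carry (marker, trait) combinations at frequencies {(1−r)/2, (1−r)/2, r/2,
r/2}; squaring through selfing and collapsing by trait dominance gives
the joint class probabilities, and LOD(r) is maximised over the grid
{0, 0.005, …, 0.5}, with phase resolved by maximising over both allele
assignments and missing calls dropped per marker. LOD(0.5) is identically
0 by construction. Perfect cosegregation of 8 homozygous-sterile and 33
carrier progeny gives the closed form 8·log₁₀4 + 33·log₁₀(4/3) ≈ 8.94;
the originally displayed peak of 8.8 was produced by linkage-map software
whose internals (and missing-data pattern) are not recoverable, so the
package's tests assert a lower bound at 8.8, not equality.

The candidate interval is the maximal run of markers with zero trait
mismatches at r = 0 containing the peak-LOD marker, bounded by the
nearest flanking markers with at least one mismatch; its length is the
simple position difference in Mb to three decimals (1-based coordinates
throughout). A mismatch tolerance knob exists for noisy data but defaults
to 0 ("perfect match" taken literally). The Sanger-typed family bundled
in the package bounds a 1.844 Mb interval with its own markers; the
capture-marker configuration, whose per-individual genotypes are not
published, is reconstructed synthetically (`synthetic_capture_family()`,
clearly labelled as such) from its documented summary — ten perfect
markers spanning 34,958,975–36,048,692, one female recombinant at the
upstream flank 34,839,229, one female and two hermaphrodites mismatching
at the downstream flank 36,607,138 — and yields the 1.768 Mb interval.

## Genome windows

`window_counts()` tiles each chromosome with non-overlapping windows
(default 1 Mb), half-open `[k·10⁶, (k+1)·10⁶)` in 0-based coordinates so
boundary genes are counted exactly once, assigns each gene by its start
coordinate (midpoint assignment is available; the original counting rule
is unstated and the choice affects boundary genes only), and keeps the
final partial window with density scaled by its true span, so counts
always sum to the class total. `call_clusters()` returns maximal runs of
windows at or above a density threshold, ranked by peak window count.
The real reference annotation is not redistributable here;
`synthetic_ppr_annotation()` builds a 7-chromosome, 225 Mb synthetic
annotation of 653 PPR genes laid out to reproduce the documented density
landscape (mean 2.9/Mb; 15 genes in the mapped interval, 12 in its
central window, 10 in the 0.5 Mb core; one denser cluster elsewhere),
so the windowing statistics can be exercised end to end.

## Problem sizes and numerical choices

The test suite and analysis scripts use: 500 simulated selfed families of
50 progeny for chi-square calibration (the rejection rate of the true 1:3
at α = 0.05 lands near the nominal 5%); 100 seeded six-parent diallels of
18 families (n = 50) for inference stress-testing; and simulated families
of 40–100 progeny for marker properties — sizes chosen to estimate the
relevant rates stably while keeping a full run in a few minutes. At n =
50 a selfed restorer heterozygote's 1:3-vs-9:7 contrast flips by sampling
noise in roughly 9% of families (P[Binom(50, 0.25) ≥ 17]), so strict
joint recovery of every generating genotype plateaus well below 1 in
panels with several heterozygous parents; the suite therefore asserts
the properties that are genuinely guaranteed — the search never returns
less than the generating assignment's likelihood, misses are always
strictly-better-fitting alternatives, and observationally equivalent
genotypes are returned as explicit ties.

Other defaults: LOD significance threshold 3; window size 1 Mb; anomaly
tolerance 0.01; branch-and-bound tie tolerance 1e-6 log units; rational
arithmetic reduces by GCD at every operation so denominators stay exact.

## Known limitations

* The model is diploid; the polyploid relatives' sex determination is out
  of scope.
* Fitness costs of restoration and frequency dynamics are not modelled —
  the package predicts cross outcomes, not population trajectories.
* The LG*x* locus is genetically unanchored; the package treats it as
  unlinked to everything, as the segregation data suggest but do not
  prove.
* Joint ML inference assumes families are independent binomial samples
  given parental genotypes; shared environment or seed-set biases across
  a dam's families would violate this.
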