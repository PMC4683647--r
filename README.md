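# gynodet

Genetic analysis of cyto-nuclear sex determination in gynodioecious wild
strawberry (*Fragaria vesca* subsp. *bracteata*), where females and
hermaphrodites coexist and sex is set by the interaction of a maternally
inherited cytoplasmic male sterility (CMS) factor with three unlinked
nuclear loci. The package is for geneticists analysing crossing designs
in gynodioecious (or similarly sex-polymorphic) plants: it predicts
progeny sex ratios from parental genotypes, tests observed ratios,
infers parental genotypes jointly from a whole crossing design, maps male
sterility as a binary trait in a single selfed family, and scans genome
annotations for restorer-candidate (pentatricopeptide repeat, PPR) gene
clusters.

## The model

A plant is **female** iff its cytoplasm carries CMS and its nuclear
genotype provides any sterility route:

```
FEMALE  ⇔  CMS ∧ ( MS– ∨ rr ∨ tt )
```

* *MS/mf* (chromosome 4): dominant male sterility, epistatically dominant
  to the restorer;
* *R/r* (chromosome 6): dominant restorer of fertility — *rr* is male
  sterile;
* *T/t* (unmapped): *tt* is male sterile.

Segregation arithmetic is exact (rational probabilities), so predicted
ratios such as 1:3, 1:1, 0:1, the two-locus 9:7 and the 2:1 produced by
genotype-dependent lethality are reproduced bit-exactly. On top of the
model sit the statistics used on such designs: Pearson chi-square
goodness of fit (no continuity correction, df = 1, not applied below 10
progeny), exact tests for 0:1 families, two-sided Fisher marker–sex
association with perfect-cosegregation flagging, joint
maximum-likelihood genotype inference with enumerated ties, two-point
LOD mapping of a recessive binary trait in a selfed F2, cosegregation
interval calling, and windowed gene-class density scans.

## Worked example

```r
library(gynodet)

# a restorer-heterozygous hermaphrodite selfed: expect 1 female : 3 herm
het <- mlg("mfmf", "Rr", "TT", cytotype = "F")
expected_ratio(het, het)
#> 1:3 (female fraction 1/4)

# a double heterozygote selfed gives the classic two-locus ratio
dhet <- mlg("mfmf", "Rr", "Tt", cytotype = "F")
expected_ratio(dhet, dhet)
#> 7:9 (female fraction 7/16)

# observed 17 females : 36 hermaphrodites vs 1:3
chisq_gof(c(17, 36), "1:3")
#> chi2 = 1.4151, df = 1, p = 0.2342

# two-point LOD of the perfectly cosegregating marker in the bundled
# 41-progeny selfed mapping family (8 females, 33 hermaphrodites)
res <- two_point_lod(mapping_family_fixture(), "Fvb6_35142280")
c(lod = res$max_lod, r_hat = res$r_hat)
#>      lod    r_hat
#> 8.939458 0.000000

# candidate interval between the nearest mismatching markers
ci <- cosegregation_interval(synthetic_capture_family())
ci$length_mb
#> [1] 1.768
```

The LOD of 8.94 is the closed form 8·log10(4) + 33·log10(4/3) for perfect
cosegregation in a selfed F2; the 1.768 Mb interval is the span between
the mismatching flank markers at positions 34,839,229 and 36,607,138.

## The analysis workflow

Numbered scripts under `analysis/` run the full pipeline over the bundled
crossing table (71 families), parent panel (12 plants) and mapping-family
genotypes, writing tab-separated tables and JSON under `results/`:

1. `01_simulate.R` — panels and crosses from the population presets;
   chi-square calibration of 500 simulated selfed families.
2. `02_segregation_tests.R` — every family tested against its published
   expected ratio; the statistics known to be irreproducible as printed
   are flagged, not matched.
3. `03_infer_genotypes.R` — joint ML genotype inference with and without
   the Rr-lethality preset; comparison to the published assignments
   (11/12 agree; the disagreement is analysed in the vignette).
4. `04_lod_mapping.R` — LOD profile and cosegregation intervals.
5. `05_ppr_windows.R` — PPR density windows and cluster ranking.

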