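#!/usr/bin/env Rscript

# Stage 3: joint maximum-likelihood inference of the 12 parental
# three-locus genotypes from the crossing table, with and without the
# Rr-lethality preset, compared with the published assignments.
# Outputs: results/inferred_genotypes.tsv, results/fit_report.json

suppressPackageStartupMessages(library(gynodet))
dir.create("results", showWarnings = FALSE)

panel <- parent_panel_fixture()
crosses <- crossing_table_fixture()

message("Joint inference over ", nrow(panel), " parents and ",
        sum(crosses$n_female + crosses$n_herm >= 10), " informative families ...")
rep <- infer_genotypes(panel, crosses, preset = lethality_preset())
print(rep)

tab <- write_fit_report_table(rep, panel,
                              file.path("results", "inferred_genotypes.tsv"))
reported <- paste(panel$LG4, panel$LG6, panel$LGx)
tab$published <- reported
tab$matches_published <- paste(tab$LG4, tab$LG6, tab$LGx) == reported
utils::write.table(tab, file.path("results", "inferred_genotypes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sum(tab$matches_published), " of ", nrow(tab),
        " maximum-likelihood genotypes match the published assignment.")
mism <- tab$id[!tab$matches_published]
if (length(mism)) {
  message("Disagreement at: ", paste(mism, collapse = ", "),
          " - the dam whose families the study itself flags as",
          " female-skewed; the published genotype sits ",
          sprintf("%.1f", rep$loglik -
                    score_assignment(as.list(stats::setNames(reported, panel$id)),
                                     crosses, panel,
                                     preset = lethality_preset())$loglik),
          " log-likelihood units below the maximum.")
}
message("Lethality preset improves the joint fit by ",
        sprintf("%.1f", rep$loglik - rep$loglik_no_preset),
        " log-likelihood units over the no-lethality model.")

jsonlite::write_json(
  list(loglik = rep$loglik,
       loglik_no_preset = rep$loglik_no_preset,
       preset = rep$preset,
       n_tied_assignments = length(rep$assignments),
       assignments = lapply(rep$assignments, as.list),
       excluded_crosses = rep$excluded_crosses),
  file.path("results", "fit_report.json"), auto_unbox = TRUE, digits = 8)
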