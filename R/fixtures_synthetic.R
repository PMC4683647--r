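# Synthetic reconstructions of data objects whose full contents are not
# printed in the study's tables, built in code so that the documented
# summary statistics hold exactly.

#' Synthetic capture-marker matrix for the selfed mapping family
#'
#' The capture genotypes of the 41-progeny selfed mapping family are not
#' printed marker-by-marker; only their summary is: ten targeted-sequence
#' markers between positions 34,958,975 and 36,048,692 on Fvb6 match male
#' sterility perfectly, the nearest mismatching markers flank them at
#' 34,839,229 (where a single female mismatches) and 36,607,138 (one
#' female and two hermaphrodites mismatch). This generator reconstructs a
#' synthetic family with exactly that configuration: 8 females homozygous
#' for the coupling allele and 33 hermaphrodite carriers (22 heterozygous,
#' 11 homozygous for the alternate allele) at every perfect marker, with
#' the stated recombinants at the two flanks.
#'
#' @return A `marker_matrix` (see [read_marker_matrix()]).
#' @export
synthetic_capture_family <- function() {
  perfect_pos <- round(seq(34958975, 36048692, length.out = 10))
  pos <- c(34839229, perfect_pos, 36607138)
  markers <- data.frame(marker = paste0("Fvb6_", pos), chrom = "Fvb6",
                        pos = pos, stringsAsFactors = FALSE)
  sex <- c(rep(SEX_FEMALE, 8), rep(SEX_HERM, 33))
  # coupling allele G homozygous in females; carriers het or hom-T
  perfect_col <- c(rep("G", 8), rep("G/T", 22), rep("T", 11))
  calls <- matrix(rep(perfect_col, nrow(markers)), ncol = nrow(markers))
  # upstream flank: one female recombinant (heterozygous)
  calls[8, 1] <- "G/T"
  # downstream flank: one female and two hermaphrodites mismatch
  calls[1, ncol(calls)] <- "G/T"
  calls[9:10, ncol(calls)] <- "G"
  colnames(calls) <- markers$marker
  structure(list(markers = markers, calls = calls, sex = sex,
                 family = rep("capture_family", 41),
                 id = sprintf("cap_%02d", 1:41),
                 design = "selfed_f2"),
            class = "marker_matrix")
}
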