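# File dialects: cross-table TSV, marker-matrix TSV, parent-panel TSV,
# assembly tables, GFF3 annotations and YAML run configuration. All tabular
# dialects are tab-separated (allele tokens contain "/"); marker ids encode
# chromosome and 1-based position as <chrom>_<pos>, parsed on the final
# underscore.

#' Read a cross table (one row per dam x sire family)
#'
#' Expected columns: `cross_type`, `dam`, `sire`, `n_female`, `n_herm`.
#' Rows with zero progeny (families that yielded no seed or none
#' germinated) are kept and flagged in the `zero_progeny` column.
#'
#' @param path TSV file path.
#' @return A data frame of validated cross records.
#' @export
read_cross_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("cross_type", "dam", "sire", "n_female", "n_herm")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cross table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("n_female", "n_herm")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] != round(df[[col]]))
    if (length(bad))
      stop("non-integer ", col, " in ", path, " at line(s) ",
           paste(bad + 1, collapse = ", "), call. = FALSE)
    df[[col]] <- as.integer(df[[col]])
  }
  key <- paste(df$cross_type, df$dam, df$sire)
  if (anyDuplicated(key))
    stop("duplicate (cross_type, dam, sire) rows in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  df$zero_progeny <- (df$n_female + df$n_herm) == 0
  df
}

#' Write a cross table TSV
#' @param crosses cross-table data frame.
#' @param path output path.
#' @export
write_cross_table <- function(crosses, path) {
  cols <- c("cross_type", "dam", "sire", "n_female", "n_herm")
  utils::write.table(crosses[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

parse_marker_id <- function(id) {
  pos <- regmatches(id, regexpr("_[0-9]+$", id))
  if (!length(pos))
    stop("marker id '", id, "' does not end in _<position>", call. = FALSE)
  list(chrom = sub("_[0-9]+$", "", id),
       pos = as.numeric(sub("^_", "", pos)))
}

#' Read a marker genotype matrix
#'
#' Rows are individuals; columns `id`, `family`, `sex`, then one column per
#' marker. Marker column names embed chromosome and 1-based position
#' (`Fvb6_35142280`). Diploid calls are written `"G/T"` (heterozygote,
#' unordered), `"T"` (homozygote) or `"."` (missing).
#'
#' @param path TSV file path.
#' @param design family design label, `"selfed_f2"` (default) or
#'   `"outcross"`.
#' @return A `marker_matrix`: list with `markers` (data frame id, chrom,
#'   pos), `calls` (character matrix individuals x markers), `sex`,
#'   `family`, `id`, `design`.
#' @export
read_marker_matrix <- function(path, design = "selfed_f2") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("id", "family", "sex"), names(df))
  if (!"sex" %in% meta_cols)
    stop("marker matrix ", path, " needs a 'sex' column", call. = FALSE)
  marker_ids <- setdiff(names(df), meta_cols)
  if (!length(marker_ids)) stop("marker matrix ", path, " has no marker columns")
  info <- lapply(marker_ids, parse_marker_id)
  markers <- data.frame(marker = marker_ids,
                        chrom = vapply(info, `[[`, "", "chrom"),
                        pos = vapply(info, `[[`, 0, "pos"),
                        stringsAsFactors = FALSE)
  calls <- as.matrix(df[, marker_ids, drop = FALSE])
  calls[is.na(calls) | calls == ""] <- "."
  for (j in seq_along(marker_ids)) {
    ok <- grepl("^\\.$|^[A-Za-z]+$|^[A-Za-z]+/[A-Za-z]+$", calls[, j])
    if (!all(ok))
      stop(sprintf("malformed genotype call '%s' at row %d, marker %s in %s",
                   calls[which(!ok)[1], j], which(!ok)[1], marker_ids[j], path),
           call. = FALSE)
  }
  structure(list(
    markers = markers,
    calls = calls,
    sex = df$sex,
    family = if ("family" %in% meta_cols) df$family else rep(NA_character_, nrow(df)),
    id = if ("id" %in% meta_cols) df$id else paste0("ind", seq_len(nrow(df))),
    design = design
  ), class = "marker_matrix")
}

#' Write a marker genotype matrix TSV
#' @param matrix a `marker_matrix`.
#' @param path output path.
#' @export
write_marker_matrix <- function(matrix, path) {
  df <- data.frame(id = matrix$id, family = matrix$family, sex = matrix$sex,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(nrow(matrix$markers))) {
    df[[matrix$markers$marker[j]]] <- matrix$calls[, j]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse one diploid call token into its (unordered) allele pair
#' @param call a token like `"G/T"`, `"T"` or `"."`.
#' @return Character vector of 2 alleles, or `NULL` for missing.
#' @export
parse_call <- function(call) {
  if (is.na(call) || call == ".") return(NULL)
  parts <- strsplit(call, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(c(parts, parts))
  if (length(parts) == 2) return(sort(parts))
  stop("malformed call token: ", call)
}

#' Read a parent panel TSV
#'
#' Columns: `id`, `population`, `sex` (F/H), `mitotype`; optional
#' per-locus constraint columns (`LG4`, `LG6`, `LGx`) giving known genotype
#' tokens (empty = unconstrained).
#'
#' @param path TSV file path.
#' @return Data frame of parents.
#' @export
read_parent_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "population", "sex", "mitotype")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("parent panel ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate parent ids in ", path, call. = FALSE)
  df
}

#' Read a gene annotation track from GFF3
#'
#' Keeps records of the given type and extracts a gene class label from an
#' attribute key (e.g. `gene_class=PPR` or a free-text `Note`).
#'
#' @param path GFF3 file path.
#' @param type feature type to keep (default `"gene"`).
#' @param class_attribute attribute key holding the class label (default
#'   `"gene_class"`).
#' @return Data frame: `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `class` (1-based inclusive coordinates).
#' @export
read_gene_annotation <- function(path, type = "gene", class_attribute = "gene_class") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == type]
  cls <- if (class_attribute %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)[[class_attribute]])
  } else rep(NA_character_, length(gr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = if ("ID" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$ID) else paste0("gene", seq_along(gr)),
    class = cls,
    stringsAsFactors = FALSE
  )
}

#' Read an assembly table (chromosome lengths)
#' @param path TSV with columns `chrom`, `length`.
#' @export
read_assembly_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(df)))
    stop("assembly table needs columns chrom, length", call. = FALSE)
  df
}

#' Default analysis thresholds and seeds as a run configuration
#'
#' @param model_file optional YAML model file path.
#' @param seed master seed.
#' @param n_min family-size threshold below which ratio tests are not
#'   applied (the study's rule).
#' @param alpha significance level.
#' @param lod_threshold LOD significance threshold.
#' @param window_size genome-scan window in bp.
#' @param output_dir where stage outputs are written.
#' @param verbose logical.
#' @return A `run_config` list.
#' @export
run_config <- function(model_file = NULL, seed = 1L, n_min = 10L, alpha = 0.05,
                       lod_threshold = 3, window_size = 1e6,
                       output_dir = ".", verbose = TRUE) {
  stopifnot(n_min > 0, alpha > 0, lod_threshold > 0, window_size > 0)
  structure(list(model_file = model_file, seed = as.integer(seed),
                 n_min = as.integer(n_min), alpha = alpha,
                 lod_threshold = lod_threshold, window_size = window_size,
                 output_dir = output_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Path to a bundled data fixture
#' @param file fixture file name under `extdata/`.
#' @export
gynodet_extdata <- function(file) {
  p <- system.file("extdata", file, package = "gynodet", mustWork = TRUE)
  p
}

#' The published crossing table (progeny sex counts per family)
#'
#' 71 dam x sire families from the two study populations with female and
#' hermaphrodite progeny counts; families that yielded no scorable progeny
#' are kept with zero counts.
#' @return Cross-table data frame (see [read_cross_table()]).
#' @export
crossing_table_fixture <- function() {
  read_cross_table(gynodet_extdata("table1_crosses.tsv"))
}

#' The published parent panel (sex, mitotype and reported genotypes)
#' @return Parent panel data frame with the reported three-locus genotypes
#'   in columns `LG4`, `LG6`, `LGx`.
#' @export
parent_panel_fixture <- function() {
  read_parent_panel(gynodet_extdata("table3_parents.tsv"))
}

#' Sanger marker genotypes for the 41-progeny selfed mapping family
#'
#' Diploid calls at the segregating LG6-region positions for the 41 selfed
#' progeny of the mapped hermaphrodite (8 females, 33 hermaphrodites).
#' @return A `marker_matrix`.
#' @export
mapping_family_fixture <- function() {
  read_marker_matrix(gynodet_extdata("table2_mapping_family.tsv"))
}

#' Published per-family statistics (expected ratios and chi-squares)
#'
#' The printed expected female:hermaphrodite ratio and chi-square value for
#' each family of the crossing table, with two flag columns: the three
#' statistics known to be irreproducible from the printed counts, and the
#' two reciprocal families whose printed expected ratio cannot be derived
#' from the published parental genotypes.
#' @return Data frame keyed by (dam, sire).
#' @export
published_stats_fixture <- function() {
  utils::read.delim(gynodet_extdata("table1_published_stats.tsv"),
                    stringsAsFactors = FALSE)
}
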