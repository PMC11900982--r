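# Delimited-text I/O for feature tables and study designs.
#
# Schema (comma default): feature_id, annotation, formula, n_carbons,
# mz, rt, polarity, <sample...>; design: sample_id, group, replicate,
# biomass_mg_dna, volume_ml, timepoint_h.

.FEATURE_META <- c("feature_id", "annotation", "formula", "n_carbons",
                   "mz", "rt", "polarity")

#' Read a feature table
#'
#' Parses the delimited feature-table schema and validates it. Malformed
#' count cells (non-numeric or negative) are reported with their file
#' line numbers so upstream exports can be fixed.
#'
#' @param path file path.
#' @param sep field separator, `","` by default.
#' @return a [feature_matrix()].
#' @export
read_feature_table <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!"feature_id" %in% names(raw))
    stopf("%s: missing feature_id column", path)
  meta_cols <- intersect(.FEATURE_META, names(raw))
  sample_cols <- setdiff(names(raw), .FEATURE_META)
  if (!length(sample_cols)) stopf("%s: no sample columns found", path)
  counts <- matrix(NA_real_, nrow(raw), length(sample_cols),
                   dimnames = list(NULL, sample_cols))
  bad <- character(0)
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(raw[[sample_cols[j]]]))
    nonnum <- which(is.na(v) & nzchar(trimws(raw[[sample_cols[j]]])))
    neg <- which(!is.na(v) & v < 0)
    # +1 for the header row
    if (length(nonnum))
      bad <- c(bad, sprintf("line %d: non-numeric count '%s' in sample %s",
                            nonnum + 1L, raw[[sample_cols[j]]][nonnum],
                            sample_cols[j]))
    if (length(neg))
      bad <- c(bad, sprintf("line %d: negative count %s in sample %s",
                            neg + 1L, v[neg], sample_cols[j]))
    counts[, j] <- v
  }
  if (length(bad))
    stopf("%s: malformed rows:\n  %s", path, paste(bad, collapse = "\n  "))
  features <- raw[meta_cols]
  for (num in intersect(c("n_carbons", "mz", "rt"), names(features)))
    features[[num]] <- suppressWarnings(as.numeric(features[[num]]))
  if ("n_carbons" %in% names(features))
    features$n_carbons <- as.integer(features$n_carbons)
  feature_matrix(features, counts)
}

#' Write a feature table
#'
#' Inverse of [read_feature_table()]; the write/read round trip is
#' lossless for counts and metadata.
#'
#' @param matrix a [feature_matrix()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(matrix, path, sep = ",") {
  meta <- matrix$features[intersect(.FEATURE_META, names(matrix$features))]
  out <- cbind(meta, as.data.frame(matrix$counts, check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a study design table
#'
#' @param path file path to a delimited table with columns `sample_id`,
#'   `group`, `replicate`, `biomass_mg_dna`, `volume_ml`, `timepoint_h`.
#' @param sep field separator.
#' @return data.frame.
#' @export
read_study_design <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(d)))
    stopf("%s: design needs sample_id and group columns", path)
  d$sample_id <- as.character(d$sample_id)
  d
}

#' Write a study design table
#'
#' @param design data.frame as returned by [generate_study()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_study_design <- function(design, path, sep = ",") {
  utils::write.table(design, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
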