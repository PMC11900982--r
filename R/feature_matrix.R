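# The central LC-MS container: annotated features x samples ion counts.

#' Construct a feature matrix
#'
#' Bundles per-feature metadata (m/z, retention time, formula, carbon
#' count, polarity) with an ion-count matrix whose columns are samples.
#' This is the object every downstream stage (filtering, normalization,
#' differential tests, envelope extraction) consumes.
#'
#' @param features data.frame with at least `feature_id`; recognised
#'   optional columns are `annotation`, `formula`, `n_carbons`, `mz`,
#'   `rt`, `polarity`.
#' @param counts numeric matrix of non-negative ion counts, one row per
#'   feature (rownames = `feature_id`), one column per sample.
#' @return object of class `feature_matrix`: a list with elements
#'   `features` and `counts`, plus a `normalized` attribute used as an
#'   idempotence guard by [normalize_biomass()].
#' @export
feature_matrix <- function(features, counts) {
  if (!is.data.frame(features) || !"feature_id" %in% names(features))
    stopf("features must be a data.frame with a feature_id column")
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id))
    stopf("duplicate feature_id: %s",
          paste(unique(features$feature_id[duplicated(features$feature_id)]),
                collapse = ", "))
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != nrow(features))
    stopf("counts has %d rows but features has %d", nrow(counts),
          nrow(features))
  if (is.null(colnames(counts)))
    stopf("counts must have sample ids as column names")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample ids in counts")
  if (any(!is.finite(counts)))
    stopf("counts contain non-finite values")
  if (any(counts < 0))
    stopf("counts contain negative values (first offending feature: %s)",
          features$feature_id[which(rowSums(counts < 0) > 0)[1]])
  rownames(counts) <- features$feature_id
  for (opt in c("annotation", "formula", "n_carbons", "mz", "rt",
                "polarity"))
    if (!opt %in% names(features)) features[[opt]] <- NA
  structure(list(features = features, counts = counts),
            class = "feature_matrix", normalized = FALSE)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (isTRUE(attr(x, "normalized"))) " (biomass-normalized)"
              else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$counts)

sample_ids <- function(x) colnames(x$counts)

#' Subset a feature matrix
#'
#' @param x a [feature_matrix()].
#' @param features optional feature ids or logical/integer index.
#' @param samples optional sample ids or index.
#' @return a `feature_matrix` restricted to the requested rows/columns.
#' @export
fm_subset <- function(x, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(x$counts)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$counts)) else samples
  if (is.character(fi)) {
    miss <- setdiff(fi, x$features$feature_id)
    if (length(miss)) stopf("unknown feature_id: %s",
                            paste(miss, collapse = ", "))
    fi <- match(fi, x$features$feature_id)
  }
  out <- feature_matrix(x$features[fi, , drop = FALSE],
                        x$counts[fi, si, drop = FALSE])
  attr(out, "normalized") <- attr(x, "normalized")
  out
}

#' Validate a study design against a feature matrix
#'
#' Checks the 1:1 sample correspondence every statistical stage assumes.
#'
#' @param matrix a [feature_matrix()].
#' @param design data.frame with columns `sample_id`, `group`,
#'   `replicate` and optionally `biomass_mg_dna`, `volume_ml`,
#'   `timepoint_h`.
#' @return the design, invisibly, with `sample_id` as character.
#' @export
check_design <- function(matrix, design) {
  req <- c("sample_id", "group")
  if (!all(req %in% names(design)))
    stopf("design must contain columns: %s", paste(req, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id)) stopf("duplicate sample_id in design")
  missing <- setdiff(sample_ids(matrix), design$sample_id)
  extra <- setdiff(design$sample_id, sample_ids(matrix))
  if (length(missing)) stopf("design lacks samples: %s",
                             paste(missing, collapse = ", "))
  if (length(extra)) stopf("design has samples absent from matrix: %s",
                           paste(extra, collapse = ", "))
  invisible(design)
}

group_samples <- function(design, group) {
  ids <- design$sample_id[design$group == group]
  if (!length(ids)) stopf("group '%s' not present in design", group)
  as.character(ids)
}
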