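# Feature-table preprocessing: low-variance filtering, biomass
# normalization, and in-silico 1:1 extract mixtures.

#' Remove low-variance features
#'
#' Drops features whose across-sample dispersion falls below a threshold.
#' The default statistic is the relative standard deviation
#' (sd / mean, RSD), which removes features that are effectively constant
#' without biasing downstream differential tests; plain standard
#' deviation is available for tables whose scale is already meaningful.
#' Features with zero mean have an undefined RSD and are treated as
#' constant (RSD 0).
#'
#' @param matrix a [feature_matrix()].
#' @param method `"rsd"` (default) or `"sd"`.
#' @param threshold non-negative cutoff; features with statistic strictly
#'   below it are removed. Default 0.01.
#' @return the filtered `feature_matrix`; attribute `"removed"` holds a
#'   data.frame of dropped features with their statistic.
#' @export
filter_low_variance <- function(matrix, method = c("rsd", "sd"),
                                threshold = 0.01) {
  method <- match.arg(method)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0 ||
      !is.finite(threshold) && threshold != Inf)
    stopf("threshold must be a single value in [0, Inf)")
  if (ncol(matrix$counts) < 3)
    stopf("need at least 3 samples to estimate feature variance")
  s <- apply(matrix$counts, 1, stats::sd)
  stat <- switch(method,
    sd = s,
    rsd = {
      m <- rowMeans(matrix$counts)
      ifelse(m > 0, s / m, 0)
    })
  drop <- stat < threshold
  removed <- data.frame(feature_id = matrix$features$feature_id[drop],
                        statistic = unname(stat[drop]),
                        method = rep(method, sum(drop)),
                        stringsAsFactors = FALSE)
  out <- fm_subset(matrix, features = which(!drop))
  attr(out, "removed") <- removed
  out
}

#' Normalize ion counts to biomass
#'
#' Divides each sample's counts by that sample's biomass (mg DNA), the
#' normalization applied before any between-group pool comparison.
#' Samples without biomass (media-only / cell-free wells) pass through
#' unchanged with a notice. A guard flag refuses double normalization.
#'
#' @param matrix a [feature_matrix()].
#' @param design study design with `sample_id` and `biomass_mg_dna`.
#' @return normalized `feature_matrix` (counts per mg DNA), `normalized`
#'   attribute set.
#' @export
normalize_biomass <- function(matrix, design) {
  if (isTRUE(attr(matrix, "normalized")))
    stopf("matrix is already biomass-normalized")
  design <- check_design(matrix, design)
  if (!"biomass_mg_dna" %in% names(design))
    stopf("design lacks biomass_mg_dna")
  b <- design$biomass_mg_dna[match(sample_ids(matrix), design$sample_id)]
  if (any(!is.na(b) & b <= 0)) stopf("biomass must be > 0")
  passthrough <- is.na(b)
  if (any(passthrough))
    message(sprintf("normalize_biomass: %d media-only sample(s) without biomass passed through unchanged: %s",
                    sum(passthrough),
                    paste(sample_ids(matrix)[passthrough], collapse = ", ")))
  b[passthrough] <- 1
  out <- matrix
  out$counts <- sweep(matrix$counts, 2, b, "/")
  attr(out, "normalized") <- TRUE
  out
}

#' In-silico 1:1 extract mixture
#'
#' Emulates the analytical dilution control in which two groups' extracts
#' are combined 1:1 before injection: for equal-concentration extracts
#' the mixture equals the per-feature arithmetic mean of the paired
#' replicates. Pairing is by replicate index unless an explicit pairing
#' is given.
#'
#' @param matrix a [feature_matrix()].
#' @param design study design.
#' @param group_a,group_b the two contributing groups (e.g. `"HJ"`,
#'   `"SJ"`).
#' @param pairing optional two-column matrix/data.frame of sample ids
#'   (one row per mixture sample); required when replicate counts are
#'   unequal.
#' @param label group label for the mixture samples.
#' @return `feature_matrix` of mixture samples `<label>_k`.
#' @export
make_insilico_1T1 <- function(matrix, design, group_a, group_b,
                              pairing = NULL, label = "1T1-insilico") {
  design <- check_design(matrix, design)
  a <- group_samples(design, group_a)
  b <- group_samples(design, group_b)
  if (is.null(pairing)) {
    if (length(a) != length(b))
      stopf("groups %s (%d) and %s (%d) have unequal replicate counts; supply an explicit pairing",
            group_a, length(a), group_b, length(b))
    ra <- design$replicate[match(a, design$sample_id)]
    rb <- design$replicate[match(b, design$sample_id)]
    if (!any(is.na(ra)) && !any(is.na(rb))) {
      a <- a[order(ra)]
      b <- b[order(rb)]
    }
    pairing <- cbind(a, b)
  } else {
    pairing <- as.matrix(pairing)
    if (ncol(pairing) != 2) stopf("pairing must have two columns")
  }
  mix <- (matrix$counts[, pairing[, 1], drop = FALSE] +
          matrix$counts[, pairing[, 2], drop = FALSE]) / 2
  colnames(mix) <- sprintf("%s_%d", label, seq_len(nrow(pairing)))
  out <- feature_matrix(matrix$features, mix)
  attr(out, "normalized") <- attr(matrix, "normalized")
  attr(out, "group") <- label
  out
}

#' Append samples of one feature matrix to another
#'
#' Convenience for adding in-silico mixture samples (and their design
#' rows) to an existing study.
#'
#' @param matrix,extra two [feature_matrix()] objects over the same
#'   features.
#' @return combined `feature_matrix`.
#' @export
fm_cbind <- function(matrix, extra) {
  if (!identical(matrix$features$feature_id, extra$features$feature_id))
    stopf("feature sets differ")
  out <- feature_matrix(matrix$features, cbind(matrix$counts, extra$counts))
  attr(out, "normalized") <- attr(matrix, "normalized")
  out
}
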