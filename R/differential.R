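# Differential metabolite-pool analysis: group comparisons with BH
# correction, the 1T1 dilution-control test, and time-course fold
# changes against starting media.

#' Log2 fold change of group means
#'
#' `log2(mean(a) / mean(b))`. When either group mean is zero a
#' pseudo-count is added symmetrically to both means; with both means
#' zero the fold change is undefined (`NA`, flagged via attribute).
#'
#' @param values_a,values_b numeric count vectors.
#' @param pseudo pseudo-count applied when a mean is 0 (default 0:
#'   caller decides; [differential_table()] uses half the smallest
#'   nonzero count of the matrix).
#' @return log2 fold change (a over b).
#' @export
log2_fold_change <- function(values_a, values_b, pseudo = 0) {
  ma <- mean(values_a)
  mb <- mean(values_b)
  if (ma == 0 && mb == 0)
    return(structure(NA_real_, undefined = TRUE))
  if (ma == 0 || mb == 0) {
    ma <- ma + pseudo
    mb <- mb + pseudo
    if (ma == 0 || mb == 0)
      return(structure(NA_real_, undefined = TRUE))
  }
  log2(ma / mb)
}

#' Unpaired two-sample t-test
#'
#' Equal-variance Student t by default (the convention of common
#' point-and-click statistics software for unpaired tests); Welch by
#' flag. Degenerate zero-variance input is resolved by convention
#' rather than error: equal means give `p = 1`, unequal means `p = 0`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) test.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
unpaired_t_test <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stopf("each group needs n >= 2")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, df = length(values_a) + length(values_b) - 2,
                  p = 1, degenerate = TRUE))
    return(list(t = Inf * sign(mean(values_a) - mean(values_b)),
                df = length(values_a) + length(values_b) - 2, p = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

.direction <- function(log2_fc, sig) {
  ifelse(!sig | is.na(log2_fc), "nc", ifelse(log2_fc > 0, "up", "down"))
}

.diff_core <- function(matrix, sa, sb, comparison, welch = FALSE) {
  pseudo <- {
    nz <- matrix$counts[matrix$counts > 0]
    if (length(nz)) min(nz) / 2 else 0
  }
  fid <- matrix$features$feature_id
  res <- lapply(fid, function(f) {
    a <- matrix$counts[f, sa]
    b <- matrix$counts[f, sb]
    fc <- log2_fold_change(a, b, pseudo = pseudo)
    tt <- unpaired_t_test(a, b, welch = welch)
    data.frame(feature_id = f,
               annotation = matrix$features$annotation[
                 match(f, matrix$features$feature_id)],
               comparison = comparison,
               log2_fc = as.numeric(fc), p_raw = tt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Per-feature differential table with BH correction
#'
#' Computes per-feature log2 fold changes (group a over group b) on
#' group means, unpaired t-test p-values and BH-adjusted p-values, and
#' calls direction at the joint fold-change/significance criterion.
#'
#' @param matrix a [feature_matrix()] (normally biomass-normalized).
#' @param design study design.
#' @param group_a,group_b comparison groups (a over b, e.g. SJH vs HJ).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param fc_cut absolute log2 fold-change cut for calling direction
#'   (default 1, i.e. 2-fold).
#' @param welch use Welch's t-test.
#' @return data.frame `feature_id, annotation, comparison, log2_fc,
#'   p_raw, p_adj, direction`; attribute `"summary"` holds up/down
#'   counts, attribute `"meta"` the test settings.
#' @export
differential_table <- function(matrix, design, group_a, group_b,
                               alpha = 0.05, fc_cut = 1, welch = FALSE) {
  design <- check_design(matrix, design)
  sa <- group_samples(design, group_a)
  sb <- group_samples(design, group_b)
  if (length(sa) < 2 || length(sb) < 2)
    stopf("each group needs >= 2 replicates")
  res <- .diff_core(matrix, sa, sb,
                    sprintf("%s vs %s", group_a, group_b), welch = welch)
  res$p_adj <- bh_adjust(res$p_raw)
  sig <- res$p_adj < alpha & !is.na(res$log2_fc) & abs(res$log2_fc) >= fc_cut
  res$direction <- .direction(res$log2_fc, sig)
  attr(res, "summary") <- c(up = sum(res$direction == "up"),
                            down = sum(res$direction == "down"))
  attr(res, "meta") <- list(alpha = alpha, fc_cut = fc_cut,
                            welch = welch, p_basis = "BH-adjusted")
  res
}

#' Dilution-control comparison (SJH vs 1T1)
#'
#' Compares the co-culture group against the analytical (or in-silico)
#' 1:1 mixture of its constituent controls. Hits exceed what pool
#' dilution alone explains, so they flag candidate metabolic
#' interactions. By design this discovery screen uses raw p-values at a
#' low threshold, not BH-adjusted ones; the output metadata says so
#' explicitly.
#'
#' @param matrix a [feature_matrix()].
#' @param design study design.
#' @param group co-culture group of interest (default `"SJH"`).
#' @param dilution_group mixture group (default `"1T1"`).
#' @param alpha raw-p discovery threshold (default 0.05).
#' @param fc_cut absolute log2 fold-change cut for flagging (default 0:
#'   any significant deviation from the dilution expectation counts).
#' @param welch use Welch's t-test.
#' @return data.frame as [differential_table()] plus logical
#'   `exceeds_dilution`; `p_adj` is `NA` by design here.
#' @export
dilution_comparison <- function(matrix, design, group = "SJH",
                                dilution_group = "1T1", alpha = 0.05,
                                fc_cut = 0, welch = FALSE) {
  design <- check_design(matrix, design)
  if (!dilution_group %in% design$group)
    stopf("dilution group '%s' missing from design", dilution_group)
  sa <- group_samples(design, group)
  sb <- group_samples(design, dilution_group)
  res <- .diff_core(matrix, sa, sb,
                    sprintf("%s vs %s", group, dilution_group),
                    welch = welch)
  res$p_adj <- NA_real_
  sig <- res$p_raw < alpha & !is.na(res$log2_fc) & abs(res$log2_fc) >= fc_cut
  res$direction <- .direction(res$log2_fc, sig)
  res$exceeds_dilution <- sig
  attr(res, "meta") <- list(alpha = alpha, fc_cut = fc_cut,
                            p_basis = "raw (low-threshold discovery; no BH)")
  res
}

#' Time-course fold change versus starting media
#'
#' log2 fold change of each feature at `t_cmp` relative to `t_ref`
#' within one group, with BH-adjusted p-values. When a cell-free
#' degradation control group is supplied its own log2 drift is reported
#' as an additional, never silently substituted, drift-adjusted column.
#'
#' @param matrix a [feature_matrix()] of media measurements.
#' @param design design with `timepoint_h`.
#' @param group group to analyse.
#' @param t_ref,t_cmp reference / comparison timepoints in hours
#'   (default 0 and 24).
#' @param degradation_control optional group name of cell-free control
#'   wells.
#' @param alpha adjusted-p significance level.
#' @param fc_cut absolute log2 fold-change cut (default 0).
#' @return data.frame with `log2_fc`, `p_raw`, `p_adj`, `direction` and,
#'   when a control is given, `control_log2_drift` and
#'   `log2_fc_drift_adj` (= `log2_fc - control_log2_drift`).
#' @export
timecourse_fold_change <- function(matrix, design, group, t_ref = 0,
                                   t_cmp = 24, degradation_control = NULL,
                                   alpha = 0.05, fc_cut = 0) {
  design <- check_design(matrix, design)
  if (!"timepoint_h" %in% names(design))
    stopf("design lacks timepoint_h")
  pick <- function(g, t)
    design$sample_id[design$group == g & design$timepoint_h == t]
  s0 <- pick(group, t_ref)
  s1 <- pick(group, t_cmp)
  if (!length(s0)) stopf("no %s samples at t = %g h", group, t_ref)
  if (!length(s1)) stopf("no %s samples at t = %g h", group, t_cmp)
  if (any(rowMeans(matrix$counts[, s0, drop = FALSE]) == 0))
    stopf("zero reference (t0) mean for feature(s): %s",
          paste(matrix$features$feature_id[
            rowMeans(matrix$counts[, s0, drop = FALSE]) == 0],
            collapse = ", "))
  res <- .diff_core(matrix, s1, s0,
                    sprintf("T%g vs T%g [%s]", t_cmp, t_ref, group))
  res$p_adj <- bh_adjust(res$p_raw)
  sig <- res$p_adj < alpha & abs(res$log2_fc) >= fc_cut
  res$direction <- .direction(res$log2_fc, sig)
  if (!is.null(degradation_control)) {
    c0 <- pick(degradation_control, t_ref)
    c1 <- pick(degradation_control, t_cmp)
    if (!length(c0) || !length(c1))
      stopf("degradation control '%s' lacks t%g/t%g samples",
            degradation_control, t_ref, t_cmp)
    drift <- log2(rowMeans(matrix$counts[, c1, drop = FALSE]) /
                  rowMeans(matrix$counts[, c0, drop = FALSE]))
    res$control_log2_drift <- unname(drift[res$feature_id])
    res$log2_fc_drift_adj <- res$log2_fc - res$control_log2_drift
  }
  attr(res, "meta") <- list(alpha = alpha, fc_cut = fc_cut,
                            p_basis = "BH-adjusted",
                            degradation_control = degradation_control)
  res
}

#' Write a differential-result table
#'
#' @param result data.frame from the differential functions.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_differential <- function(result, path, sep = ",") {
  utils::write.table(result, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
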