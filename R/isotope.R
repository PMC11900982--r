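# Isotopologue envelopes, natural-abundance correction and MIDs.
#
# Heavy isotopologues sit at m/z shifts of k * 1.0033 Da. Natural 13C
# (1.11% of carbon) inflates observed envelopes; the lower-triangular
# binomial correction matrix maps true MIDs to observed envelopes and
# is inverted by non-negative least squares so corrected fractions can
# never go negative.

DELTA_MZ_13C <- 1.0033
NATURAL_13C <- 0.0111

#' Construct an isotopologue envelope
#'
#' @param metabolite metabolite id.
#' @param counts numeric matrix of ion counts, rows `M0..Mn`, columns
#'   samples (a vector is treated as a single sample).
#' @param mz_base m/z of the M+0 feature (optional).
#' @param code short metabolite code used in variable names (defaults to
#'   `metabolite`).
#' @param flags optional character notes (e.g. zero-filled members).
#' @return object of class `iso_envelope` with `n_carbons = nrow - 1`.
#' @export
iso_envelope <- function(metabolite, counts, mz_base = NA_real_,
                         code = metabolite, flags = character()) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = 1,
                     dimnames = list(NULL, "sample1"))
  n <- nrow(counts) - 1L
  if (n < 1) stopf("envelope needs at least M0 and M1 rows")
  if (any(counts < 0)) stopf("envelope counts must be non-negative")
  rownames(counts) <- paste0("M", 0:n)
  structure(list(metabolite = metabolite, code = code, n_carbons = n,
                 counts = counts, mz_base = mz_base,
                 delta_mz = DELTA_MZ_13C, flags = flags),
            class = "iso_envelope")
}

#' @export
print.iso_envelope <- function(x, ...) {
  cat(sprintf("<iso_envelope> %s: M0..M%d x %d sample(s)%s\n",
              x$metabolite, x$n_carbons, ncol(x$counts),
              if (length(x$flags)) paste0(" [", length(x$flags), " flag(s)]")
              else ""))
  invisible(x)
}

#' Extract an isotopologue envelope from a feature table
#'
#' For k = 0..n the feature nearest `mz_base + k * 1.0033` within the
#' ppm tolerance (and, when retention times are available, within an RT
#' window of the M+0 feature, since isotopologues co-elute) contributes
#' its counts. Missing members are zero-filled and flagged; a missing
#' M+0 is an error; two equally near candidates raise an ambiguity
#' error naming both.
#'
#' @param matrix a [feature_matrix()] with an `mz` column.
#' @param metabolite metabolite id for the envelope.
#' @param mz_base m/z of M+0.
#' @param n_carbons number of carbons n (envelope M+0..M+n).
#' @param ppm_tol match tolerance in ppm (default 5).
#' @param rt_window RT window in minutes around the M+0 feature
#'   (default 0.1; ignored when RT is absent).
#' @return an [iso_envelope()].
#' @export
extract_envelope <- function(matrix, metabolite, mz_base, n_carbons,
                             ppm_tol = 5, rt_window = 0.1) {
  if (ppm_tol < 0) stopf("ppm_tol must be >= 0")
  mz <- matrix$features$mz
  if (all(is.na(mz))) stopf("feature table has no m/z values")
  rt <- matrix$features$rt
  counts <- matrix(0, n_carbons + 1, ncol(matrix$counts),
                   dimnames = list(paste0("M", 0:n_carbons),
                                   colnames(matrix$counts)))
  flags <- character()
  rt0 <- NA_real_
  for (k in 0:n_carbons) {
    target <- mz_base + k * DELTA_MZ_13C
    tol_da <- ppm_tol * target / 1e6
    d <- abs(mz - target)
    cand <- which(!is.na(d) & d <= tol_da)
    if (!is.na(rt0) && length(cand) && any(!is.na(rt[cand])))
      cand <- cand[is.na(rt[cand]) | abs(rt[cand] - rt0) <= rt_window]
    if (!length(cand)) {
      if (k == 0)
        stopf("M+0 not found for %s at m/z %.4f (tol %g ppm)",
              metabolite, mz_base, ppm_tol)
      flags <- c(flags, sprintf("M+%d missing; zero-filled", k))
      next
    }
    best <- cand[order(d[cand])]
    if (length(best) > 1 && abs(d[best[1]] - d[best[2]]) < 1e-9)
      stopf("ambiguous M+%d for %s: features %s tie at m/z %.4f", k,
            metabolite,
            paste(matrix$features$feature_id[best[1:2]], collapse = " and "),
            target)
    hit <- best[1]
    if (k == 0 && !is.na(rt[hit])) rt0 <- rt[hit]
    counts[k + 1, ] <- matrix$counts[hit, ]
  }
  iso_envelope(metabolite, counts, mz_base = mz_base, flags = flags)
}

#' Binomial natural-abundance correction matrix
#'
#' Lower-triangular matrix with
#' `entries[i, j] = choose(n - j, i - j) p^(i-j) (1-p)^(n-i)` for
#' `i >= j` (zero-based): the probability that a molecule truly carrying
#' j tracer carbons is observed at M+i because `i - j` of its `n - j`
#' remaining carbons are naturally 13C. Columns are probability vectors.
#'
#' @param n_carbons number of carbons n (>= 1).
#' @param natural_p natural 13C fraction, in `[0, 0.5)`; default 0.0111.
#' @return list with `entries` ((n+1) x (n+1) matrix), `n_carbons`,
#'   `natural_p`; class `correction_matrix`.
#' @export
build_correction_matrix <- function(n_carbons, natural_p = NATURAL_13C) {
  if (n_carbons < 1) stopf("n_carbons must be >= 1")
  if (natural_p < 0 || natural_p >= 0.5)
    stopf("natural_p must lie in [0, 0.5)")
  n <- n_carbons
  C <- matrix(0, n + 1, n + 1,
              dimnames = list(paste0("M", 0:n), paste0("M", 0:n)))
  for (j in 0:n)
    C[(j:n) + 1, j + 1] <- stats::dbinom(0:(n - j), n - j, natural_p)
  structure(list(entries = C, n_carbons = n, natural_p = natural_p),
            class = "correction_matrix")
}

#' Correct an envelope for natural 13C abundance
#'
#' Solves `measured = C x` per sample by non-negative least squares and
#' renormalizes the solution to percentages. NNLS (rather than plain
#' matrix inversion) guarantees corrected fractions are never negative
#' on noisy envelopes.
#'
#' @param envelope an [iso_envelope()].
#' @param natural_p natural 13C fraction (default 0.0111; 0 makes the
#'   correction the identity on fractions).
#' @return object of class `mid`: list with `metabolite`, `fractions`
#'   ((n+1) x samples percent matrix summing to 100 per sample),
#'   `corrected = TRUE`, `natural_p`.
#' @export
correct_natural_abundance <- function(envelope, natural_p = NATURAL_13C) {
  stopifnot(inherits(envelope, "iso_envelope"))
  C <- build_correction_matrix(envelope$n_carbons, natural_p)$entries
  frac <- apply(envelope$counts, 2, function(y) {
    if (all(y == 0)) stopf("all-zero envelope for %s", envelope$metabolite)
    x <- pracma::lsqnonneg(C, y)$x
    if (sum(x) == 0) stopf("degenerate correction for %s",
                           envelope$metabolite)
    100 * x / sum(x)
  })
  frac <- matrix(frac, nrow = envelope$n_carbons + 1,
                 dimnames = dimnames(envelope$counts))
  structure(list(metabolite = envelope$metabolite, code = envelope$code,
                 fractions = frac, corrected = TRUE,
                 natural_p = natural_p),
            class = "mid")
}

#' Uncorrected MID fractions
#'
#' Expresses each isotopologue's ion counts as a percentage of the
#' metabolite's total pool (sum over the envelope), the 0-100 scale used
#' throughout; e.g. enrichment of S_M3 = counts(S_M3) / total serine
#' counts x 100.
#'
#' @param envelope an [iso_envelope()].
#' @return object of class `mid` with `corrected = FALSE`.
#' @export
mid_fractions <- function(envelope) {
  stopifnot(inherits(envelope, "iso_envelope"))
  tot <- colSums(envelope$counts)
  if (any(tot == 0))
    stopf("zero total counts for %s in sample(s): %s",
          envelope$metabolite,
          paste(colnames(envelope$counts)[tot == 0], collapse = ", "))
  structure(list(metabolite = envelope$metabolite, code = envelope$code,
                 fractions = sweep(envelope$counts, 2, tot, "/") * 100,
                 corrected = FALSE, natural_p = NA_real_),
            class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s: M0..M%d x %d sample(s), %scorrected\n",
              x$metabolite, nrow(x$fractions) - 1, ncol(x$fractions),
              if (isTRUE(x$corrected)) "" else "un"))
  invisible(x)
}

#' Total 13C enrichment
#'
#' Percentage of the metabolite pool carrying at least one tracer
#' carbon: `100 - M+0 fraction`.
#'
#' @param mid a corrected `mid` object (or a percent vector whose first
#'   entry is M+0).
#' @return per-sample enrichment percentages in `[0, 100]`.
#' @export
total_enrichment <- function(mid) {
  if (inherits(mid, "mid")) {
    if (!isTRUE(mid$corrected))
      warning("total enrichment computed from an uncorrected MID")
    return(100 - mid$fractions["M0", ])
  }
  100 - mid[1]
}

#' Write MID tables in long format
#'
#' Schema: `metabolite, sample, isotopologue, fraction_percent,
#' corrected`.
#'
#' @param mids a `mid` or list of `mid` objects.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_mid_table <- function(mids, path, sep = ",") {
  if (inherits(mids, "mid")) mids <- list(mids)
  long <- do.call(rbind, lapply(mids, function(m) {
    f <- m$fractions
    data.frame(metabolite = m$metabolite,
               sample = rep(colnames(f), each = nrow(f)),
               isotopologue = rep(rownames(f), ncol(f)),
               fraction_percent = as.numeric(f),
               corrected = isTRUE(m$corrected),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
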