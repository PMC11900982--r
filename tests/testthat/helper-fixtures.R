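# Shared fixtures and independent oracles, built in code at test time.

## tiny feature matrix with explicit values
tiny_fm <- function(counts = NULL, mz = NULL, rt = NULL) {
  if (is.null(counts))
    counts <- matrix(c(100, 300, 10, 20, 1000, 1000), nrow = 3,
                     byrow = TRUE, dimnames = list(NULL, c("s1", "s2")))
  nf <- nrow(counts)
  feature_matrix(
    data.frame(feature_id = paste0("f", seq_len(nf)),
               annotation = paste0("met", seq_len(nf)),
               mz = mz %||% (100 + seq_len(nf)),
               rt = rt %||% rep(5, nf),
               stringsAsFactors = FALSE),
    counts)
}

tiny_design <- function(groups, n = 3, biomass = 1) {
  data.frame(
    sample_id = unlist(lapply(groups, function(g) sprintf("%s_%d", g, 1:n))),
    group = rep(groups, each = n),
    replicate = rep(1:n, length(groups)),
    biomass_mg_dna = biomass,
    volume_ml = 1, timepoint_h = 24,
    stringsAsFactors = FALSE)
}

## independent brute-force BH step-up (kept free of stats::p.adjust)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1)
    for (k in (m - 1):1) adj[k] <- min(adj[k], adj[k + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## brute-force Pearson correlation from explicit sums
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## forward natural-abundance convolution, independent of the package's
## correction matrix (direct binomial sum)
convolve_mid_brute <- function(mid_percent, n, p) {
  obs <- numeric(n + 1)
  for (j in 0:n) {
    for (i in j:n) {
      obs[i + 1] <- obs[i + 1] +
        (mid_percent[j + 1] / 100) * choose(n - j, i - j) *
        p^(i - j) * (1 - p)^(n - i)
    }
  }
  obs
}

random_mid <- function(n) {
  x <- stats::runif(n + 1)
  100 * x / sum(x)
}
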