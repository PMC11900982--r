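# Discriminant ITUM: enrichment matrix assembly, PCA, loading-based
# selection, co-enrichment correlation, clustering and export.

make_mid_obj <- function(code, fractions, samples) {
  f <- matrix(rep(fractions, length(samples)), ncol = length(samples),
              dimnames = list(paste0("M", seq_along(fractions) - 1),
                              samples))
  structure(list(metabolite = code, code = code, fractions = f,
                 corrected = TRUE, natural_p = 0.0111), class = "mid")
}

test_that("enrichment matrix lays out one column per isotopologue", {
  design <- tiny_design(c("SJ", "SJH"), n = 2)
  samples <- design$sample_id
  mids <- list(make_mid_obj("S", c(60, 10, 10, 20), samples),
               make_mid_obj("M", c(50, 10, 10, 10, 20), samples))
  em <- build_enrichment_matrix(mids, design, groups = c("SJ", "SJH"))
  expect_equal(ncol(em), 4 + 5)
  expect_equal(unname(em["SJ_1", paste0("S_M", 0:3)]), c(60, 10, 10, 20))
  # per-metabolite closure: rows sum to 100 per metabolite
  expect_equal(unname(rowSums(em[, paste0("M_M", 0:4)])), rep(100, 4))
  # unenriched metabolite excluded by the SJH enrichment rule
  mids2 <- c(mids, list(make_mid_obj("Z", c(100, 0, 0), samples)))
  em2 <- build_enrichment_matrix(mids2, design, groups = c("SJ", "SJH"))
  expect_false(any(grepl("^Z_", colnames(em2))))
  # variable names parse back to metabolite and k
  pv <- parse_iso_variable(colnames(em))
  expect_equal(pv$code[1], "S")
  expect_equal(pv$k, c(0:3, 0:4))
  # uncorrected MIDs are refused
  bad <- mids
  bad[[1]]$corrected <- FALSE
  expect_error(build_enrichment_matrix(bad, design,
                                       groups = c("SJ", "SJH")),
               "not natural-abundance corrected")
})

test_that("PCA puts the discriminating variable on top of PC1", {
  # two groups differing only in X, all other variables noise-free
  # (constant): the constants drop and X carries all the loading
  x <- c(10, 10, 10, 20, 20, 20)
  em <- cbind(X = x, Y = 5, Z = 7)
  rownames(em) <- paste0("s", 1:6)
  expect_message(pc <- run_pca(em), "zero-variance")
  expect_equal(rownames(pc$loadings)[which.max(abs(pc$loadings[, 1]))],
               "X")
  # eigendecomposition oracle on a small case: loadings match the
  # eigenvectors of the correlation matrix up to sign
  set.seed(241)
  em3 <- matrix(rnorm(8 * 3), 8, dimnames = list(paste0("s", 1:8),
                                                 c("a", "b", "c")))
  pc3 <- run_pca(em3)
  ev <- eigen(cor(em3))$vectors
  for (j in 1:3)
    expect_equal(abs(unname(pc3$loadings[, j])), abs(ev[, j]),
                 tolerance = 1e-8)
  # duplicated variable: symmetric loadings on PC1
  y <- c(5, 5.2, 4.9, 5.1, 5.0, 5.05)
  em2 <- cbind(X1 = x + rnorm(6, 0, 0.05), Y = y)
  em2 <- cbind(em2, X2 = em2[, "X1"])
  pc2 <- run_pca(em2)
  expect_equal(abs(pc2$loadings["X1", 1]), abs(pc2$loadings["X2", 1]),
               tolerance = 1e-10)
  # standardize = FALSE on pre-z-scored data gives the identical result
  emz <- scale(em3)
  attr(emz, "scaled:center") <- attr(emz, "scaled:scale") <- NULL
  expect_equal(run_pca(emz, standardize = FALSE)$loadings,
               run_pca(emz, standardize = TRUE)$loadings,
               tolerance = 1e-10)
})

test_that("PCA satisfies reconstruction, orthonormality and variance order", {
  set.seed(201)
  em <- matrix(rnorm(9 * 12), 9, dimnames = list(paste0("s", 1:9),
                                                 paste0("v", 1:12)))
  pc <- run_pca(em)
  # orthonormal loadings
  expect_equal(crossprod(pc$loadings),
               diag(ncol(pc$loadings)), ignore_attr = TRUE,
               tolerance = 1e-8)
  # scores %*% t(loadings) reconstructs the standardized matrix
  expect_equal(pc$scores %*% t(pc$loadings), scale(em),
               ignore_attr = TRUE, tolerance = 1e-8)
  # explained variance fractions are non-increasing and sum <= 1
  ev <- pc$explained_variance_fraction
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-12)
  # zero-variance columns removed with a notice
  em0 <- cbind(em, const = 5)
  expect_message(pc0 <- run_pca(em0), "zero-variance")
  expect_false("const" %in% rownames(pc0$loadings))
  expect_error(run_pca(em, n_components = 100), "components")
})

test_that("loading-based selection honors top-k and quantile rules", {
  pca <- list(loadings = matrix(c(0.9, 0.1, 0.05), 3,
                                dimnames = list(c("a", "b", "c"), "PC1")))
  class(pca) <- "pca_result"
  expect_equal(as.character(select_discriminant(pca, rule = "top:1")), "a")
  expect_length(select_discriminant(pca, rule = "quantile:0"), 3)
  sel <- select_discriminant(pca, rule = "quantile:0.75")
  expect_equal(attr(sel, "rule"), "quantile:0.75")
  expect_error(select_discriminant(pca, component = 5), "component")
  expect_error(select_discriminant(pca, rule = "best:2"), "rule")
})

test_that("co-enrichment matrix matches brute-force Pearson and t-transform p", {
  set.seed(211)
  for (rep in 1:20) {
    em <- matrix(rnorm(8 * 5), 8, dimnames = list(paste0("s", 1:8),
                                                  paste0("v", 1:5)))
    net <- coenrichment_matrix(em, groups = NULL, design = NULL)
    for (i in 1:4) for (j in (i + 1):5) {
      r_bf <- pearson_brute(em[, i], em[, j])
      expect_equal(net$r[i, j], r_bf, tolerance = 1e-10)
      t_bf <- abs(r_bf) * sqrt(6 / (1 - r_bf^2))
      expect_equal(net$p[i, j], 2 * pt(-t_bf, 6), tolerance = 1e-10)
    }
  }
  expect_equal(unname(diag(net$r)), rep(1, 5))
})

test_that("labeling gradients anticorrelate M+0 with heavy isotopologues", {
  # increasing labeling across samples: M+0 falls as M+n rises
  lab <- seq(10, 60, length.out = 6)
  em <- cbind(S_M0 = 100 - lab, S_M3 = lab,
              Q_M0 = 80 + rnorm(6, 0, 0.5))
  rownames(em) <- paste0("s", 1:6)
  net <- coenrichment_matrix(em)
  expect_lt(net$r["S_M0", "S_M3"], -0.99)
  # zero-variance variable flagged, r set NA
  em2 <- cbind(em, C_M0 = 50)
  net2 <- coenrichment_matrix(em2)
  expect_equal(net2$flagged, "C_M0")
  expect_true(all(is.na(net2$r["C_M0", ])))
})

test_that("clustering separates anticorrelated blocks and is order-stable", {
  set.seed(221)
  t_grad <- seq(-1, 1, length.out = 8)
  block1 <- sapply(1:3, function(i) t_grad + rnorm(8, 0, 0.01))
  block2 <- sapply(1:3, function(i) -t_grad + rnorm(8, 0, 0.01))
  em <- cbind(block1, block2)
  colnames(em) <- c(paste0("a", 1:3), paste0("b", 1:3))
  rownames(em) <- paste0("s", 1:8)
  net <- coenrichment_matrix(em)
  cl <- cluster_coenrichment(net, h = 1)
  expect_equal(length(unique(cl$clusters)), 2)
  expect_equal(length(unique(cl$clusters[paste0("a", 1:3)])), 1)
  # permutation of input columns preserves the partition
  perm <- c(4, 1, 6, 2, 5, 3)
  net_p <- coenrichment_matrix(em[, perm])
  cl_p <- cluster_coenrichment(net_p, h = 1)
  expect_equal(length(unique(cl_p$clusters)), 2)
  for (grp in list(paste0("a", 1:3), paste0("b", 1:3)))
    expect_equal(length(unique(cl_p$clusters[grp])), 1)
  # single variable: trivially one cluster
  single <- cluster_coenrichment(matrix(1, 1, 1,
                                        dimnames = list("v", "v")))
  expect_equal(unname(single$clusters), 1L)
  # NA entries refuse to cluster
  bad <- net$r
  bad[1, 2] <- bad[2, 1] <- NA
  expect_error(cluster_coenrichment(bad), "NA")
})

test_that("network export thresholds edges and round-trips", {
  t_grad <- seq(-1, 1, length.out = 6)
  em <- cbind(x = t_grad, y = t_grad * 2, z = rnorm(6, 0, 1e-3))
  rownames(em) <- paste0("s", 1:6)
  net <- coenrichment_matrix(em)
  # threshold 1.0 keeps only |r| = 1 (x vs y exactly linear)
  e1 <- export_network(net, 1.0)
  expect_equal(nrow(e1), 1)
  expect_setequal(c(e1$node1, e1$node2), c("x", "y"))
  # threshold 0: complete graph minus self-edges
  e0 <- export_network(net, 0)
  expect_equal(nrow(e0), choose(3, 2))
  # signed, lossless file round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, 0.5, path = path)
  back <- read_network(path)
  written <- export_network(net, 0.5)
  expect_equal(back, written)
  expect_error(export_network(net, 1.5), "r_threshold")
})

test_that("removing the group-linked planting collapses discriminant recovery", {
  # leakage guard: when the MID shift is not planted (all groups share
  # the same labeling), the planted pair's selection frequency must
  # fall far below the >= 95% recovery seen under planting
  cfg_null <- cocult_scenario("itum-planted", cv = 0.05)
  cfg_null$label_mids$SJH <- cfg_null$label_mids$SJ
  hits <- 0
  for (s in 1:20) {
    st <- generate_study(cfg_null, seed = 900 + s)
    envs <- generate_envelopes(st, seed = 950 + s)
    mids <- lapply(envs$envelopes, correct_natural_abundance)
    em <- build_enrichment_matrix(mids, st$design)
    pc <- run_pca(em, standardize = FALSE)
    top <- select_discriminant(pc, rule = "top:1")
    if (top[1] %in% c("GSH_M0", "GSH_M3")) hits <- hits + 1
  }
  expect_lte(hits, 6)
})

test_that("within-metabolite closure makes the raw block rank-deficient", {
  cfg <- cocult_scenario("itum", cv = 0.05)
  st <- generate_study(cfg, seed = 231)
  envs <- generate_envelopes(st, seed = 232)
  mids <- lapply(envs$envelopes, correct_natural_abundance)
  em <- build_enrichment_matrix(mids, st$design)
  block <- em[, paste0("S_M", 0:3)]
  # columns sum to 100 -> centered block has rank <= ncol - 1
  sv <- svd(scale(block, scale = FALSE))$d
  expect_lt(sv[4] / sv[1], 1e-10)
})
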