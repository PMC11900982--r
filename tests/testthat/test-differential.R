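# Differential pools: fold changes, t-tests, BH adjustment, dilution
# control and timecourse analysis.

test_that("log2 fold change matches hand arithmetic and is antisymmetric", {
  expect_equal(log2_fold_change(c(400, 400), c(100, 100)), 2)
  expect_equal(log2_fold_change(1:5, 1:5), 0)
  set.seed(51)
  for (i in 1:20) {
    a <- runif(4, 1, 100)
    b <- runif(4, 1, 100)
    expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  }
  # both means zero: undefined and flagged
  fc <- log2_fold_change(c(0, 0), c(0, 0))
  expect_true(is.na(fc))
  expect_true(attr(fc, "undefined"))
  # single zero mean: symmetric pseudo-count
  expect_equal(log2_fold_change(c(0, 0), c(3, 5), pseudo = 1),
               log2(1 / 5))
})

test_that("unpaired t-test matches closed forms and Welch equivalence", {
  # identical groups
  r <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # hand-computable fixture: pooled SD = 1, t = 10 / sqrt(2/3), df = 4
  r2 <- unpaired_t_test(c(10, 11, 12), c(0, 1, 2))
  t_expected <- 10 / sqrt(2 / 3)
  expect_equal(r2$t, t_expected)
  expect_equal(r2$df, 4)
  expect_equal(r2$p, 2 * stats::pt(-t_expected, 4))
  expect_lt(r2$p, 0.001)
  # Welch equals pooled when group variances are equal
  a <- c(4, 5, 6, 7)
  b <- c(1, 2, 3, 4)
  expect_equal(unpaired_t_test(a, b, welch = TRUE)$p,
               unpaired_t_test(a, b, welch = FALSE)$p, tolerance = 1e-6)
  # degenerate zero-variance conventions
  expect_equal(unpaired_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(unpaired_t_test(c(3, 3), c(2, 2))$p, 0)
  expect_error(unpaired_t_test(1, c(1, 2)), "n >= 2")
})

test_that("BH adjustment equals an independent brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(61)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential table recovers planted effects and their signs", {
  # 5 planted up-effects at |log2FC| = 2, CV = 0.05, on the null
  # mixture so the 1T1 control carries the additive expectation
  base <- cocult_scenario("dilution-null")
  up <- c("serine", "malate", "citrate", "uracil", "UMP")
  effects <- lapply(up, function(m)
    list(metabolite = m, log2_shift = 2,
         target_compartment = "intracellular"))
  cfg <- cocult_config(base$profiles, base$mixtures, effects,
                       n_reps = 3, cv = 0.05)
  st <- generate_study(cfg, seed = 71)
  d0 <- differential_table(st$features, st$design, "SJH", "1T1")
  expect_setequal(d0$feature_id[d0$direction == "up"], up)
  expect_equal(unname(attr(d0, "summary")["up"]), 5L)
  # sign recovery is exact at CV = 0
  cfg0 <- cocult_config(base$profiles, base$mixtures, effects,
                        n_reps = 3, cv = 0)
  st0 <- generate_study(cfg0, seed = 72)
  d00 <- differential_table(st0$features, st0$design, "SJH", "1T1",
                            alpha = 1, fc_cut = 0)
  expect_true(all(d00$log2_fc[d00$feature_id %in% up] > 0))
  expect_equal(sum(abs(d00$log2_fc) > 1e-9), 5)
  # fc_cut = Inf: nothing can be called
  dInf <- differential_table(st$features, st$design, "SJH", "HJ",
                             fc_cut = Inf)
  expect_true(all(dInf$direction == "nc"))
  expect_error(differential_table(st$features, st$design, "SJH", "XX"),
               "not present")
})

test_that("null differential table stays quiet at the 2-fold/BH criterion", {
  cfg <- cocult_scenario("dilution-null", cv = 0.1)
  quiet <- 0
  for (s in 1:25) {
    st <- generate_study(cfg, seed = 700 + s)
    d <- differential_table(st$features, st$design, "SJH", "1T1")
    if (sum(attr(d, "summary")) == 0) quiet <- quiet + 1
  }
  expect_gte(quiet, 23)  # >= 90% of seeds
})

test_that("dilution comparison flags interactions and respects alpha", {
  cfg <- cocult_scenario("interaction", cv = 0.05)
  st <- generate_study(cfg, seed = 81)
  d <- dilution_comparison(st$features, st$design)
  gg <- d[d$feature_id == "glutamyl-glycine", ]
  expect_true(gg$exceeds_dilution)
  expect_gt(gg$log2_fc, 0)
  expect_true(all(is.na(d$p_adj)))  # raw-p discovery by design
  expect_match(attr(d, "meta")$p_basis, "raw")
  # alpha = 0: no hits
  d0 <- dilution_comparison(st$features, st$design, alpha = 0)
  expect_false(any(d0$exceeds_dilution))
  # missing dilution group
  no1t1 <- st$design[st$design$group != "1T1", ]
  expect_error(
    dilution_comparison(fm_subset(st$features,
                                  samples = no1t1$sample_id),
                        no1t1),
    "dilution group")
})

test_that("timecourse fold change handles reference, drift and nc calls", {
  cfg <- cocult_scenario("media", cv = 0)
  mt <- generate_media_timecourse(cfg, seed = 91)
  mfm <- media_feature_matrix(mt$media)
  # T24 = T0 for glutamine (no rate, no drift): log2FC 0, nc
  res <- timecourse_fold_change(mfm$matrix, mfm$design, "SJ")
  gln <- res[res$feature_id == "glutamine", ]
  expect_equal(gln$log2_fc, 0)
  expect_equal(gln$direction, "nc")
  # drift adjustment subtracts the cell-free log2 drift
  res_adj <- timecourse_fold_change(mfm$matrix, mfm$design, "SJ",
                                    degradation_control = "cell-free")
  ua <- res_adj[res_adj$feature_id == "uric acid", ]
  expect_equal(ua$control_log2_drift, log2(1.47))
  expect_equal(ua$log2_fc_drift_adj, ua$log2_fc - log2(1.47))
  expect_match(attr(res_adj, "meta")$p_basis, "BH")
})

test_that("planted uridine accumulation reproduces the expected fold change", {
  # hepatocyte-containing wells accumulate uridine ~5.1-fold in 24 h
  cfg <- cocult_scenario("media", cv = 0.03)
  cfg$media$initial_mM <- c(cfg$media$initial_mM, uridine = 0.05)
  # production rate chosen so c24/c0 = 5.1: delta = 4.1 * c0 * V / (b * d)
  rate_u <- 4.1 * 0.05 * 1e-3 / (sum(cfg$mixtures$HJ) * 1)
  cfg$media$rates <- rbind(cfg$media$rates,
    data.frame(group = "HJ", metabolite = "uridine", rate = rate_u,
               mode = "production", stringsAsFactors = FALSE))
  mt <- generate_media_timecourse(cfg, seed = 92)
  mfm <- media_feature_matrix(mt$media)
  res <- timecourse_fold_change(mfm$matrix, mfm$design, "HJ")
  urd <- res[res$feature_id == "uridine", ]
  expect_lt(abs(urd$log2_fc - 2.36), 0.2)
  expect_equal(urd$direction, "up")
})
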