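# Synthetic co-culture generator: mixing semantics, noise model,
# forward envelope model, expression coupling, media timecourse.

test_that("noise-free mixing is exactly additive and 1T1 is the HJ/SJ mean", {
  cfg <- cocult_scenario("dilution-null", cv = 0)
  st <- generate_study(cfg, seed = 1)
  mu <- st$truth$true_pools
  for (k in 1:3) {
    expect_equal(unname(st$features$counts[, sprintf("SJH_%d", k)]),
                 unname(mu[, "SJH"]))
    expect_equal(unname(st$features$counts[, sprintf("1T1_%d", k)]),
                 unname((mu[, "HJ"] + mu[, "SJ"]) / 2))
  }
  # dilution-null scenario: SJH expectation equals the 1T1 expectation
  expect_equal(unname(mu[, "SJH"]), unname((mu[, "HJ"] + mu[, "SJ"]) / 2))
})

test_that("identical config and seed give bit-identical studies", {
  cfg <- cocult_scenario("interaction", cv = 0.1)
  a <- generate_study(cfg, seed = 99)
  b <- generate_study(cfg, seed = 99)
  expect_identical(a$features$counts, b$features$counts)
  expect_identical(a$design, b$design)
  c <- generate_study(cfg, seed = 100)
  expect_false(identical(a$features$counts, c$features$counts))
})

test_that("generator rejects invalid configurations with named errors", {
  cfg <- cocult_scenario("default")
  bad_mix <- cfg$mixtures
  bad_mix$HJ <- c(astrocyte = 1e-3)
  expect_error(cocult_config(cfg$profiles, bad_mix),
               "unknown cell type")
  expect_error(cocult_config(cfg$profiles, cfg$mixtures, cv = -0.1),
               "non-negative")
  expect_error(cocult_config(cfg$profiles, cfg$mixtures, n_reps = 1),
               "n_reps")
  expect_error(cell_type_profile("x", c(a = -1)), "positive")
  expect_error(cell_type_profile("x", c(a = 1),
                                 label_mid = list(a = c(50, 49))),
               "sum to 100")
})

test_that("planted log2 interaction shift is recovered downstream", {
  # oracle: noise-free regeneration gives the planted value exactly
  cfg0 <- cocult_scenario("interaction", cv = 0)
  st0 <- generate_study(cfg0, seed = 5)
  d0 <- differential_table(st0$features, st0$design, "SJH", "1T1",
                           alpha = 1)
  expect_equal(d0$log2_fc[d0$feature_id == "glutamyl-glycine"], 2.59)
  expect_equal(d0$log2_fc[d0$feature_id == "lactate"], -2)
  # with noise the estimate stays near the planted value
  cfg <- cocult_scenario("interaction", cv = 0.05)
  st <- generate_study(cfg, seed = 5)
  d <- differential_table(st$features, st$design, "SJH", "1T1", alpha = 1)
  expect_lt(abs(d$log2_fc[d$feature_id == "glutamyl-glycine"] - 2.59), 0.3)
  expect_lt(abs(d$log2_fc[d$feature_id == "lactate"] - (-2)), 0.3)
})

test_that("forward envelope model matches the binomial closed form", {
  # unlabeled 6-carbon pool: M+1/total = 6 p (1-p)^5
  p <- 0.0111
  cfg <- cocult_scenario("itum-planted", cv = 0)
  cfg$label_mids <- lapply(cfg$label_mids, function(g) {
    g$citrate <- c(100, 0, 0, 0, 0, 0, 0)
    g
  })
  st <- generate_study(cfg, seed = 3)
  env <- generate_envelopes(st, natural_p = p, cv = 0)
  cit <- env$envelopes[["citrate"]]$counts[, 1]
  expect_equal(unname(cit[2] / sum(cit)), 6 * p * (1 - p)^5,
               tolerance = 1e-9)
  # natural_p = 0: observed envelope proportional to the true MID
  env0 <- generate_envelopes(st, natural_p = 0, cv = 0)
  ser <- env0$envelopes[["serine"]]$counts[, "SJ_1"]
  true_mid <- st$truth$true_mids$SJ$serine
  expect_equal(100 * ser / sum(ser), true_mid, ignore_attr = TRUE)
})

test_that("envelope scaling reproduces counts from fractions", {
  # 3-carbon pool at fractions (60,10,10,20), total 1000, p = 0
  C <- build_correction_matrix(3, 0)$entries
  counts <- 1000 * as.numeric(C %*% (c(60, 10, 10, 20) / 100))
  expect_equal(counts, c(600, 100, 100, 200))
})

test_that("envelope generation validates MID length", {
  cfg <- cocult_scenario("itum-planted", cv = 0)
  cfg$label_mids$SJ$serine <- c(50, 25, 25)  # serine has 3 carbons -> 4
  st <- generate_study(cfg, seed = 2)
  expect_error(generate_envelopes(st), "length")
})

test_that("expression coupling propagates exactly at zero noise", {
  cfg <- cocult_scenario("default", cv = 0.1)
  st <- generate_study(cfg, seed = 11)
  cp <- data.frame(gene = c("gpos", "gneg"),
                   metabolite = c("lactate", "malate"),
                   slope = c(2, -0.5), noise_sd = 0)
  ex <- generate_expression(st, n_genes = 10, coupled_pairs = cp,
                            seed = 12)
  pr <- pair_samples(ex$design, ex$metab_design)
  met_l <- st$features$counts["lactate", pr$metab_sample]
  met_m <- st$features$counts["malate", pr$metab_sample]
  expect_equal(pearson_brute(ex$expr["gpos", pr$expr_sample], met_l), 1)
  expect_equal(pearson_brute(ex$expr["gneg", pr$expr_sample], met_m), -1)
  expect_error(generate_expression(st, n_genes = 1, coupled_pairs = cp),
               "n_genes")
})

test_that("media timecourse reproduces rates, drift and conservation", {
  cfg <- cocult_scenario("media", cv = 0)
  mt <- generate_media_timecourse(cfg, seed = 4)
  # consumption 2.50/day recovered exactly without noise
  fs <- flux_summary(mt$media, mt$design, "glucose", "consumption")
  expect_equal(fs$rate[fs$group == "SJ"], 2.50)
  expect_equal(fs$rate[fs$group == "SJH"], 0.5)
  # cell-free drift: uric acid +47%, hypoxanthine +9%
  cf <- mt$media[mt$media$group == "cell-free", ]
  for (m in c("uric acid", "hypoxanthine")) {
    x <- cf[cf$metabolite == m, ]
    expect_equal(mean(x$conc_mM[x$timepoint_h > 0]) /
                 mean(x$conc_mM[x$timepoint_h == 0]),
                 1 + mt$truth$drift[[m]])
  }
  # zero rate, zero drift: concentration conserved
  gln <- mt$media[mt$media$metabolite == "glutamine" &
                  mt$media$group == "SJ", ]
  expect_equal(gln$conc_mM[gln$timepoint_h > 0],
               gln$conc_mM[gln$timepoint_h == 0])
  # negative initial concentration rejected
  bad <- cfg
  bad$media$initial_mM[["glucose"]] <- -1
  expect_error(generate_media_timecourse(bad), "negative initial")
})

test_that("config round-trips through the YAML file format", {
  cfg <- cocult_scenario("interaction", n_reps = 4, cv = 0.07)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cocult_config(cfg, path)
  cfg2 <- read_cocult_config(path)
  expect_equal(cfg2$n_reps, 4)
  expect_equal(cfg2$cv, 0.07)
  expect_equal(expected_pools(cfg2), expected_pools(cfg))
  st <- generate_study(cfg, seed = 8)
  st2 <- generate_study(cfg2, seed = 8)
  expect_equal(st$features$counts, st2$features$counts)
})
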