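# Synthetic co-culture study generator.
#
# Mixed-culture metabolite pools are biomass-weighted sums of per-cell-
# type pools; the SJH group can carry planted multiplicative interaction
# effects beyond additive mixing; the analytical 1T1 control is the
# arithmetic mean of the HJ and SJ noise-free profiles. Measurement
# noise is multiplicative log-normal with configurable CV.

#' Define a cell-type profile
#'
#' @param name cell-type label (e.g. `"hepatocyte"`).
#' @param base_pool named numeric vector of mean ion counts per unit
#'   biomass (strictly positive), one entry per metabolite.
#' @param label_mid optional named list of true 13C mass isotopologue
#'   distributions (percent vectors M+0..M+n summing to 100) under
#'   uniformly labeled glucose.
#' @param secretion,consumption optional named media rates
#'   (mol/day/mg DNA).
#' @return object of class `cell_type_profile`.
#' @export
cell_type_profile <- function(name, base_pool, label_mid = NULL,
                              secretion = NULL, consumption = NULL) {
  if (is.null(names(base_pool)) || any(!nzchar(names(base_pool))))
    stopf("base_pool must be a named vector")
  if (any(base_pool <= 0)) stopf("base_pool must be strictly positive")
  if (!is.null(label_mid))
    for (m in names(label_mid)) validate_mid_vector(label_mid[[m]], m)
  structure(list(cell_type_name = name, base_pool = base_pool,
                 label_mid = label_mid, secretion = secretion,
                 consumption = consumption),
            class = "cell_type_profile")
}

validate_mid_vector <- function(mid, what = "MID") {
  if (any(mid < 0)) stopf("%s: MID fractions must be non-negative", what)
  if (abs(sum(mid) - 100) > 1e-9)
    stopf("%s: MID must sum to 100 within 1e-9 (got %.12g)", what, sum(mid))
  invisible(mid)
}

#' Assemble a co-culture scenario configuration
#'
#' @param profiles named list of [cell_type_profile()] objects covering a
#'   common metabolite set.
#' @param mixtures named list: group label -> named numeric vector of
#'   biomass weights (mg DNA) over profile names. Mixed pools are the
#'   weight-weighted sums of cell-type pools.
#' @param effects list of interaction effects, each
#'   `list(metabolite =, log2_shift =, target_compartment = "intracellular")`,
#'   applied to SJH samples only (beyond additive mixing).
#' @param n_reps replicates per group (default 3, the usual metabolomics
#'   design).
#' @param cv coefficient of variation of multiplicative log-normal
#'   measurement noise (default 0.1).
#' @param label_mids named list (group -> metabolite -> percent vector)
#'   of true MIDs used by [generate_envelopes()].
#' @param panel metabolite metadata table; defaults to the built-in
#'   [metabolite_panel()] rows matching the profiled metabolites.
#' @param make_1t1 generate analytical 1T1 samples when both `HJ` and
#'   `SJ` mixtures exist (default TRUE).
#' @param media optional media-timecourse block for
#'   [generate_media_timecourse()]: `list(initial_mM =, rates =,
#'   drift =, volume_ml =, days =)`.
#' @param volume_ml culture volume per well.
#' @return object of class `cocult_config`.
#' @export
cocult_config <- function(profiles, mixtures, effects = list(),
                          n_reps = 3, cv = 0.1, label_mids = NULL,
                          panel = NULL, make_1t1 = TRUE, media = NULL,
                          volume_ml = 1) {
  if (length(profiles) < 2) stopf("config needs at least 2 cell-type profiles")
  mets <- names(profiles[[1]]$base_pool)
  if (!length(mets)) stopf("config needs at least 1 metabolite")
  for (p in profiles)
    if (!setequal(names(p$base_pool), mets))
      stopf("profile '%s' covers a different metabolite set",
            p$cell_type_name)
  if (n_reps < 2) stopf("n_reps must be >= 2")
  if (cv < 0) stopf("cv must be non-negative")
  for (g in names(mixtures)) {
    unknown <- setdiff(names(mixtures[[g]]), names(profiles))
    if (length(unknown))
      stopf("mixture '%s' references unknown cell type(s): %s", g,
            paste(unknown, collapse = ", "))
    if (any(mixtures[[g]] < 0)) stopf("mixture '%s' has negative weights", g)
  }
  for (e in effects)
    if (!e$metabolite %in% mets)
      stopf("interaction effect targets unknown metabolite '%s'",
            e$metabolite)
  if (is.null(panel)) panel <- metabolite_panel(mets)
  structure(list(profiles = profiles, mixtures = mixtures,
                 effects = effects, n_reps = n_reps, cv = cv,
                 label_mids = label_mids, panel = panel,
                 make_1t1 = make_1t1, media = media,
                 volume_ml = volume_ml),
            class = "cocult_config")
}

## noise-free expected pool of every group, metabolites x groups
expected_pools <- function(config) {
  mets <- names(config$profiles[[1]]$base_pool)
  groups <- names(config$mixtures)
  mu <- sapply(groups, function(g) {
    w <- config$mixtures[[g]]
    Reduce(`+`, lapply(names(w), function(ct)
      w[[ct]] * config$profiles[[ct]]$base_pool[mets]))
  })
  rownames(mu) <- mets
  mu
}

apply_effects <- function(mu, config, compartment = "intracellular") {
  if ("SJH" %in% colnames(mu)) {
    for (e in config$effects) {
      tc <- e$target_compartment %||% "intracellular"
      if (tc == compartment)
        mu[e$metabolite, "SJH"] <- mu[e$metabolite, "SJH"] * 2^e$log2_shift
    }
  }
  mu
}

#' Generate a synthetic co-culture study
#'
#' Produces an annotated feature table, a study design and a planted
#' ground truth. Pools of mixed groups are biomass-weighted sums of the
#' cell-type pools; SJH pools are additionally shifted by the configured
#' interaction effects; analytical 1T1 samples are the arithmetic mean
#' of the HJ and SJ noise-free profiles. All ion counts then receive
#' multiplicative log-normal noise with the configured CV. Identical
#' `(config, seed)` pairs give bit-identical output.
#'
#' @param config a [cocult_config()].
#' @param seed integer RNG seed.
#' @return object of class `cocult_study`: list with `features` (a
#'   [feature_matrix()]), `design` (data.frame) and `truth` (list with
#'   `true_pools`, `interaction_set`, `true_mids`, `true_rates`).
#' @export
generate_study <- function(config, seed = NULL) {
  if (!inherits(config, "cocult_config")) stopf("config must be a cocult_config")
  maybe_seed(seed)
  mu <- apply_effects(expected_pools(config), config)
  groups <- colnames(mu)
  n <- config$n_reps
  mk <- function(g) {
    ids <- sprintf("%s_%d", g, seq_len(n))
    cnt <- sapply(ids, function(i)
      mu[, g] * lnorm_factor(nrow(mu), config$cv))
    colnames(cnt) <- ids
    cnt
  }
  counts <- do.call(cbind, lapply(groups, mk))
  biomass <- vapply(groups, function(g) sum(config$mixtures[[g]]),
                    numeric(1))
  design <- data.frame(
    sample_id = colnames(counts),
    group = rep(groups, each = n),
    replicate = rep(seq_len(n), length(groups)),
    biomass_mg_dna = rep(unname(biomass), each = n),
    volume_ml = config$volume_ml,
    timepoint_h = 24,
    stringsAsFactors = FALSE)
  t1_truth <- NULL
  if (isTRUE(config$make_1t1) && all(c("HJ", "SJ") %in% groups)) {
    t1mu <- (mu[, "HJ"] + mu[, "SJ"]) / 2
    t1 <- sapply(seq_len(n), function(k)
      t1mu * lnorm_factor(length(t1mu), config$cv))
    colnames(t1) <- sprintf("1T1_%d", seq_len(n))
    counts <- cbind(counts, t1)
    design <- rbind(design, data.frame(
      sample_id = colnames(t1), group = "1T1", replicate = seq_len(n),
      biomass_mg_dna = mean(biomass[c("HJ", "SJ")]),
      volume_ml = config$volume_ml, timepoint_h = 24,
      stringsAsFactors = FALSE))
    t1_truth <- t1mu
  }
  panel <- config$panel
  feats <- data.frame(feature_id = panel$metabolite,
                      annotation = panel$metabolite,
                      code = panel$code,
                      formula = panel$formula,
                      n_carbons = panel$n_carbons,
                      mz = panel$mz, rt = panel$rt,
                      polarity = "negative",
                      stringsAsFactors = FALSE)
  counts <- counts[panel$metabolite, , drop = FALSE]
  truth <- list(true_pools = mu,
                true_pool_1T1 = t1_truth,
                interaction_set = vapply(config$effects, `[[`, "",
                                         "metabolite"),
                effects = config$effects,
                true_mids = config$label_mids,
                true_rates = config$media$rates)
  structure(list(features = feature_matrix(feats, counts),
                 design = design, truth = truth, config = config),
            class = "cocult_study")
}

#' @export
print.cocult_study <- function(x, ...) {
  cat(sprintf("<cocult_study> %d metabolites, groups: %s (n = %d)\n",
              nrow(x$features$counts),
              paste(unique(x$design$group), collapse = ", "),
              x$config$n_reps))
  invisible(x)
}

#' Generate raw isotopologue envelopes
#'
#' Forward model that the natural-abundance correction must invert:
#' observed envelope = convolution of the group's true MID with binomial
#' natural 13C abundance, scaled by the sample's total pool, times
#' log-normal noise.
#'
#' @param study a `cocult_study` whose config carries `label_mids`.
#' @param natural_p natural 13C fraction in `[0, 0.5)`; default 0.0111.
#' @param cv measurement CV for isotopologue counts (default: the study
#'   CV).
#' @param groups groups to generate (default: all groups with MIDs).
#' @param seed integer RNG seed.
#' @return object of class `cocult_envelopes`: list with `envelopes`
#'   (named list of [iso_envelope()]), `design`, `truth`, `natural_p`.
#' @export
generate_envelopes <- function(study, natural_p = 0.0111, cv = NULL,
                               groups = NULL, seed = NULL) {
  if (!inherits(study, "cocult_study")) stopf("study must be a cocult_study")
  mids <- study$truth$true_mids
  if (is.null(mids)) stopf("study config has no label_mids")
  if (natural_p < 0 || natural_p >= 0.5)
    stopf("natural_p must lie in [0, 0.5)")
  maybe_seed(seed)
  cv <- cv %||% study$config$cv
  groups <- groups %||% names(mids)
  design <- study$design[study$design$group %in% groups, , drop = FALSE]
  panel <- study$config$panel
  mets <- Reduce(intersect, lapply(mids[groups], names))
  envs <- list()
  for (m in mets) {
    nC <- panel$n_carbons[panel$metabolite == m]
    if (!length(nC)) stopf("metabolite '%s' absent from panel", m)
    C <- build_correction_matrix(nC, natural_p)$entries
    cnt <- matrix(0, nC + 1, nrow(design),
                  dimnames = list(paste0("M", 0:nC), design$sample_id))
    for (g in groups) {
      mid <- mids[[g]][[m]]
      if (length(mid) != nC + 1)
        stopf("MID for '%s' in group %s has length %d, expected %d",
              m, g, length(mid), nC + 1)
      validate_mid_vector(mid, m)
      total <- study$truth$true_pools[m, g]
      expected <- total * as.numeric(C %*% (mid / 100))
      for (s in design$sample_id[design$group == g])
        cnt[, s] <- expected * lnorm_factor(nC + 1, cv)
    }
    code <- panel$code[panel$metabolite == m]
    envs[[m]] <- iso_envelope(metabolite = m, counts = cnt,
                              mz_base = panel$mz[panel$metabolite == m],
                              code = code)
  }
  structure(list(envelopes = envs, design = design, truth = study$truth,
                 natural_p = natural_p),
            class = "cocult_envelopes")
}

#' Flatten envelopes to an LC-MS feature table
#'
#' Writes each isotopologue as an individual feature at
#' `mz_base + k * 1.0033`, the representation [extract_envelope()]
#' consumes.
#'
#' @param envs a `cocult_envelopes` object.
#' @return a [feature_matrix()].
#' @export
envelopes_to_features <- function(envs) {
  rows <- list()
  cnts <- list()
  for (e in envs$envelopes) {
    n <- e$n_carbons
    rows[[e$metabolite]] <- data.frame(
      feature_id = sprintf("%s_M%d", e$code, 0:n),
      annotation = e$metabolite, code = e$code, formula = NA,
      n_carbons = n, mz = e$mz_base + (0:n) * 1.0033,
      rt = NA, polarity = "negative", stringsAsFactors = FALSE)
    cnts[[e$metabolite]] <- e$counts
  }
  feature_matrix(do.call(rbind, c(rows, make.row.names = FALSE)),
                 do.call(rbind, cnts))
}

#' Generate a coupled gene-expression matrix
#'
#' Emulates the tumor-cell transcriptome for SJ and SJH samples: coupled
#' genes are linear in a metabolite's (observed) abundance plus Gaussian
#' noise; uncoupled genes are independent log-normal.
#'
#' @param study a `cocult_study`.
#' @param n_genes total genes (>= number of coupled pairs).
#' @param coupled_pairs data.frame with `gene`, `metabolite`, `slope`
#'   and either `noise_sd` or `target_r` (population Pearson r implied
#'   by the coupling noise; `noise_sd` wins if both are present).
#' @param groups expression groups (default SJ, SJH).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of
#'   uncoupled genes.
#' @param seed integer RNG seed.
#' @return list with `expr` (genes x samples matrix), `design` (the
#'   matching design rows) and `coupled_pairs`.
#' @export
generate_expression <- function(study, n_genes,
                                coupled_pairs = NULL,
                                groups = c("SJ", "SJH"),
                                baseline_meanlog = log(1000),
                                baseline_sdlog = 0.5, seed = NULL) {
  if (!inherits(study, "cocult_study")) stopf("study must be a cocult_study")
  coupled_pairs <- coupled_pairs %||%
    data.frame(gene = character(), metabolite = character(),
               slope = numeric())
  if (n_genes < nrow(coupled_pairs))
    stopf("n_genes (%d) < number of coupled pairs (%d)", n_genes,
          nrow(coupled_pairs))
  miss <- setdiff(coupled_pairs$metabolite, study$features$features$feature_id)
  if (length(miss))
    stopf("coupled_pairs reference unknown metabolite(s): %s",
          paste(miss, collapse = ", "))
  maybe_seed(seed)
  design <- study$design[study$design$group %in% groups, , drop = FALSE]
  samples <- design$sample_id
  expr <- matrix(NA_real_, n_genes, length(samples))
  colnames(expr) <- sprintf("RNA_%s", samples)
  gene_ids <- if (nrow(coupled_pairs))
    c(coupled_pairs$gene,
      sprintf("gene%04d", seq_len(n_genes - nrow(coupled_pairs))))
  else sprintf("gene%04d", seq_len(n_genes))
  rownames(expr) <- gene_ids
  k <- nrow(coupled_pairs)
  if (k) {
    for (i in seq_len(k)) {
      met <- study$features$counts[coupled_pairs$metabolite[i], samples]
      slope <- coupled_pairs$slope[i]
      sd_i <- if ("noise_sd" %in% names(coupled_pairs) &&
                  !is.na(coupled_pairs$noise_sd[i]))
        coupled_pairs$noise_sd[i]
      else if ("target_r" %in% names(coupled_pairs))
        coupling_noise_for_r(met, slope, coupled_pairs$target_r[i])
      else 0
      expr[i, ] <- slope * met + stats::rnorm(length(met), 0, sd_i)
    }
  }
  if (n_genes > k)
    expr[(k + 1):n_genes, ] <- stats::rlnorm((n_genes - k) * length(samples),
                                             baseline_meanlog,
                                             baseline_sdlog)
  rna_design <- design
  rna_design$sample_id <- colnames(expr)
  list(expr = expr, design = rna_design, metab_design = design,
       coupled_pairs = coupled_pairs)
}

#' Coupling noise giving a target Pearson r
#'
#' For `gene = slope * metabolite + N(0, sd)`, returns the `sd` at which
#' the population correlation over the supplied metabolite values equals
#' `r`.
#'
#' @param metab_values metabolite abundances across the paired samples.
#' @param slope linear coupling slope.
#' @param r target |population correlation| in (0, 1].
#' @return Gaussian noise standard deviation.
#' @export
coupling_noise_for_r <- function(metab_values, slope, r) {
  if (r <= 0 || r > 1) stopf("target_r must lie in (0, 1]")
  abs(slope) * stats::sd(metab_values) * sqrt(1 / r^2 - 1)
}

#' Generate a media timecourse with cell-free degradation controls
#'
#' Simulates t0 and t24 media concentrations:
#' `c_t24 = c_t0 + (production - consumption) * biomass * days / volume +
#' drift * c_t0`, with multiplicative measurement noise on every measured
#' value. Drift (spontaneous degradation/accumulation at 37 C) applies
#' to all wells including the cell-free controls, which carry no cellular
#' rates at all.
#'
#' @param config a [cocult_config()] whose `media` block defines
#'   `initial_mM` (named), `rates` (data.frame `group`, `metabolite`,
#'   `rate`, `mode` in consumption/production, units per day per mg
#'   DNA), optional `drift` (named fraction/day), `volume_ml`, `days`.
#' @param cellfree include cell-free control wells (default TRUE).
#' @param seed integer RNG seed.
#' @return list with `media` (long data.frame `sample_id`, `group`,
#'   `replicate`, `metabolite`, `timepoint_h`, `conc_mM`), `design`, and
#'   `truth` (planted rates and drift).
#' @export
generate_media_timecourse <- function(config, cellfree = TRUE,
                                      seed = NULL) {
  mb <- config$media
  if (is.null(mb)) stopf("config has no media block")
  c0 <- mb$initial_mM
  if (any(c0 < 0)) stopf("negative initial concentration")
  maybe_seed(seed)
  drift <- mb$drift %||% stats::setNames(numeric(0), character(0))
  days <- mb$days %||% 1
  vol_l <- (mb$volume_ml %||% config$volume_ml) / 1000
  groups <- unique(mb$rates$group)
  if (cellfree) groups <- c(groups, "cell-free")
  n <- config$n_reps
  rows <- list()
  for (g in groups) {
    biomass <- if (g == "cell-free") NA_real_ else sum(config$mixtures[[g]])
    for (k in seq_len(n)) {
      sid <- sprintf("media_%s_%d", g, k)
      for (m in names(c0)) {
        delta <- 0
        if (g != "cell-free") {
          r <- mb$rates[mb$rates$group == g & mb$rates$metabolite == m, ,
                        drop = FALSE]
          if (nrow(r)) {
            signed <- ifelse(r$mode == "consumption", -r$rate, r$rate)
            delta <- sum(signed) * biomass * days / vol_l
          }
        }
        d <- if (m %in% names(drift)) drift[[m]] else 0
        true24 <- c0[[m]] + delta + d * c0[[m]]
        if (true24 < 0) true24 <- 0
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, group = g, replicate = k,
          metabolite = m,
          timepoint_h = c(0, 24 * days),
          conc_mM = c(c0[[m]] * lnorm_factor(1, config$cv),
                      true24 * lnorm_factor(1, config$cv)),
          stringsAsFactors = FALSE)
      }
    }
  }
  media <- do.call(rbind, c(rows, make.row.names = FALSE))
  design <- unique(data.frame(
    sample_id = media$sample_id, group = media$group,
    replicate = media$replicate,
    biomass_mg_dna = ifelse(media$group == "cell-free", NA_real_,
                            vapply(media$group, function(g)
                              if (g == "cell-free") NA_real_
                              else sum(config$mixtures[[g]]), numeric(1))),
    volume_ml = mb$volume_ml %||% config$volume_ml,
    stringsAsFactors = FALSE))
  list(media = media, design = design,
       truth = list(rates = mb$rates, drift = drift,
                    initial_mM = c0, days = days))
}

#' Media timecourse as a feature matrix
#'
#' Reshapes the long media table into a [feature_matrix()] (metabolites x
#' measurements) with a matching design carrying `timepoint_h`, for use
#' with [timecourse_fold_change()].
#'
#' @param media long media table from [generate_media_timecourse()].
#' @return list with `matrix` and `design`.
#' @export
media_feature_matrix <- function(media) {
  media$mid <- sprintf("%s_t%g", media$sample_id, media$timepoint_h)
  mets <- unique(media$metabolite)
  ids <- unique(media$mid)
  cnt <- matrix(0, length(mets), length(ids),
                dimnames = list(mets, ids))
  for (i in seq_len(nrow(media)))
    cnt[media$metabolite[i], media$mid[i]] <- media$conc_mM[i]
  d <- unique(media[c("mid", "group", "replicate", "timepoint_h")])
  names(d)[1] <- "sample_id"
  list(matrix = feature_matrix(
         data.frame(feature_id = mets, stringsAsFactors = FALSE), cnt),
       design = d)
}

#' Write the ground-truth sidecar table
#'
#' Long table of planted truths (pool means per group, interaction
#' flags) for test harnesses.
#'
#' @param study a `cocult_study`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(study, path) {
  mu <- study$truth$true_pools
  gt <- do.call(rbind, lapply(colnames(mu), function(g)
    data.frame(metabolite = rownames(mu), group = g,
               true_pool = mu[, g],
               interaction = rownames(mu) %in% study$truth$interaction_set,
               stringsAsFactors = FALSE)))
  utils::write.table(gt, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
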