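# Preset co-culture scenarios and the YAML config reader.
#
# The presets fix the study conditions used throughout the test suites:
# biomass weights approximating 150k hepatocytes + 150k fibroblasts
# (+50k tumor cells) per well at ~6.6 pg DNA/cell, n = 3 replicates per
# group, and log-normal measurement noise.

## deterministic, positive, well-spread base pools per cell type
.base_pools <- function(mets, offset) {
  i <- seq_along(mets)
  stats::setNames(1e5 * 2^(((i * 3 + offset) %% 9) - 4), mets)
}

.weights_hj <- c(hepatocyte = 1e-3, fibroblast = 1e-3)
.weights_sj <- c(tumor = 3.3e-4, fibroblast = 1e-3)

## evenly spread `enrich` percent across M+1..M+n
.make_mid <- function(n, enrich) {
  mid <- c(100 - enrich, rep(enrich / n, n))
  mid[1] <- 100 - sum(mid[-1])
  mid
}

#' Preset co-culture scenarios
#'
#' Ready-made [cocult_config()]s covering the situations the analysis
#' stages are designed for:
#'
#' * `"default"`: full-biomass additive SJH mixture, no planted effects.
#' * `"dilution-null"`: SJH biomass weights equal the arithmetic mean of
#'   the HJ and SJ weights, so the SJH expectation equals the 1T1
#'   dilution control exactly — the null for dilution-test calibration.
#' * `"interaction"`: the dilution-null mixture plus a planted
#'   `+2.59` log2 interaction shift on glutamyl-glycine (and `-2` on
#'   lactate), the magnitudes the dilution test should flag.
#' * `"itum"`: 8-metabolite labeling panel with group-specific MIDs
#'   (glutathione and glutamate more enriched in SJH, serine less).
#' * `"itum-planted"`: identical MIDs in all groups except one planted
#'   discriminating shift (20 points M+0 -> M+3 of glutathione in SJH);
#'   used for discriminant-recovery simulations.
#' * `"media"`: media-timecourse block with the fuel rates observed in
#'   co-culture (glucose consumption 2.50/0.5, lactate production
#'   3.86/0.23 per day per mg DNA for SJ/SJH) plus hypoxanthine 9% and
#'   uric acid 47% per-day spontaneous drift.
#'
#' @param name scenario name.
#' @param n_reps replicates per group (default 3).
#' @param cv measurement CV (default 0.1).
#' @return a [cocult_config()].
#' @export
cocult_scenario <- function(name = c("default", "dilution-null",
                                     "interaction", "itum",
                                     "itum-planted", "media"),
                            n_reps = 3, cv = 0.1) {
  name <- match.arg(name)
  panel <- metabolite_panel()
  mets <- panel$metabolite
  profiles <- list(
    hepatocyte = cell_type_profile("hepatocyte", .base_pools(mets, 0)),
    tumor = cell_type_profile("tumor", .base_pools(mets, 2)),
    fibroblast = cell_type_profile("fibroblast", .base_pools(mets, 5)))
  sjh_full <- c(hepatocyte = 1e-3, fibroblast = 1e-3, tumor = 3.3e-4)
  sjh_null <- c(hepatocyte = 5e-4, fibroblast = 1e-3, tumor = 1.65e-4)
  mixtures <- list(HJ = .weights_hj, SJ = .weights_sj, SJH = sjh_full)

  if (name %in% c("dilution-null", "interaction"))
    mixtures$SJH <- sjh_null
  effects <- list()
  if (name == "interaction")
    effects <- list(list(metabolite = "glutamyl-glycine",
                         log2_shift = 2.59,
                         target_compartment = "intracellular"),
                    list(metabolite = "lactate", log2_shift = -2,
                         target_compartment = "intracellular"))

  label_mids <- NULL
  if (name %in% c("itum", "itum-planted")) {
    itum_mets <- c("serine", "glutamate", "glutathione", "malate",
                   "citrate", "lactate", "succinate", "aspartate")
    codes <- panel$code[match(itum_mets, panel$metabolite)]
    nc <- panel$n_carbons[match(itum_mets, panel$metabolite)]
    base_enrich <- c(serine = 35, glutamate = 45, glutathione = 30,
                     malate = 50, citrate = 55, lactate = 60,
                     succinate = 40, aspartate = 45)
    base <- stats::setNames(lapply(seq_along(itum_mets), function(i)
      .make_mid(nc[i], base_enrich[[itum_mets[i]]])), itum_mets)
    hj <- sj <- sjh <- base
    if (name == "itum") {
      # group-specific labeling: SJH routes more glucose carbon into
      # glutathione/glutamate, less into serine
      sjh$glutathione <- shift_mid(base$glutathione, from = 0, to = 4, by = 15)
      sjh$glutamate <- shift_mid(base$glutamate, from = 0, to = 5, by = 10)
      sjh$serine <- shift_mid(base$serine, from = 3, to = 0, by = 8)
      hj$glutathione <- shift_mid(base$glutathione, from = 0, to = 4, by = 5)
    } else {
      sjh$glutathione <- shift_mid(base$glutathione, from = 0, to = 3, by = 20)
    }
    label_mids <- list(HJ = hj, SJ = sj, SJH = sjh)
  }

  media <- NULL
  if (name == "media") {
    media <- list(
      initial_mM = c(glucose = 22, lactate = 0.5, hypoxanthine = 0.02,
                     `uric acid` = 0.01, glutamine = 4),
      rates = data.frame(
        group = c("SJ", "SJ", "SJH", "SJH"),
        metabolite = c("glucose", "lactate", "glucose", "lactate"),
        rate = c(2.50, 3.86, 0.5, 0.23),
        mode = c("consumption", "production", "consumption",
                 "production"),
        stringsAsFactors = FALSE),
      drift = c(hypoxanthine = 0.09, `uric acid` = 0.47),
      volume_ml = 1, days = 1)
  }
  cocult_config(profiles = profiles, mixtures = mixtures,
                effects = effects, n_reps = n_reps, cv = cv,
                label_mids = label_mids, panel = panel, media = media)
}

#' Shift MID mass between two isotopologues
#'
#' Moves `by` percentage points from isotopologue `from` to `to`,
#' preserving closure (sum 100).
#'
#' @param mid percent vector M+0..M+n.
#' @param from,to zero-based isotopologue indices.
#' @param by percentage points to move (must leave `from` non-negative).
#' @return shifted percent vector.
#' @export
shift_mid <- function(mid, from, to, by) {
  if (mid[from + 1] < by)
    stopf("cannot move %g points from M+%d (only %g available)", by, from,
          mid[from + 1])
  mid[from + 1] <- mid[from + 1] - by
  mid[to + 1] <- mid[to + 1] + by
  mid
}

#' Read a scenario configuration from YAML
#'
#' Structured text config with sections `profiles`, `mixtures`,
#' `effects`, `noise` (`cv`, `n_reps`) and optional `label_mids` /
#' `media`.
#'
#' @param path YAML file path.
#' @return a [cocult_config()].
#' @export
read_cocult_config <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- lapply(names(y$profiles), function(nm) {
    p <- y$profiles[[nm]]
    cell_type_profile(nm, unlist(p$base_pool),
                      label_mid = p$label_mid)
  })
  names(profiles) <- names(y$profiles)
  mixtures <- lapply(y$mixtures, unlist)
  media <- y$media
  if (!is.null(media)) {
    media$initial_mM <- unlist(media$initial_mM)
    media$drift <- unlist(media$drift)
    if (!is.null(media$rates))
      media$rates <- do.call(rbind,
        lapply(media$rates, function(r) as.data.frame(r,
                                                      stringsAsFactors = FALSE)))
  }
  label_mids <- y$label_mids
  if (!is.null(label_mids))
    label_mids <- lapply(label_mids, function(g) lapply(g, unlist))
  cocult_config(profiles = profiles, mixtures = mixtures,
                effects = y$effects %||% list(),
                n_reps = y$noise$n_reps %||% 3,
                cv = y$noise$cv %||% 0.1,
                label_mids = label_mids, media = media)
}

#' Write a scenario configuration to YAML
#'
#' @param config a [cocult_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_cocult_config <- function(config, path) {
  y <- list(
    profiles = lapply(config$profiles, function(p)
      list(base_pool = as.list(p$base_pool),
           label_mid = p$label_mid)),
    mixtures = lapply(config$mixtures, as.list),
    effects = config$effects,
    noise = list(cv = config$cv, n_reps = config$n_reps),
    label_mids = config$label_mids,
    media = if (!is.null(config$media)) {
      m <- config$media
      m$initial_mM <- as.list(m$initial_mM)
      m$drift <- as.list(m$drift)
      if (!is.null(m$rates))
        m$rates <- lapply(seq_len(nrow(m$rates)), function(i)
          as.list(m$rates[i, ]))
      m
    })
  yaml::write_yaml(y, path)
  invisible(path)
}
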