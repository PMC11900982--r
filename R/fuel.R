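# Fuel-utilization quantification: NMR concentrations, net
# consumption/production rates, lactate:glucose ratio, ketone bodies,
# adenylate energy charge and NAD+/NADH.

#' Molar concentration from NMR integrals
#'
#' `conc = (I_analyte / n_protons) / (I_ref / 9) * ref_conc_mM`: the
#' analyte signal per contributing proton relative to the 9-proton
#' trimethyl reference signal (TSP), scaled by the spiked reference
#' concentration. Glucose uses its 1-proton alpha-anomeric signal,
#' lactate its 3-proton methyl signal.
#'
#' @param integrals data.frame with `sample_id`, `analyte`, `integral`,
#'   `protons`.
#' @param analyte analyte name to quantify.
#' @param reference reference analyte name (default `"TSP"`).
#' @param ref_conc_mM reference concentration (default 0.3 mM).
#' @return data.frame `sample_id, analyte, conc_mM`.
#' @export
nmr_concentration <- function(integrals, analyte, reference = "TSP",
                              ref_conc_mM = 0.3) {
  req <- c("sample_id", "analyte", "integral", "protons")
  if (!all(req %in% names(integrals)))
    stopf("integrals needs columns: %s", paste(req, collapse = ", "))
  if (any(integrals$integral < 0)) stopf("integrals must be >= 0")
  if (any(integrals$protons <= 0 |
          integrals$protons != round(integrals$protons)))
    stopf("proton counts must be positive integers")
  a <- integrals[integrals$analyte == analyte, , drop = FALSE]
  r <- integrals[integrals$analyte == reference, , drop = FALSE]
  if (!nrow(a)) stopf("analyte '%s' absent from integrals", analyte)
  if (!nrow(r)) stopf("reference '%s' absent from integrals", reference)
  ri <- r$integral[match(a$sample_id, r$sample_id)]
  rp <- r$protons[match(a$sample_id, r$sample_id)]
  if (any(is.na(ri))) stopf("missing reference integral for sample(s): %s",
                            paste(a$sample_id[is.na(ri)], collapse = ", "))
  if (any(ri == 0)) stopf("zero reference integral")
  data.frame(sample_id = a$sample_id, analyte = analyte,
             conc_mM = (a$integral / a$protons) / (ri / rp) * ref_conc_mM,
             stringsAsFactors = FALSE)
}

#' Net consumption or production rate
#'
#' Converts a media concentration change over an incubation into a
#' biomass-normalized rate:
#' consumption = `(c_t0 - c_t24) * V / biomass / days`, production with
#' the opposite sign. A negative result under the chosen mode (a net
#' producer tested as consumer, or vice versa) is returned signed and
#' flagged, never clipped.
#'
#' @param c_t0,c_t24 concentrations at start / end (same units, e.g.
#'   mM).
#' @param volume media volume (e.g. L; the rate unit follows the
#'   inputs and is echoed, not converted).
#' @param biomass biomass (mg DNA, > 0).
#' @param days incubation length in days (> 0).
#' @param mode `"consumption"` or `"production"`.
#' @param unit unit string echoed in the result.
#' @return list with `rate`, `mode`, `unit`, `inverted` (TRUE when the
#'   sign contradicts the mode), `convention`.
#' @export
net_rate <- function(c_t0, c_t24, volume, biomass, days = 1,
                     mode = c("consumption", "production"),
                     unit = "mol/day/mg DNA") {
  mode <- match.arg(mode)
  if (biomass <= 0) stopf("biomass must be > 0")
  if (days <= 0) stopf("days must be > 0")
  delta <- switch(mode, consumption = c_t0 - c_t24,
                  production = c_t24 - c_t0)
  rate <- delta * volume / biomass / days
  list(rate = rate, mode = mode, unit = unit, inverted = rate < 0,
       convention = "+ = consumption for substrates, + = production for products")
}

#' Lactate:glucose rate ratio
#'
#' Ratio of lactate production to glucose consumption. Pure aerobic
#' glycolysis converts one glucose into two lactates, so 2.0 is the
#' stoichiometric ceiling; a diagnostic note is attached when the ratio
#' exceeds it (other carbon sources feeding lactate).
#'
#' @param lactate_rate lactate production rate.
#' @param glucose_rate glucose consumption rate (nonzero).
#' @return the ratio; attribute `"note"` when > 2.
#' @export
lactate_glucose_ratio <- function(lactate_rate, glucose_rate) {
  if (glucose_rate == 0) stopf("glucose rate must be nonzero")
  ratio <- lactate_rate / glucose_rate
  if (is.finite(ratio) && ratio > 2)
    attr(ratio, "note") <-
      "ratio exceeds the glycolytic stoichiometric ceiling of 2"
  ratio
}

#' Signed percent change
#'
#' `(new - reference) / reference * 100`.
#'
#' @param reference_value nonzero baseline.
#' @param new_value new value.
#' @return signed percent.
#' @export
percent_change <- function(reference_value, new_value) {
  if (reference_value == 0) stopf("reference value must be nonzero")
  (new_value - reference_value) / reference_value * 100
}

#' Total ketone bodies
#'
#' Sum of acetoacetate and beta-hydroxybutyrate, the two hepatocyte-
#' derived ketone bodies.
#'
#' @param acac acetoacetate (e.g. mmol/g DNA, >= 0).
#' @param bohb beta-hydroxybutyrate (same units, >= 0).
#' @return TKB = AcAc + bOHB.
#' @export
total_ketone_bodies <- function(acac, bohb) {
  if (any(acac < 0) || any(bohb < 0))
    stopf("ketone concentrations must be >= 0")
  acac + bohb
}

#' Adenylate energy charge
#'
#' Atkinson's index of cellular energy status:
#' `(ATP + 0.5 ADP) / (ATP + ADP + AMP)`, bounded in `[0, 1]`.
#'
#' @param atp,adp,amp non-negative pool abundances (any common unit);
#'   alternatively a list with elements `atp`, `adp`, `amp`.
#' @return energy charge in `[0, 1]`.
#' @export
energy_charge <- function(atp, adp = NULL, amp = NULL) {
  if (is.list(atp)) {
    adp <- atp$adp; amp <- atp$amp; atp <- atp$atp
  }
  if (any(c(atp, adp, amp) < 0)) stopf("adenylate pools must be >= 0")
  denom <- atp + adp + amp
  if (any(denom == 0)) stopf("at least one adenylate pool must be > 0")
  (atp + 0.5 * adp) / denom
}

#' NAD+/NADH ratio
#'
#' @param nad_plus,nadh non-negative pool abundances; `nadh > 0`.
#' @return the quotient.
#' @export
nad_ratio <- function(nad_plus, nadh) {
  if (any(nadh <= 0)) stopf("NADH must be > 0")
  nad_plus / nadh
}

#' Group comparison of per-sample NAD+/NADH ratios
#'
#' Computes the ratio per sample and reuses the unpaired t-test to
#' compare two groups.
#'
#' @param nad_plus,nadh named numeric vectors per sample.
#' @param design study design.
#' @param group_a,group_b groups to compare.
#' @param welch use Welch's t-test.
#' @return list with per-group means and the test result.
#' @export
nad_ratio_test <- function(nad_plus, nadh, design, group_a, group_b,
                           welch = FALSE) {
  ratio <- nad_ratio(nad_plus, nadh)
  sa <- intersect(names(ratio), group_samples(design, group_a))
  sb <- intersect(names(ratio), group_samples(design, group_b))
  tt <- unpaired_t_test(ratio[sa], ratio[sb], welch = welch)
  list(mean_a = mean(ratio[sa]), mean_b = mean(ratio[sb]), test = tt)
}

#' Group-level flux summary from a media table
#'
#' Estimates per-well net rates from t0/t24 concentrations and
#' summarizes them per group as mean and SEM.
#'
#' @param media long media table (`sample_id`, `group`, `replicate`,
#'   `metabolite`, `timepoint_h`, `conc_mM`), e.g. from
#'   [generate_media_timecourse()].
#' @param design design with `biomass_mg_dna` and `volume_ml` per
#'   sample.
#' @param metabolite metabolite to quantify.
#' @param mode `"consumption"` or `"production"`.
#' @param days incubation days.
#' @return data.frame `group, metabolite, mode, rate, sem, n`.
#' @export
flux_summary <- function(media, design, metabolite,
                         mode = c("consumption", "production"),
                         days = 1) {
  mode <- match.arg(mode)
  m <- media[media$metabolite == metabolite, , drop = FALSE]
  if (!nrow(m)) stopf("metabolite '%s' absent from media table", metabolite)
  groups <- setdiff(unique(m$group), "cell-free")
  out <- lapply(groups, function(g) {
    wells <- unique(m$sample_id[m$group == g])
    rates <- vapply(wells, function(w) {
      c0 <- m$conc_mM[m$sample_id == w & m$timepoint_h == 0]
      c1 <- m$conc_mM[m$sample_id == w & m$timepoint_h > 0]
      b <- design$biomass_mg_dna[design$sample_id == w][1]
      v <- design$volume_ml[design$sample_id == w][1] / 1000
      net_rate(c0, c1, v, b, days, mode)$rate
    }, numeric(1))
    data.frame(group = g, metabolite = metabolite, mode = mode,
               rate = mean(rates),
               sem = stats::sd(rates) / sqrt(length(rates)),
               n = length(rates), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
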