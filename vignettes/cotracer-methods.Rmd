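---
title: "Methods: differential pools, dilution controls and discriminant 13C-ITUM in co-culture"
author: "cotracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential pools, dilution controls and discriminant 13C-ITUM in co-culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotracer)
```

## The problem

Untargeted LC-MS metabolomics of a mixed-cell culture measures pooled
metabolite abundances across every cell type in the well. When a tumor
line is grown on a hepatocyte–fibroblast feeder layer, a feature that
falls in the triple co-culture (SJH) relative to a control may reflect
a genuine metabolic interaction — or nothing more than dilution of one
compartment's pool by the added biomass. `cotracer` implements the
analysis stages needed to tell these apart in such a design, plus the
¹³C-tracing layer that localizes *where* glucose carbon is rerouted,
and a synthetic-data module that generates every input with planted
ground truth so each stage can be validated end to end.

## Differential pools and the 1T1 dilution control

Counts are first normalized to per-sample biomass (mg DNA); fold
changes are computed on group means of the normalized counts,
`log2(mean_a / mean_b)`, which matches volcano-plot convention. When a
single group mean is zero, a pseudo-count of half the smallest nonzero
count in the matrix is added to both means; with both means zero the
fold change is undefined and flagged rather than invented. Student's
pooled-variance *t* is the default (the convention of common
point-and-click packages for unpaired tests); Welch is a flag.
Zero-variance degeneracies resolve by convention (*p* = 1 for equal
means) instead of erroring, so a constant housekeeping feature cannot
abort a whole table.

The dilution control asks a sharper question: does SJH differ from a
literal 1:1 mixture of the HJ and SJ extracts? A 1:1 mix of
equal-volume extracts has, per feature, the arithmetic mean of the two
contributing replicates, so the in-silico control is
`(A_k + B_k) / 2` with pairing by replicate index.
`dilution_comparison()` deliberately uses **raw** *p* values at a low
threshold: it is a discovery screen whose hits are triaged downstream,
and its output metadata records that no multiplicity correction was
applied so the results cannot be mistaken for adjusted ones.
Timecourse fold changes against starting media report a cell-free
degradation control as an extra drift-adjusted column
(`log2_fc − log2 drift`), never as a silent substitution, because
spontaneous degradation at 37 °C (purine intermediates accumulate
measurably in cell-free wells) is a property of the media, not of the
cells.

## MIDs and natural-abundance correction

Isotopologues of an *n*-carbon metabolite appear at
*m/z* = *m/z*₀ + *k* · 1.0033 Da. Envelope assembly takes the nearest
feature within a ppm tolerance (default 5 ppm; configurable) and,
when retention times are present, within ±0.1 min of the M+0 feature,
since isotopologues co-elute. Exactly tied candidates raise an
ambiguity error naming both features; missing members are zero-filled
and flagged; a missing M+0 is an error because the envelope scale is
then unknown.

With natural ¹³C abundance *p* = 0.0111, a molecule truly carrying
*j* tracer carbons is observed at M+*i* with probability
`choose(n−j, i−j) · p^(i−j) · (1−p)^(n−i)` — the lower-triangular
correction matrix whose columns are probability vectors. The measured
envelope `y = C x` is inverted by **non-negative least squares**
rather than by `solve(C)`: on noisy envelopes plain inversion produces
negative fractions, violating the definition of a MID, while NNLS
guarantees non-negativity; the solution is then renormalized to sum
to 100. On noise-free data the two agree to machine precision (the
suite verifies inversion of 1000 random MIDs, up to 20 carbons, to
1e−6). Only carbon is corrected — H/N/O/S isotopes and tracer purity
are not modeled (purity is exposed as a parameter defaulting to 1)
— consistent with a correction basis of 1.11 % ¹³C.

## Discriminant ITUM

Each metabolite contributes one variable per isotopologue
(`S_M0 … S_M3` for serine), on the 0–100 enrichment scale;
metabolites with no enrichment in the co-culture group are excluded.
The enrichment floor is configurable (`min_enrichment`, default 0)
because a statistical definition of "significant enrichment" is a
study-level choice we do not hard-code. The pipeline default is PCA
on **z-scored** variables (correlation PCA), with a deterministic
sign convention — the largest-|loading| entry of each component is
made positive — so results are reproducible across BLAS/LAPACK
builds. "Top contributors to PC1" is unquantified in general use, so
selection offers `top:k` and `quantile:q` rules (default top quartile
by |loading|), always echoing the rule in the output.

One numerical point deserves emphasis. With *s* samples and *v*
variables, the top eigenvalue of the sample correlation matrix of
pure noise concentrates near `(1 + sqrt(v/s))²` (Marchenko–Pastur),
about 11 for the 9-sample × 47-variable matrices of a 3-replicate
design. z-scoring equalizes every column's variance, so a planted
shift confined to one metabolite contributes a correlated block of
at most its isotopologue count — eigenvalue ≤ 2 for the
M+0/M+3 pair that a single mass movement creates (closure forces at
least two columns to move). Correlation-mode PC1 therefore *cannot*
recover a single planted isotopologue at these dimensions, whatever
its magnitude. Recovery of a planted enrichment-magnitude shift is a
covariance-scale property, so the recovery simulations in the
acceptance suite run `run_pca(standardize = FALSE)`, where the
group-driven variance of the planted pair (~100 squared-percent)
dwarfs measurement noise and recovery is essentially certain. On real
data, where many isotopologues co-respond, standardized PCA is the
right default and remains ours.

The co-enrichment stage computes Pearson *r* over the SJ and SJH
samples only (the contrast of interest), with two-sided *p* from the
exact *t* transform at df = *n* − 2. Positive *r* reads as
co-enrichment in response to co-culture, negative as bifurcation of
labeled carbon. Clustering is agglomerative on distance 1 − *r*,
average linkage by default (the standard for correlation heatmaps;
complete and Ward available), with flat clusters cut at a
configurable height (default 1, i.e. blocks of positive correlation).

## Fuel utilization

NMR concentrations follow
`conc = (I_analyte / n_protons) / (I_ref / 9) × 0.3 mM`
for a TSP reference; net rates are
`Δconc × V / biomass / days`, signed by mode and flagged (never
clipped) when the sign contradicts the declared mode. The
lactate:glucose ratio uses the biomass-normalized rates — 3.86/2.50
reproduces the canonical Warburg-culture value of 1.54 — and carries a
diagnostic note above 2.0, the stoichiometric ceiling of pure aerobic
glycolysis. Energy charge uses Atkinson's definition
(ATP + ½ADP)/(ATP + ADP + AMP); the quantity's name alone does not fix
a formula, so the choice is recorded in the output. Units are echoed,
not converted: rates are reported in whatever unit system the inputs
carry (mol/day/mg DNA in the worked examples).

## Multi-omics integration

Gene × metabolite Pearson tables are computed over explicitly paired
samples. Cross-platform pairing sets the degrees of freedom of every
*p* value, so it is a named strategy (`by-replicate-index` default,
`group-mean` fallback) recorded in the output rather than an implicit
join. The two-stage filter — *p* < 0.001, then |R| > 0.98 — is a
conjunction, hence order-independent. DEG pre-filtering is consumed
as an input table; RNA-seq differential expression itself is out of
scope. Metabolite abundances enter on the raw normalized-count scale
by default, with a log option.

The |R| > 0.98 stage has a sample-size-dependent null leak rate: at
*n* paired samples the null density of *r* is proportional to
`(1 − r²)^((n−4)/2)`, giving P(|r| > 0.98) ≈ 6.9e−4 at *n* = 6 but
≈ 2e−5 at *n* = 8 and ≈ 7e−7 at *n* = 10. A 3-replicate design
therefore leaks ~7 false edges per 10⁴ null tests through the
correlation filter alone, and no implementation can do better while
honoring the filter definition. The network calibration and recovery
simulations in this package accordingly run at 5 replicates per group
(10 paired samples), where the filter's intended "≈ zero false
edges" behavior actually holds; the metabolomics simulations keep the
3-replicate design throughout.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions used across the
test suites: 3 replicates per group (5 for the expression module, per
the leak-rate argument above), biomass weights approximating
150k hepatocytes + 150k fibroblasts (+50k tumor cells) per well at
~6.6 pg DNA per cell, measurement noise multiplicative log-normal
with CV 0.1 for pool profiling (0.05 for tracing and expression
couplings, 0.01 for NMR-grade media quantification), and planted
effect sizes taken from the magnitudes the analysis is expected to
resolve (+2.59 log₂ on glutamyl-glycine, −2 on lactate, a 20-point
M+0→M+3 MID shift on glutathione, 98 genes coupled at population
*r* = 0.995). Mixed pools are biomass-weighted sums of per-cell-type
pools; interaction effects multiply the SJH expectation (log₂ shifts,
matching how fold changes are reported); the analytical 1T1 sample is
the mean of the HJ and SJ noise-free profiles with its own
measurement noise, which makes the dilution test's null calibration
exact by construction.

What the generator does **not** emulate: chromatographic peak shapes,
RT drift, adduct/in-source fragment redundancy, missingness
mechanisms, heteroscedastic intensity-dependent noise, or
between-replicate biological variance distinct from measurement
noise. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under the stated noise model —
not that any particular real dataset satisfies that model. The
per-isotopologue log-normal noise model also sets the attainable MID
recovery accuracy: at CV 0.02 a ~55 % fraction moves ~0.5 percentage
points at one sigma, so recovery is validated as a mean absolute
error below 0.5 points (and to 1e−6 noise-free), not as a worst-case
bound.

## Problem sizes and numerical conventions

The simulation suites use 100 seeds for calibration/recovery rates
(dilution null and detection, ITUM recovery, network sensitivity),
1000 random MIDs for the correction oracle, and ~3×10⁵ null tests for
network false-edge rates; these sizes put Monte-Carlo error well
inside the asserted bands while keeping the whole suite in tens of
seconds. Other conventions: seeds propagate explicitly
(identical config + seed is bit-identical); CV = 0 short-circuits to
exact factors of 1; BH adjustment delegates to `stats::p.adjust` and
is cross-checked against an independent step-up implementation;
PCA components never exceed `min(samples − 1, variables)`;
correlation matrices flag zero-variance variables as NA rather than
emitting NaN; cluster cuts and linkage are parameters, not defaults
hidden in code.

## Known limitations

* Envelope extraction assumes the feature table is already
  deisotoped no further than charge 1 and polarity-consistent; no
  adduct resolution is attempted.
* The NNLS correction is validated against the forward binomial
  model only; vendor implementations may differ in their treatment
  of truncated envelopes.
* The discriminant stage is unsupervised; it finds directions of
  variance, not labeled contrasts, and its selection should be read
  as hypothesis generation (as the permissive raw-*p* dilution screen
  should).
* Gene neighborhoods are exported as plain lists for external
  enrichment tools; no ontology testing is performed here.
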