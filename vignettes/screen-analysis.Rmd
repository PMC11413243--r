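---
title: "Analysing quantitative high-throughput viability screens with qhtscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing quantitative high-throughput viability screens with qhtscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtscreen)
```

## The problem

A quantitative high-throughput screen (qHTS) doses thousands of compounds
at several concentrations across a panel of cancer cell lines on 384-well
plates, reading out viability as the number of DAPI-stained nuclei per
well. Two systematic artefacts stand between the raw counts and a usable
potency readout: smooth within-plate spatial trends (evaporation-driven
edge effects, dispensing gradients) and plate-to-plate scale differences
(seeding, incubation and staining batch effects). On top of that, a hit
list built from cancer-line cytotoxicity alone is dominated by compounds
that are simply poisonous to everything; a screen aimed at
cancer-*specific* therapy needs a normal-cell counter-screen built into the
selection rule.

`qhtscreen` implements this chain for an LGSOC-style screen design: 12
cancer lines plus one normal epithelial control line, three doses
(0.1/1/10 µM), and plates carrying 14 DMSO (0.2 % vehicle) wells, 12
media-only wells and six cytotoxic positive controls.

## Normalisation model

Observed counts are modelled as multiplicatively decomposable,

count(well) ≈ baseline(plate) × S(row, col) × v(compound, dose) × noise,

with S a smooth spatial field. `loess_correct()` estimates S by locally
weighted regression of log counts on (row index, column index) — the log
makes the multiplicative model additive — and divides it out, rescaling by
the plate-level median of the fitted surface so the overall plate scale is
untouched. Defaults: span 0.75, local degree 1, all exposed in
`smoothing_config()`.

Three design points matter here:

* **Toxic-well exclusion.** Wells with counts below 50 % of the plate's
  pooled DMSO/media median are excluded from the fit and corrected
  afterwards with the surface evaluated at their position. The threshold is
  strict (`< 0.5`, configurable); a well at exactly half the reference is
  kept. This prevents genuinely lethal compounds from being smoothed away
  as "edge effects" while still removing the same spatial artefact from
  their measurement.
* **Fit population.** The surface is fitted on the unflagged *compound*
  wells only (`fit_wells = "compound"`). Control wells sit in fixed
  columns at full (negative controls) or fixed low (positive controls)
  viability, while the compound population at the screened doses averages
  somewhat below baseline; a fit over all wells therefore absorbs the
  column-wise contrast between the two populations into the "spatial"
  surface and systematically inflates corrected compound viabilities (we
  measured a 5–10 % median bias on simulated plates). Fitting the
  homogeneous compound population removes that bias; control wells are
  still corrected by the surface evaluated at their own positions, and the
  all-wells variant remains available as `fit_wells = "all"`.
* **Degenerate plates.** Plates with fewer than `min_fit_wells` (default
  30) usable wells skip smoothing with a warning and pass raw counts
  through, rather than fitting an unstable surface.

Smoothed counts are then divided by the plate's DMSO median
(`normalize_plate()`), pinning the DMSO median at 1 — exactly up to one
floating-point rounding step when the number of DMSO wells is even, since
the median is then a mean of two quotients — and binned by
`assign_viability_bin()`: high > 1.15, normal 0.8–1.15, moderate 0.5 to
< 0.8, low < 0.5. The boundaries 0.5 and 0.8 belong to the bin above and
1.15 to normal; only the outer boundaries are dictated by the bin
definitions, the inner conventions are fixed here so the partition is
total.

## Robust Z-scoring

The 10 µM dose is removed before scoring (`filter_concentrations()`): at
that concentration most library compounds show substantial non-specific
toxicity, so it carries little compound-specific signal (it returns in the
secondary-validation rule, where *failing* to kill at 10 µM is the
informative event). Each cell line is scored separately, per retained dose:
the scoring population is all compound wells of that (line, dose) slice,
controls excluded, and

z = (x − median(x)) / (c · MAD(x)),  MAD(x) = median |x − median(x)|.

The consistency constant c defaults to 1 — the raw MAD, as the formula is
conventionally written in screening practice — rather than the
normal-consistent 1.4826; it is configurable because both conventions are
in circulation. Whether the two retained doses should be pooled into one
scoring population per line is not uniquely determined by the screen
design; the per-dose reading matches per-dose hit counting and is the
default, with `pool_doses = TRUE` as the alternative. Slices with zero MAD
(e.g. constant values) raise an error naming the slice rather than
returning infinities.

Because the scoring population is compound wells of real libraries — most
of which do *something* mild — a robust Z of −2 corresponds to far more
than two counting-noise standard deviations; under the generator's
defaults it lands near 50 % cell death, which is the practical reading of
the cytotoxicity cutoff.

## Tiered hit selection

`select_hits()` applies, in order:

1. **High confidence**: z ≤ −2 at 1 µM in ≥ 50 % of the cancer lines
   *scored for that compound* (the denominator matters: pilot-only
   compounds are scored in fewer lines), and control-line z at 1 µM
   strictly above −2. The control clause is deliberately the complement of
   the cytotoxicity call: a compound exactly at z = −2 in the control is
   cytotoxic there and excluded. Compounds with no control-line score
   cannot demonstrate specificity and are excluded (reported separately).
2. **Low-dose advancement**: high-confidence compounds with mean
   cancer-line z at 0.1 µM ≤ −2.
3. **Moderate confidence**: compounds not in the high tier, with z ≤ −2 at
   0.1 µM in ≥ 50 % of scored cancer lines and control z ≤ −2 at 1 µM —
   i.e. exactly the low-dose-active compounds that the single control line
   vetoed. Relying on one normal line is the screen's weakest assumption,
   and this tier is the hedge against it.

The advanced and moderate tiers, deduplicated and ordered by tier then
compound id, form the secondary-validation list. All thresholds
(−2/+2, the 0.5 line fraction, doses) live in `pipeline_config()`, and
`control_filter = FALSE` reproduces the selection without the
counter-screen — by construction a superset, and the comparison
`aggregate_targets()` tabulates side by side.

Secondary validation (`secondary_validation_assessment()`) passes a
compound when normalised viability at 10 µM is strictly below 0.5 in at
least 3 of the 4 validation lines; the strict inequality mirrors the
low-viability bin (< 0.5), and lines missing from the data count against
the compound.

## Quality control

`percent_cv()` is 100·sd/mean with the sample (n−1) standard deviation;
`z_prime()` is the standard screening-window statistic
1 − 3(σ₊+σ₋)/|µ₊−µ₋|. `control_summary()` reports, per cell line and
control, the across-plate mean normalised count, the %CV and the per-plate
Z′ against the same plate's DMSO wells. The %CV default aggregation is the
mean over plates of the within-plate %CV across a control's replicate
wells: after per-plate median normalisation the per-plate *mean* of DMSO
values is pinned near 1, so a CV across plate means would be degenerate
for the very control it is meant to characterise. Controls carried at one
well per plate (cisplatin) fall back to the CV of their per-plate values;
`cv_method = "plate_means"` and `"pooled"` are available for comparison.
Z′ for positive controls uses the duplicate wells of each plate (n = 2 per
arm), so individual plate values are noisy; the summary reports their mean
and the count of failing (Z′ < 0) plates.

## The synthetic screen generator

`simulate_screen()` generates the design the analysis expects, with known
truth. Per compound: an effect class (default mix 85 % inactive, 6 %
cancer-specific cytotoxic, 6 % pan-cytotoxic, 3 % proliferative), Hill
parameters EC50 ∈ [0.03, 0.3] µM, Emax ∈ [0.75, 0.95], Hill slope ∈ [1, 2],
and a susceptible-line set — every line for pan toxins, a random ~75 %
subset of cancer lines (never the control) for specific ones. Viability is
1 − Emax·cʰ/(cʰ+EC50ʰ) in susceptible lines, a constant uplift for
proliferative compounds, and 1 − m·c/(c+1) for the "inactive" background,
where m is a per-compound half-normal (sd 0.6, capped at 0.95) mild
nonspecific inhibition. Expected counts are
seeding × growth × batch(plate) × S(row, col) × v, with seeding densities
from the study panel (350–1900 cells/well), growth factor 3 over the 72 h
assay, log-normal batch factors (sd 0.05), and a spatial field combining a
radial edge depression with a random low-order tilt, bounded at amplitude
0.15. Counts are negative-binomial with dispersion 0.006
(variance = µ + 0.006 µ²), i.e. ~8 % well-level noise, the middle of the
reported DMSO variability band; dispersion 0 switches noise off entirely
for exact-expectation tests.

Two generator choices deserve their rationale:

* **The mild nonspecific background** is what makes the simulated screen
  statistically faithful. With a perfectly inert background the population
  MAD collapses to counting noise, z = −2 would mean ~11 % cell death
  (nothing like its intended reading), and a clean control well would be
  vetoed by noise alone ~9 % of the time. A broad, mostly-mild,
  saturable-in-dose background reproduces the observed regime: z = −2 sits
  near half-maximal death, per-dose hit rates land near 13 %, and the top
  dose becomes non-specifically toxic for much of the library — the reason
  it is dropped from scoring.
* **Cytotoxic potency floors** (Emax ≥ 0.75 with EC50 ≤ 0.3 µM) ensure
  every labelled toxin reaches at least ~58 % kill at the 1 µM screening
  dose. Pan-toxicity that hovers exactly at the detection threshold is not
  a well-posed recovery target: whether the control filter catches it
  would be decided by noise, not by the method.

What the generator does **not** emulate: cell-line-specific positive
control potencies (fixed viabilities per control are used), correlated
biological replicate structure, growth-kinetic time courses, liquid
handling failures, or image segmentation errors. Recovery results on
simulations therefore demonstrate the pipeline's correctness and the
counter-screen's mechanism, not the biological hit rates of any real
library.

## Numerical and testing notes

Determinism: all generator randomness flows from a single integer seed and
the caller's RNG state is restored afterwards; pipeline outputs are
byte-identical across reruns with the same inputs and configuration. The
test-suite simulations use 3-line panels with 80–300 compounds (one to
three plates per line) for the per-stage properties, and the full
13-line × 200-compound default — ten seeds — for the end-to-end recovery
checks; the spatial-recovery check runs with noise disabled and evaluates
interior wells (rows C–N, columns 4–21), since loess extrapolation at the
outermost rows and columns is intrinsically less constrained. The
flat-plate identity and scoring oracle checks are asserted at 10⁻⁶ and
10⁻¹² respectively; the DMSO-median invariant at one part in 10¹²
(floating-point rounding of the even-count median).

## Limitations

The loess correction assumes the spatial artefact is smooth and
multiplicative; step artefacts (dispenser nozzle failures) violate it.
The robust Z reading of "≈50 % death" is a property of the compound
population, so it drifts for libraries with unusually high or low active
fractions. The counter-screen uses a single normal line scored once per
dose; its veto is one measurement deep, which is precisely why the
moderate tier exists. No dose–response (IC50) fitting is attempted from
three doses; potency ranking beyond the tier structure is out of scope.
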