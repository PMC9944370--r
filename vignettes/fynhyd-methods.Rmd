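---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fynhyd)
```

# Scope

`fynhyd` implements the inference chain used to characterize seasonal
water relations of co-occurring shrubland growth forms: half-hourly
micrometeorology → vapour pressure deficit, dew events and calibrated soil
moisture; heat-ratio sap flow → sap flux density, transpiration and canopy
conductance, normalized to an unstressed reference period; optical image
stacks of drying xylem → vulnerability curves, P50, safety margins and
predicted in-situ embolism; and the seasonal statistics layered on top
(recovery after rehydration, minimum water potentials, AIC model selection,
ANOVA with Tukey letters). Field protocols (pressure chambers,
psychrometer installation, scanner control) and radiation/energy-balance
modelling are out of scope.

# Micrometeorology

**Saturation vapour pressure.** The dew-point inversion fixes the Magnus
constants `A = 17.625`, `B = 243.04` °C but leaves the saturation-pressure
coefficient unstated; we use `e_s(T) = 0.61094 · exp(AT/(B+T))` kPa, the
coefficient published alongside those constants, so that
`dew_point(t, 100) = t` holds to machine precision (tested to 1e-9 over
−10…40 °C).

**Dew events.** "Periods without rainfall" is read in its smallest
defensible scope: `rain == 0` in the current half-hour interval. A record
is dew-flagged iff it is rain-free, leaf-wetness resistance < 400 kΩ, and
air temperature is within 0.5 °C of the dew point; consecutive flags merge
into one event whose duration closes the final half-hour. The detector is
tested for exact equality with a brute-force per-record rule evaluation
plus run merging.

**Daily summaries.** The midday window is fixed at 12:00–14:00 local
clock, mirroring the midday water-potential protocol; no timezone
conversion, no gap-filling. Days with fewer than 80 % of the 48 expected
intervals are flagged incomplete rather than imputed. Soil-probe depth is
carried as metadata only — the package does not try to reconcile probe
depths across deployments.

**Probe calibration** is ordinary least squares of gravimetric content
(g/g) on raw probe output, requiring ≥ 3 pairs and a non-constant
predictor. On the study's printed line (slope 1.53, intercept −1.54) with
5 % noise, the mean recovered slope over 100 replicates is within ±0.05
(an acceptance check).

# Sap flow

The heat-ratio conversion is `v_h = (k/x)·ln(ratio)` with thermal
diffusivity `k` (default 0.0025 cm² s⁻¹, a standard green-wood value) and
probe spacing `x` (default 0.5 cm). Exact gauge constants for the
`v_h → v_s → J_s` chain are instrument-specific and are therefore exposed
as two linear factors defaulting to identity; no wound correction is
applied for external non-invasive gauges (a multiplicative factor is
available). This is safe because every seasonal result the package reports
is normalized, so constant factors cancel.

**The conductance constant α.** The canopy-conductance relation
`G_sf = α·E_sf/VPD` is implemented verbatim with
`α = ρ_w·G_v·T_K` (`ρ_w` 1000 kg m⁻³, `G_v` 0.462 m³ kPa kg⁻¹ K⁻¹). As
printed, α is dimensionally awkward (it evaluates to ~1.4 × 10⁵ kPa, not
atmospheric pressure), so `gsf(..., alpha_mode = "barometric")` offers the
standard `E·P_atm/VPD` form. We deliberately do not guess the intent:
because normalized `G_sf` divides out any multiplicative constant, the two
modes give identical percent-of-reference series (tested to 1e-9), and
nothing downstream depends on the choice.

**Numerical guards.** Records with VPD at or below 0.1 kPa are masked
rather than divided (dawn/dusk blow-up); negative predicted transpiration
is floored at zero; days missing more than 10 % of half-hours are excluded
from daily totals.

**Reference normalization.** The "pre-stressed maximum" of early-season
mesic weeks is quantified as the *mean* daily value over the user-supplied
reference window (≥ 5 valid days); the mean is stable where the maximum is
noise-sensitive, and `statistic = "max"` remains selectable.

# Optical vulnerability

Consecutive frames are mean-normalized and differenced; supra-threshold
pixels are clustered by 8-connectivity; clusters below `min_cluster_px`
(default 10 px) are discarded as noise; a pixel is counted at most once.
Cumulative embolized pixels are converted to percent of the run total,
each event frame is assigned a water potential by linear interpolation in
the psychrometer timeline (never extrapolated), and the sigmoid
`PE = 100 − 100/(1 + e^{a(Ψ−b)})` is fitted by least squares with `b`
initialized at the interpolated 50 % crossing, `a` at −1, five jittered
restarts, and a BFGS polish. `Ψ` is MPa, negative under tension;
tension-positive input is rejected, not silently negated.

**Threshold default.** The threshold is `mean + 5·sd` of the first ten
difference frames — an automated stand-in for interactive thresholding —
but floored at 20 grey levels. The floor matters on very quiet baselines:
with near-zero early noise the 5-sd rule collapses toward zero, and
per-frame mean normalization leaves a small uniform background residue
(the frame mean shifts when several vessels fire at once) that would then
be thresholded as one giant spurious cluster. Twenty grey levels sit far
below genuine events (~80 grey levels in the synthetic stacks) and far
above the normalization residue for any plausible event density. A
user-supplied threshold is always used verbatim.

**Species curves.** Individuals are fitted independently; the species
curve defaults to the mean of fitted parameters (mean `a`, mean `b`),
with a pooled-point refit selectable. Whether published summary tables
used mean-parameter or pooled fits is generally ambiguous; mean-parameter
is the default because it weights individuals equally.

**Reported loss** is the curve evaluated at the seasonal minimum water
potential, reported raw and rounded to one decimal *half-up*, matching how
such tables are printed (base R's half-to-even would turn 0.45 into 0.4).
One known ambiguity is documented rather than resolved: methods texts
sometimes say minima are predawn values while the tabulated minima match
midday values; `table2_report()` simply uses whichever minima table the
caller supplies (predawn by default).

The proteoid archetype's sigmoid slope deserves a note: a species whose
printed predicted losses are 0 in both seasons gives no finite solvable
slope (the inversion needs a loss strictly inside (0, 100)). Its default
`a = −4` MPa⁻¹ is the shallowest slope that still reproduces both printed
zeros after one-decimal rounding at the printed minima and P50.

# Synthetic data: the stated world

The generators provide the statistical structure the analysis assumes, not
a reconstruction of any site's record.

**Weather.** Two preset seasons encode the study conditions: a dry summer
of 90 mm and a normal summer of 253 mm over 182 days (Oct–Mar), with three
> 20 mm events only in the normal season. Large events sit at fixed
fractions of the season (configurable); small (< 10 mm) events are a
thinned daily Bernoulli process at ~1–1.5 events/week; within a day, rain
falls in the afternoon; event amounts are rescaled so the season total is
met exactly. Diel temperature (12 °C amplitude around a 20 °C mean with
AR(1) day-to-day anomalies) and humidity (40 % amplitude, anti-phase) peak
at 14:00. Dew nights occur with probability 0.5 per night (dew was
near-ubiquitous at the emulated site, with events mostly > 2 h); on a dew
night the 01:00–05:00 records are saturated with a wet leaf sensor (100–
300 kΩ), so generator labels and the detector rule agree by construction
(tested at ≥ 95 %; in practice 100 % at zero noise).

**Soil.** A single-store bucket per layer: gains of
`infiltration_fraction` % per mm of rain, exponential decay toward a
residual at `drainage + evapotranspiration` per day, capped at capacity.
The deep (probe) layer takes only daily totals above 10 mm — small events
never reach 50–70 cm, which is what makes deep-rooted archetypes
insensitive to small pulses — while the shallow root-zone bucket (faster
gain and decay) takes everything. The zero-rain closed form
(`residual + (S₀ − residual)·e^{−kt}`) is tested exactly.

**Plant responses.** Predawn water potential is a saturating function of
root-weighted relative soil moisture (weights: ericoid 1.0 shallow,
proteoid 0.1, restioid 0.9), running from −0.2 MPa when wet to the
archetype's `psi_min_dry` (−4.0 / −1.5 / −1.9 MPa) under full depletion;
dew nights add a relative-moisture credit scaled by `dew_use_fraction`
(0.3 for the restioid, encoding the dew-use hypothesis as a switchable
mechanism; magnitude is a free parameter because quantitative deposition
amounts are not available). Midday water potential is predawn minus a
VPD-scaled, stomatally moderated drawdown — so predawn ≥ midday holds by
construction. Half-hourly heat pulse velocity is
`max_vh · light · rel^soil_sensitivity · VPD/(VPD+1)`; the soil exponent
(2 / 0.8 / 0.6) makes the shallow-rooted ericoid respond ≥ 5-fold to a
small dry-spell rain pulse while the deep-rooted proteoid moves < 1.4-fold
(both tested). Campaign observations add individual-level Gaussian noise
(0.05 MPa) in a way that never violates the predawn–midday ordering.

**Image stacks.** Vessels are 12-pixel blocks on a 6-pixel grid; each
draws its embolism water potential by inverse-CDF sampling from the
sigmoid with the archetype's (`a`, `b`), flips brightness once (100 → 180)
at the first frame whose scheduled Ψ drops below the threshold, and the
default drying schedule ramps from −0.1 MPa to just beyond the most
resistant draw over 144 five-minute frames. With 100 vessels and zero
noise the full image pipeline recovers a generating P50 of −5.68 MPa
within ±0.3 MPa in the mean over 50 replicates (an acceptance check, ~6 s
total).

**What a green test does not establish.** The generators have no spatial
soil heterogeneity, no energy-balance leaf temperatures, no radial or
azimuthal sap-flow variation, no scanner artefacts (drift, refocusing,
bubbles outside vessels), and rain/dew placement is schematic. Passing
tests demonstrate that the algorithms recover the structure they assume,
not that any particular field record would be reproduced.

**Reproducibility.** Every generator takes a seed in its config, is a pure
function of (config, seed), and records the seed in its output attributes;
the pipeline derives per-stage seeds from one master seed and writes them
to the run manifest.

# Seasonal analysis

"Pre-stressed" predawn water potential is quantified as the mean over the
reference window, with a rehydration tolerance of 0.1 MPa; recovery is the
maximum normalized value on/after the first post-minimum date within
tolerance, and a season with no qualifying date is flagged rather than
raised. Minimum water potentials are the most negative per-date species
means, reported with that date's between-individual SE.

Model selection follows the lowest-AIC-that-differs rule: candidates are
ranked by AIC (ties to fewer parameters) and a candidate is accepted only
if it beats every simpler nested rival in a likelihood-ratio test at
p < 0.05, falling back to the simpler rival otherwise. Mixed-model
candidates are refitted by maximum likelihood before comparison (REML
likelihoods are not comparable across fixed-effect structures); the
estimation itself is delegated to `lm()`/`lme4`. Temporal autocorrelation
in daily series may make these comparisons anti-conservative; no AR(1)
correction is applied by default. Tukey HSD runs on `stats::TukeyHSD`; the
compact letter display uses the insert-and-absorb algorithm and is
property-tested (groups sharing no letter always differ at α).

The assimilation–conductance relation is fitted as a saturating
rectangular hyperbola `A = A_max·g_s/(K + g_s)` by default (a second-degree
polynomial is selectable) — the conventional form where none is specified.
The conductance–water-potential envelope reports the Ψ at which gs falls
to 10 % of its observed maximum, by interpolation along the dry-down.

# Numerical conventions

- Rounding of reported percentages: one decimal, half away from zero.
- Daily integration of flux: rectangle rule on the regular half-hourly
  grid (`ΣJ_sΔt`), which equals the trapezoid rule for diel pulses
  vanishing at day boundaries (tested).
- Curve fitting: Nelder–Mead multi-start + BFGS polish on the residual sum
  of squares; non-convergence after five restarts raises an error carrying
  the point count and percent span.
- Degenerate inputs error early: constant predictors in calibrations,
  < 5 vulnerability points or < 20 percentage-point span, capacity ≤
  residual buckets, non-monotone drying schedules, water potentials above
  zero.

# Known limitations

Sapwood-area upscaling, radial sensor-depth integration, gap-filling of
meteorology, autocorrelation-corrected mixed models and vessel-length
corrections are not implemented. On-disk image stacks use plain-text PGM
frames with a CSV manifest rather than TIFF; stacks are normally held in
memory, and the text format keeps fixtures inspectable and portable.
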