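---
title: "Modelling maize organ morphology under increased plant density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling maize organ morphology under increased plant density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizecanopy)
```

## The problem

Maize grown at high sowing density competes for light, and the fully
expanded canopy responds organ by organ: laminae and sheaths narrow,
internodes stretch in the lower canopy and thin everywhere, and lamina
length shifts between lower and upper phytomers. Functional–structural
plant models (FSPMs) of the ADEL-Maize family reconstruct canopies in 3D
from per-phytomer organ dimensions, but classically at a single density.
`maizecanopy` implements a density-response layer for such models: given a
reference organ-size profile at 4.5 plants m⁻², it predicts the profile at
any higher density, builds the corresponding 3D canopy, and quantifies
agreement with field measurements.

## The response model

Six organ dimensions are modelled per phytomer (all in cm): lamina length
(LL) and maximum width (LW), sheath length (SL) and average width (SW),
internode length (IL) and diameter (ID). Phytomer ranks are counted
acropetally; ranks 1–5 senesce before full expansion and carry no modelled
morphology, so ranks 6–18 of an 18-leaf plant are modelled.

The percent change $Y$ of an organ's final size relative to its
reference-density size is, for the grouped phytomers,

$$Y_{o}(x, r) = A_o \ln(x) + B_o\, r + C_o, \qquad r \in \{6..11\} \cup \{13..18\},$$

with separate coefficient sets for the lower (6–11) and upper (13–18)
groups, and for the ear-bearing phytomer (rank 12, whose response differs
because the ear is the dominant sink there)

$$Y_{o}(x) = D_o\, x + E_o.$$

Here $x$ is the *density regressor*. The package defaults to the
increment convention $x = \mathrm{PD} - 4.5$ (plants m⁻² above the
reference): the source regressions plot change against the *increase* in
density, even though the equation prose names the density itself. Both
conventions are supported (`regressor_mode` of `response_params()`); the
increment is the default because it makes the reference density an exact
fixed point of the model. At exactly 4.5 plants m⁻² the equations are
bypassed (the log term is undefined at $x = 0$) and $Y = 0$ by contract.

Predicted sizes are applied multiplicatively,
$\mathrm{size}(d) = \mathrm{size}(4.5)\,(1 + Y/100)$, floored at zero.
Densities between the calibrated treatments (4.5, 6, 7.5, 9, 15
plants m⁻²) are allowed — the model is continuous — and densities above 15
are permitted but flagged as extrapolation with a warning.

The default coefficients (`default_params()`) are package constants for
the hybrid Zhengdan 958 and are never re-derived at run time. Refitting is
available through `fit_group()` (plain unweighted OLS on the design
$[\ln x, r, 1]$ or $[x, 1]$, via `stats::lm`), for recalibrating the
response to other hybrids or row configurations from a measurement table.

## Validation statistic

Agreement between simulated and observed organ sizes uses the normalized
root-mean-square error,

$$\mathrm{NRMSE} = \frac{100}{\overline{\mathrm{OBS}}}
  \sqrt{\tfrac{1}{n}\sum_i (\mathrm{SIM}_i - \mathrm{OBS}_i)^2},$$

in percent of the observed mean. One notational point deserves emphasis:
renderings of this statistic sometimes omit the radical over the
mean-square term, but "root mean square error" semantics require it, and
this package applies the square root. Quality bands are excellent
(≤ 10 %), good (10–20 %], fair (20–30 %], poor (> 30 %); band edges belong
to the lower band, so exactly 10 % is excellent. Replicates are averaged
per rank before pairing with the simulation (field comparisons are made
against per-rank treatment means), and derived quantities — leaf area
LA = 0.75·LL·LW and leaf insertion height LIH = cumulative IL — are
validated whenever their ingredients are observed.

## Canopy geometry

`build_plant()` stacks internode segments from the soil upward and
attaches a sheath and leaf per modelled rank. Choices where measurements
give no guidance:

* **Leaf area shape factor** 0.75 — the standard maize blade-area
  convention (blade area as a fraction of the LL × LW bounding
  rectangle); configurable in `leaf_area()`.
* **Insertion angles.** Measured anchors exist only at the three
  ear-adjacent ranks at the reference density: 18° one rank below the
  ear, 22° at the ear, 10° one above (angles from the vertical stem).
  Other ranks are linearly interpolated in rank between anchors and held
  at the nearest anchor outside the span, clamped to [5°, 40°]. Angles
  are held constant across densities — the ear-adjacent angles of this
  compact hybrid are approximately density-stable — with a per-rank
  override hook for cases such as the below-ear flattening reported at
  6 plants m⁻² and above, whose magnitude is unquantified.
* **Midrib curvature.** A quadratic Bézier leaving the stem at the
  insertion angle, with the tip dropped by `droop × LL` (droop
  coefficient default 0.3). No curvature measurements exist; with
  droop = 0 the midrib is exactly straight with length LL.
* **Azimuths.** Alternate-distichous: 180° flip per rank plus seeded
  uniform jitter of ±15°, reproducible for a fixed seed. Plant height is
  azimuth-invariant by construction.
* **Units and frame.** Organ space in cm, z-up, soil at z = 0; scene
  (plot) space in m; exported meshes are in cm and include a 100 cm
  vertical reference bar.

`build_canopy()` places plants on the field grid: rows 0.6 m apart,
intra-row spacing $1/(0.6 \cdot \mathrm{PD})$ m. This reciprocal rule
reproduces the reported field spacings at 6, 7.5, 9 and 15 plants m⁻²
(0.28, 0.22, 0.19, 0.11 m after rounding); at 4.5 plants m⁻² it gives
0.370 m where field notes say 0.38 m — the reciprocal is used and the
discrepancy simply documented. Meshes export as Wavefront OBJ with one
named group per organ per plant.

## The heatmap

`successive_change_matrix()` computes, per organ, the 13 × 4 matrix of
percent changes between *successive* densities (4.5→6, 6→7.5, 7.5→9,
9→15), which is what the canopy-size heatmap displays; note this is a
different referential from the regressions, which express change relative
to the 4.5 reference — `reference_change_matrix()` provides that variant.
`render_heatmap()` draws one panel per organ on a diverging red→green
scale with fixed limits −16 to +10 % (out-of-range cells are clamped to
the limits, so the rendered scale equals the configured one exactly), the
canopy top at the top, and optionally the absolute reference sizes as a
numeral column.

## Synthetic data: what it emulates and what it does not

No per-phytomer field profile is published in machine-readable form, so
`generate_base_profile()` emulates one: each organ's size over ranks 6–18
is a Gaussian-in-rank bump,
$\mathrm{size}(r) = \mathrm{peak} \cdot e^{-(r - r_\mathrm{peak})^2 / 2w^2}$,
with defaults chosen as realistic maize magnitudes (LL peaking at 80 cm
around rank 12, LW 10 cm @ 13, SL 18 cm @ 10, SW 3 cm @ 10, IL 14 cm @
14, ID 2.2 cm @ 8). These are plausible, not calibrated — the true
reference profile exists only graphically.

`generate_observations()` emulates the destructive-sampling structure of
the field trial: 5 densities {4.5, 6, 7.5, 9, 15} × 3 replicates × 13
ranks × 6 organs, with multiplicative Gaussian noise
$v = \hat v (1 + \varepsilon)$, $\varepsilon \sim N(0, \sigma)$, default
σ = 2 %. Multiplicative noise is used because organ sizes are positive
and measurement error scales with size; values are truncated at zero
(with a log note) in the rare large-σ case. One master seed drives
deterministic per-density streams.

What passing tests on this generator do **not** show: real profiles are
not exactly Gaussian in rank (LL is left-skewed), real replicate error has
spatial structure within plots, and real organ responses deviate from the
fitted equations (the published fits have R² ≈ 0.65–0.99). Round-trip
tests therefore establish correctness of the *machinery* — that the
pipeline recovers whatever response generated the data — not field
predictive accuracy, which requires independent measurements.

## Numerical and statistical choices

* OLS is unweighted and unregularized; R² = 1 − SSE/SST, undefined (NA)
  for degenerate SST. Grouped fits demand ≥ 3 points spanning ≥ 2
  regressor values and ≥ 2 ranks; ear fits ≥ 2 distinct regressor values;
  anything less is a singular-design error, not a silent NA.
* Observed relative changes default to the table's own reference-density
  means as the denominator (all a field campaign provides). In simulation
  studies the true reference profile can be passed instead
  (`observed_relative_change(..., reference = )`): a shared noisy
  denominator injects errors correlated across densities, which breaks
  the independence assumption behind OLS standard errors. The package's
  stochastic coverage suite uses the known reference for exactly that
  reason, and its 3-standard-error check then covers ≥ 95 % of 200
  seeded trials.
* Zero denominators in change matrices yield flagged NA cells, not
  errors; zero observed means make NRMSE a hard error (the statistic is
  undefined).
* Test problem sizes: the full trial structure (1 170 observation rows)
  per generated table, 200 trials in the stochastic suite, single-plant
  or single-row scenes for mesh checks — the whole suite runs in well
  under a minute.

## Known limitations

Only final (fully expanded) morphology is modelled — no thermal-time
organ kinetics, phenology, or weather response. The response coefficients
are hybrid- and row-configuration-specific. Leaf angles beyond the three
ear-adjacent anchors and the midrib curvature are geometric conventions,
not measurements. Light interception and photosynthesis are out of scope,
though the exported 3D scenes are intended as input to such models.
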