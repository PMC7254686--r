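---
title: "Inferring speed and gait from bipedal trackways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring speed and gait from bipedal trackways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackgait)
library(dplyr)
```

## The problem

A trackway records where an animal's feet fell, and nothing else. To say how
fast the trackmaker moved, or which gait it used, the stride length
`l_stride` measured from the footprints must be translated into a speed `U`
— and that translation needs information the trackway does not contain: the
animal's hip height, the substrate it moved over, and the gait-specific
relationship between stride and speed. `trackgait` implements both families
of translation used for bipeds, and the machinery to ask how well each one
works when a ground truth is available.

The package is organised around the Svalbard rock ptarmigan (*Lagopus muta
hyperborea*), an Arctic bird that spends half the year walking, grounded
running and aerial running over snow — a substrate that records essentially
every step. For such a bird, matched observations exist: a video-measured
speed for the same locomotor bout whose trackway was photographed. That
pairing is what lets prediction error be measured rather than assumed.

## The two model families

**General (Froude-based) predictors.** Dynamic similarity says geometrically
similar animals moving at equal Froude number `Fr = U²/(g h)` move alike, so
cross-species regressions can predict speed from the relative stride
`λ = l_stride / h`:

* walking band (`λ < 2.0`): `U = 0.25 g^0.5 l_stride^1.67 h^−1.17`
  (`alexander_speed()`);
* running band (`λ ≥ 2.9`): `U = sqrt(g h (l_stride/(1.8 h))^2.56)`
  (`thulborn_wade_speed()`), which collapses to `sqrt(g h)` exactly at
  `l_stride = 1.8 h`;
* trotting band (`2.0 ≤ λ < 2.9`): the arithmetic mean of the two
  (`trot_speed()`).

`froude_model_speed()` applies the piecewise recipe as published: no
smoothing at the thresholds, so the predicted speed is discontinuous there
by construction. Boundary points belong to the faster band — once `λ`
*reaches* a threshold the gait has shifted. The exponents (1.67, 2.56,
−1.17) and coefficients (0.25, 1.8) are fixed constants of the named models,
not fitting parameters. The band thresholds default to 2.0 and 2.9 but are
arguments, because the grounded-to-aerial transition is known to be
species-dependent.

**Species-specific calibration.** When matched stride/speed data exist for
the species itself, a per-gait ordinary least-squares fit of measured speed
on stride length (`fit_gait_model()`) beats any cross-species predictor.
Fitting is always per gait, never pooled: the speed–stride slope differs
between walking, grounded running and aerial running, and pooling would
average incompatible mechanics. Records without a measured speed are
excluded with a message; no weighting by the number of strides averaged is
applied (the measurement protocol gives no basis for weights).

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `h` (hip height) | m | 0.1727 | literature value for a male ptarmigan; proxied as 4× foot length (`hip_from_footlength()`) when the animal is unavailable — a proxy that can err by a factor of 1.5 or more, entering every Froude-based estimate as `h^−1.17` or `h^0.5` |
| `g` | m/s² | 9.81 | standard gravity; all predictors scale as `g^0.5` |
| band thresholds | — | 2.0, 2.9 | comparative-literature transition values of `λ`; configurable because they are not species-safe |
| PI `level` | — | 0.95 | the conventional prediction-interval coverage; configurable since published interval bands rarely state their level |

## Prediction intervals

`predict_with_interval()` returns the two-sided t interval for a *new
observation*: `fit ± t(df = n−2) · s · sqrt(1 + 1/n + (l − l̄)²/Sxx)`. It
accounts for residual scatter plus the uncertainty of the fitted line, so it
widens hyperbolically away from the mean training stride. The interval is
computed from stored sufficient statistics (`n`, `l̄`, `Sxx`, `s`), which is
why a model reloaded from the plain-text model file
(`write_gait_models()`/`read_gait_models()`) predicts identically to a fresh
fit; the test suite checks the formula against `stats::predict.lm` as an
independent route. Gaussian residuals are an assumption, not a fact, which
is why `residual_normality()` (Shapiro–Wilk on the fit residuals) is part of
the calibration surface.

## Gait classification and ambiguity

Two classifiers are provided:

* `classify_relative_stride()` applies the λ thresholds; it always returns a
  single band and is exactly as trustworthy as the thresholds are for the
  species at hand.
* `classify_species_ranges()` assigns every gait whose *observed calibration
  stride range* contains the stride. Gaits overlap in stride length while an
  animal transitions, so a stride can match two ranges at once: such
  trackways are flagged `ambiguous`, and `unclassifiable_fraction()` is the
  proportion flagged. Strides outside every range are assigned the nearest
  range and flagged `out_of_range`, never silently clamped.

The default ambiguity criterion is range membership of the stride itself,
because the scientific claim at stake is about what can be inferred "from
the trackway's stride length alone". A stricter mode
(`use = "speed_interval"`) additionally requires the competing gaits' speed
prediction intervals to overlap at that stride before keeping the
ambiguity; it can only resolve ambiguity, never create it, and is offered
because published ambiguity fractions do not always state which criterion
was used.

## Error analysis

`percent_error()` is the signed relative error `100 (predicted −
measured)/measured`: negative means the model underestimated the measured
speed. `summarize_errors()` reports the mean *absolute* error as the
headline accuracy figure — signed errors span both signs, so their absolute
mean is what measures accuracy — alongside the signed mean, SD, range and a
histogram binned to width 10 with edges anchored at multiples of 10
(closed-left, open-right). Both interpretations of "mean error" are thereby
available to the reader.

## The synthetic-data generator

`default_gait_specs()` encodes the study conditions the package simulates:

* generating lines `U = 3.20 l − 0.23` (walking), `U = 2.34 l + 0.34`
  (grounded running), `U = 4.29 l − 0.03` (aerial running);
* sample sizes n = 48, 56, 61, plus a 50-trackway hold-out drawn
  multinomially in those proportions;
* stride ranges 0.225–0.322, 0.312–0.436, 0.373–0.646 m, obtained by
  inverting the published predicted-speed endpoints through each gait's own
  line (forward substitution recovers the published speed ranges to the
  printed precision);
* Gaussian residual SDs 0.092, 0.168, 0.180 m/s, back-calculated as the
  published prediction-interval half-widths divided by 1.96. This is an
  acknowledged approximation: a prediction-interval half-width slightly
  exceeds 1.96 residual SDs (it also carries the fit uncertainty), so these
  SDs are very mildly conservative upper bounds on the residual scatter.

Stride lengths default to uniform draws over each range — the
least-assumption choice given that the real stride distribution is
unpublished — with a truncated-normal alternative behind the
`stride_distribution` knob. `generate_trackways()` sets the video speed from
the *true* stride and then perturbs the *recorded* stride by an optional
Gaussian measurement error, mimicking the fact that the analyst measures a
photographed trackway, not the stride the bird actually took. Each gait
draws from its own seeded substream (keyed on the gait label), so adding or
removing a gait spec does not reshuffle the draws of the others.

What the generator does *not* emulate: substrate compliance and its
gait-dependent effect on stride (the main suspected cause of the grounded
running gait's low r² in the field), sex and ontogenetic structure, and any
correlation between measurement error and stride length. Passing tests
therefore demonstrate that the pipeline's statistics behave correctly under
the stated generating model — parameter recovery, interval coverage,
ambiguity accounting — not that real snow trackways satisfy that model.

```{r overlap}
specs <- default_gait_specs()
specs

trk <- generate_trackways(seed = 1)
models <- fit_gait_models(trk)
glance(models)
unclassifiable_fraction(trk, models)
```

Under these defaults the adjacent gaits' stride ranges overlap, and with
uniform strides the expected ambiguous fraction is the n-weighted mass of
the overlap intervals — about 0.32, the same order as reported ambiguity in
field trackway studies. The exact published fractions (and the published
per-model error means and r² values) are properties of the unpublished raw
dataset and are deliberately not targets of the simulation.

## Numerical choices

* Degenerate inputs: fewer than 3 usable records or zero stride variance
  abort with a specific error; zero residual variance yields a zero-width
  prediction interval and a flagged (`degenerate = TRUE`) normality result
  rather than an error, since exact fits arise legitimately from noiseless
  synthetic data. Residual SDs below 1e-12 are treated as exact fits.
* Units are fixed to metres and m/s throughout; nothing auto-detects units,
  because silent conversion is a bug source.
* The gait vocabulary is closed (`walking`, `grounded_running`,
  `aerial_running`); `"trot"` is accepted on input and normalized to
  `grounded_running` with a message, since the literature's trot band maps
  onto this species' grounded run.
* Simulation sizes in the test suite (500 replicate fits for parameter
  recovery, 2000 draws for interval coverage, 200 replicates for the
  normality null) were chosen so Monte-Carlo standard errors are several
  times smaller than the tolerances being checked.

## Limitations

The calibrated models are ptarmigan-specific and substrate-specific: a
species-specific model built on snow trackways is the *best case* for
trackway inference, and even it leaves roughly 10% mean absolute error in
speed and a quarter to a third of trackways gait-ambiguous. Applying the
general predictors to extinct bipeds inherits, on top of that, the hip
height proxy error and stride-band thresholds that birds demonstrably do
not all share. The package quantifies these limits; it cannot remove them.
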