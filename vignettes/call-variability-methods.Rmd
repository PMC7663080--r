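---
title: "Measuring spatial and temporal variability in frog advertisement calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial and temporal variability in frog advertisement calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callvar)
library(dplyr)
```

## The question

Male frogs advertise with species-specific calls, yet two key call traits —
call duration (s) and peak frequency (Hz, the frequency at maximum power) —
vary considerably among individuals of the same species. How much of that
variability a study *measures* depends on how it sampled: how many
individuals, how widely they are spread in space, and how widely in time
within the breeding season. `callvar` quantifies these effects by bootstrap
resampling of per-individual call records, and asks, across species, whether
species with larger geographic ranges or larger bodies show stronger
spatial/temporal structuring of call variability.

The unit of observation is one recorded individual: species, location
(WGS84), date, and the individual's mean call duration and peak frequency
over the 3–10 consecutive calls analysed for it. Working with per-individual
means deliberately targets among-individual variation, not within-individual
variation.

## Pipeline

1. **Ingest and filter** (`read_call_table()`, `thin_unique_location()`,
   `thin_min_distance()`). Spatial thinning guards against recording the
   same individual twice: either keep one record per exact coordinate, or a
   greedy 1-km minimum-separation pass for densely sampled species. Both
   rules are deterministic: records are scanned in (date, individual id)
   order and earlier records win, so the same input always yields the same
   thinned set. Per-call tables are collapsed to individuals by
   `aggregate_individuals()` (arithmetic means; at least 3 calls, at most
   the first 10 by call index, extra calls dropped with a warning).

2. **Bootstrap** (`fixed_n_resample()`, `resample_study()`). For each
   species, 1,000 samples of N = 20 individuals are drawn with replacement,
   and each draw is summarised by four parameters:
   the sample SD of call duration; the sample SD of peak frequency; the
   convex-hull area (km²) of the draw's recording locations; and the
   intra-annual span in days between the first and last individuals within
   the (relativised) breeding season. N = 20 is where the sample-size curve
   (below) flattens. Sample SDs use the n−1 denominator throughout.

3. **Models** (`zscore_within_species()`, `fit_species_lm()`,
   `fit_pooled_lmm()`, `fit_meta_regression()`). All four parameters are
   standardised to intraspecific z-scores so species on very different
   scales are comparable. Four comparisons are fitted — each SD against
   hull area and against day span. Per species this is an OLS fit whose
   slope, on z-scored data, equals the Pearson correlation (a tested
   identity). Across species, a linear mixed model with a species random
   intercept (REML, `lme4`) estimates the overall effect; the reported t is
   slope/SE with a two-sided p on n−2 residual df (6 species × 1,000 draws
   gives df = 5,998). Finally, a meta-regression asks whether per-species
   slopes are linear in range size (km²) or maximum male snout–vent length
   (mm), in raw units with an intercept.

4. **Sample-size curve** (`sample_size_curve()`). For N = 2…48, 1,000
   bootstrap samples per N, the curve reports the mean absolute deviation
   of each sample's SD from the full data's SD. 48 is the default ceiling
   because it matches the smallest per-species sample the design
   anticipates. Root-mean-square deviation is available via
   `deviation = "rmse"`; the qualitative shape is identical, so the more
   robust absolute deviation is the default. The curve falls steeply up to
   roughly N = 20 and flattens after — the basis for the N ≥ 20 sampling
   recommendation.

## Geographic and temporal metrics

*Distance* is haversine on a sphere of radius 6371.0088 km (IUGG mean).
*Hull area* projects the points with a Lambert azimuthal equal-area
projection centred on their centroid and takes the planar convex-hull area;
an equal-area projection makes "area in km²" well defined, and at
intra-range extents (< 500 km) it agrees with a spherical-excess oracle to
well under 1%. Degenerate sets (fewer than three distinct, non-collinear
points) have area 0. Because the projection recentres on the input's
centroid, adding a point can perturb the area by O((extent/R)²) — about
0.1% at 200 km — which is why monotonicity under point addition is checked
to that tolerance rather than exactly.

*Season-relative days* live on a fixed 365-day year (Feb 29 counts as day
59, keeping relative days identical across years). Each species gets a
season clock: within-year breeders are anchored at Jan 1; year-spanning
breeders (austral summer: the season crosses New Year) are anchored at the
first observation of the breeding season; year-round breeders are anchored
at Jan 1 with the span capped at 364 since "a season" has no boundary for
them. For year-spanning species the anchor is derived as the observed
day-of-year that begins the tightest circular window containing all
observations (equivalently, the day ending the largest empty gap in the
annual circle). A naive minimum day-of-year would land mid-season — early
January for a November–March breeder — and wreck the relativisation; the
circular rule recovers the actual season start from the data.

## The synthetic study generator

`synth_species_config()` / `generate_species()` produce records with known
structure so every stage can be verified against ground truth:

- individuals placed uniformly (equal-area, √-radius sampling) in a disc of
  configurable radius;
- dates uniform in a season window, wrapping the calendar year when the
  window does;
- expected trait values = species base + an east–west spatial gradient
  (per 100 km) + a within-season drift (per 100 days) — an explicit
  isolation-by-distance/time structure;
- independent Gaussian individual noise on top, with values clipped
  positive (warning) in the rare case noise crosses zero.

The gradient acts along the east–west axis by default so the induced
area–variability relation has a simple analytic expectation; an isotropic
(radial) option exists. Everything is a pure function of the configuration,
including the seed; per-species seeds derive from a master seed plus a hash
of the species name, so adding a species never perturbs another's records
or draws.

`default_study_preset()` supplies a six-species study whose magnitudes echo
the published table for the six study species: per-species sample sizes
(123, 221, 82, 232, 48, 56), base duration/frequency at the published
means, disc radius `sqrt(range/π)` from the published range sizes, noise
SDs at two-thirds of the published SDs with gradient and drift supplying
roughly the remaining spread, and season types taken from the species'
natural history (the two winter breeders within-year, the three summer
breeders year-spanning, one year-round breeder). These are presets that
make synthetic output visually comparable to the real study's figures, not
claims about the populations.

What the generator does **not** emulate: uneven spatial clustering of
citizen-science submissions, recording-quality heterogeneity, temperature
effects on call traits, non-Gaussian trait distributions, or spatial
autocorrelation beyond the smooth gradient. Passing tests therefore show
the pipeline recovers structure *of this idealised kind*; they do not show
the real data meet these assumptions.

## Acoustics

For audio-based measurement the package mirrors standard spectrogram
practice: Hann window of 512 samples with 50% overlap (93.75 Hz bins at
48 kHz), a zero-phase band-pass (4th-order Butterworth run forward and
backward) to cut out-of-band noise without shifting note boundaries, and
peak frequency taken from the selection-averaged power spectrum — averaging
across frames before the argmax is robust to single-frame noise. Duration
is the selection length. `detect_notes()` replaces manual selection for
synthetic fixtures: a 10-ms moving-average envelope thresholded at −20 dB
relative to the clip's peak, with runs closer than 50 ms merged.

`synthesize_call_audio()` shapes each tone burst with a Tukey envelope
(5-ms Hann ramps, flat sustain). A full-burst Hann envelope would put the
−20 dB crossing about 10% of the burst duration inside the burst, making
envelope-detected durations systematically short; with short ramps the
crossing error is bounded by the ramp length, so detected durations land
within the hop-plus-smoothing tolerance.

## Numerical and design choices

- **Deviation statistic.** The sample-size curve's "deviation of measured
  from actual variability" is the mean absolute deviation of per-draw SDs
  from the full-data SD ("actual" = the species' full analysed-record SD);
  RMSE is a documented alternative, not the default.
- **Degenerate variables.** A parameter constant within a species z-scores
  to all zeros and is flagged; fits involving it are reported with status
  `"degenerate"` rather than silently fitted.
- **df convention.** Species OLS fits report n−2 residual df (998 at 1,000
  draws); the pooled mixed model reports n_obs−2, and meta-regressions
  n−2 = 4 for six species.
- **Random effects.** Random intercept only: the cross-species question is
  about a common slope, and the n−2 df convention is consistent with two
  fixed-effect parameters.
- **Tie-breaks.** All order-dependent operations (duplicate-coordinate
  retention, greedy distance thinning) fix (date, individual id) ascending
  order.
- **Problem sizes.** The test suite and the acceptance script use the
  six-species preset at 1,000 bootstrap replicates for the end-to-end run
  and the curve; parameter recovery uses 20 gradient datasets and 20 null
  datasets of 4 species × 80 individuals at 400 replicates — sizes chosen
  to keep Monte-Carlo error comfortably inside the tested margins.
- **Recovery scenario.** The parameter-recovery check uses a gradient of
  300 Hz per 100 km against 100 Hz individual noise over a 150-km disc, so
  spatially driven spread (~225 Hz) dominates noise and a positive pooled
  area–SD slope is statistically expected in essentially every dataset.

## Known limitations

- **Bootstrap coupling under the null.** Draws that happen to repeat
  individuals have both a smaller convex hull and a smaller n−1 SD, so even
  with zero spatial gradient the pooled area–SD slope has a small positive
  expectation (empirically ≈ +0.01 on the z-scale in the null scenario
  above, versus ≈ +0.29 with the recovery gradient). This is a property of
  with-replacement resampling of a finite set, not of the estimation code;
  any analysis built on this resampling design shares it. Null-calibration
  checks over 20-dataset batches are correspondingly noisy.
- **Projection recentring.** Hull areas are comparable within a species but
  are not a fixed-projection quantity; absolute areas may differ from other
  software by a fraction of a percent.
- **Year-round breeders.** "Days between first and last individuals within
  a breeding season" is not well defined without a season; collapsing years
  and capping at 364 is a convention.
- **Intra-annual span ignores distribution.** The span is max − min of
  relative days; a sample bunched near one end of the season has the same
  span as one spread evenly.
- **Acoustic scope.** Detection and measurement are validated on clean
  synthetic tones; no claim is made for noisy field recordings, which the
  original workflow handled by manual selection and quality grading.

## A worked miniature

```{r mini, eval = FALSE}
preset <- default_study_preset(master_seed = 1)
study <- generate_study(preset$configs, preset$profiles)

bundle <- run_full_analysis(study$records, study$profiles,
                            n = 20, reps = 1000, master_seed = 1)
glance(bundle)
tidy(bundle) |> filter(kind == "pooled_lmm")
autoplot(bundle$curves)
```
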