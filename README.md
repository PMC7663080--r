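# callvar

Bootstrap analysis of intraspecific variability in frog advertisement
calls: how the spread of call duration and peak frequency measured from a
sample of individuals depends on how many individuals were sampled, how
large a geographic area their recording locations span, and how far apart
in the breeding season they were recorded — and whether those effects
scale with species range size or body size.

It is written for bioacousticians and macroecologists working with
per-individual call measurements (for example from validated
citizen-science recordings), and for anyone designing a call-description
study who wants to know how many individuals are enough.

## The method

Each record is one individual: species, location, date, and mean call
duration and peak frequency over the 3–10 calls analysed for it. After
deterministic spatial thinning (one record per coordinate, or a greedy
≥ 1 km separation pass), the analysis is resampling-based:

- **Sample-size curve.** For N = 2…48, draw 1,000 bootstrap samples of N
  individuals and record the mean absolute deviation of each sample's SD
  (duration; peak frequency) from the full-data SD. The curve falls
  steeply to about N = 20 and flattens — the basis for recommending
  samples of at least 20 individuals.
- **Fixed-N bootstrap.** Draw 1,000 samples of N = 20 per species and
  summarise each draw by four parameters: SD of call duration, SD of peak
  frequency, convex-hull area of the locations (km², equal-area
  projection), and the intra-annual day span within the (relativised)
  breeding season.
- **Three model layers** on intraspecific z-scores, for the four
  comparisons SD(duration) ~ area, SD(duration) ~ span, SD(freq) ~ area,
  SD(freq) ~ span:
  per-species OLS (on z-scores the slope is the Pearson correlation;
  24 models for six species); a pooled linear mixed model with a species
  random intercept (REML, t = slope/SE, df = n − 2); and meta-regressions
  of the per-species slopes on range size (km²) and maximum male SVL (mm).

A synthetic-data module generates studies with known spatial gradients,
seasonal drift and noise (plus tone-burst audio with exact ground-truth
selections), so every stage is verifiable without any field data. An
acoustics module measures duration and peak frequency from WAV audio under
standard settings (Hann window 512, 50% overlap, zero-phase band-pass).

## Worked example

```r
library(callvar)
library(dplyr)

preset <- default_study_preset(master_seed = 1)
study  <- generate_study(preset$configs, preset$profiles)

bundle <- run_full_analysis(study$records, study$profiles,
                            n = 20, reps = 1000, master_seed = 1)
bundle
#> <callvar_analysis> 6 species, 762 records (seed 1)
#>   24 species fits, 4 pooled LMM fits, 8 meta-regressions
#>   fixed-N bootstrap: n = 20, reps = 1000; curves over n = 2..48

tidy(bundle) |> filter(kind == "pooled_lmm") |>
  select(response, predictor, slope, se, t_stat, df_resid, p_value)
#>      response predictor  slope     se t_stat df_resid  p_value
#> 1 sd_duration      span 0.0190 0.0129   1.47     5998 1.42e-01
#> 2 sd_duration      area 0.0826 0.0129   6.42     5998 1.47e-10
#> 3     sd_freq      span 0.1219 0.0128   9.51     5998 2.66e-21
#> 4     sd_freq      area 0.0656 0.0129   5.09     5998 3.66e-07
```

Each pooled row is the cross-species effect of one sample property on one
kind of call variability, on the z-scale: here, bootstrap samples spanning
a larger hull area or a longer stretch of the season measure systematically
more variability — the generator's built-in isolation-by-distance and
seasonal-drift structure, recovered by the pipeline.

The per-species sample-size curve shows why small samples mislead:

```r
bundle$curves |>
  filter(species == "Crinia insignifera", n %in% c(2, 5, 10, 20, 48))
#>              species  n reps deviation_duration deviation_freq
#> 1 Crinia insignifera  2 1000            0.02303          161.3
#> 2 Crinia insignifera  5 1000            0.01115           89.4
#> 3 Crinia insignifera 10 1000            0.00730           58.2
#> 4 Crinia insignifera 20 1000            0.00473           39.4
#> 5 Crinia insignifera 48 1000            0.00309           25.1

autoplot(bundle$curves)   # deviation vs N, one line per species
```

At N = 2 a sample's measured SD of peak frequency is off by ~161 Hz on
average; by N = 20 that error has fallen to ~39 Hz, and gains beyond 20
are marginal.

File-based workflows go through the configuration entry points
(`cmd_simulate()`, `cmd_analyze()`, `cmd_curve()`; YAML config, CSV/JSON
outputs, manifest with the seed) or the wrapper script
`inst/cli/callvar.R`.

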