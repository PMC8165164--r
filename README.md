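# mirrorforage

Pose-trajectory analysis of mirror and social foraging experiments in birds.

`mirrorforage` implements the full analysis chain for an arena experiment in
which focal birds forage next to a separation panel that is either an opaque
wall, a mirror, or a transparent barrier with a stranger bird behind it
("Wall", "Mirror", "Stranger" conditions). The question is behavioural:
does the bird treat its mirror image like a stranger (social facilitation,
vigilance, threat displays) or like a wall? The package covers:

- **Synthetic data generation** — a trajectory and ethogram simulator whose
  defaults emulate the full study design (8 birds × 3 conditions × 6 sessions
  of 600 s at 30 fps in a 50 × 60 cm arena), with known ground truth for every
  quantity the analysis estimates.
- **Tracking I/O** — reading and writing markerless pose-tracking CSV files
  (three header rows: scorer / bodyparts / coords; `x, y, likelihood` triplets
  per bodypart), session manifests, and pixel-to-cm arena calibration.
- **Kinematics** — initial-segment trimming, likelihood filtering with
  gap interpolation, LOESS smoothing, feeding-bout detection, latency to
  feed, log activity rate, and the body-orientation index.
- **Condition comparison model** — a Bayesian dual random-walk state-space
  model comparing two conditions' orientation time courses, fitted by a
  custom Gibbs sampler (compiled forward-filter backward-sampling for the
  latent states, slice sampling plus ancillarity–sufficiency interweaving for
  the scales).
- **Behaviour statistics** — ethogram summaries, Cohen's kappa for
  inter-rater reliability, repeated-measures ANOVA with Tukey post-hocs, and
  mixed-model likelihood-ratio tests.
- **Pipeline / CLI** — a configurable end-to-end pipeline with deterministic,
  byte-identical outputs for a fixed seed, plus a small `Rscript` wrapper.

## The orientation index and the condition model

The body-orientation index is the cosine of the angle between the
body-to-head vector and the body-to-feeder vector: 1 facing the feeder (and
with it the panel), 0 perpendicular, −1 facing away. Index differences are
reported in degrees through the sign-preserving arcsine mapping
`asin(x)·180/π`, so an index difference of 0.32 corresponds to 18.66°.

For two conditions, the binned orientation time courses are modelled as

```
y_ref,t = μ_t       + ε_t        μ_t = μ_{t−1} + η_t,   η_t ~ N(0, σ_μ²)
y_alt,t = μ_t + δ_t + ε'_t       δ_t = δ_{t−1} + ν_t,   ν_t ~ N(0, σ_δ²)
```

with Gaussian observation noise (scale σ_obs) and half-normal priors on all
three scales. The headline summary is the posterior of the time-averaged
difference Δ̄ = mean(δ_t); "difference periods" are the bins whose pointwise
95% credible interval excludes 0. Convergence is monitored with split-R̂ over
4 chains.

## Worked example

Simulate a small experiment, run the kinematics, and compare two conditions:

```r
library(mirrorforage)

cfg <- sim_config(n_birds = 4, n_sessions = 2, session_length = 120, seed = 42)
dir <- file.path(tempdir(), "mirrorforage-demo")
write_fixture_set(cfg, dir)

geom <- arena_geometry()
manifest <- read_manifest(file.path(dir, "manifest.csv"))
kin <- analyze_sessions(manifest, geom)
head(kin$sessions, 4)
#> # A tibble: 4 × 7
#>   bird_id condition session latency_s censored log_activity mean_orientation
#>   <chr>   <chr>       <dbl>     <dbl> <lgl>           <dbl>            <dbl>
#> 1 B01     Wall            1      18.3 FALSE            1.25            0.376
#> 2 B01     Wall            2      23   FALSE            1.27            0.437
#> 3 B01     Mirror          1      65.3 FALSE            1.25            0.522
#> 4 B01     Mirror          2      31.2 FALSE            1.26            0.561

binned <- bin_series(kin$frames, bin_width = 1)
post <- fit_condition_model(binned, reference = "Wall", alternative = "Stranger",
                            mcmc = list(draws = 2000, warmup = 2000,
                                        chains = 4, seed = 7))
post
#> <condition_posterior> Stranger vs Wall: mean difference 0.220, 95% CI (0.199, 0.241)
#>   81/118 bins with CI excluding 0; max split-Rhat 1.013

summarize_difference(post)
#> # A tibble: 1 × 7
#>   comparison       delta_mean ci_low ci_high degrees n_difference_bins converged
#>   <chr>                 <dbl>  <dbl>   <dbl>   <dbl>             <int> <lgl>
#> 1 Stranger vs Wall      0.220  0.199   0.241    12.7                81 TRUE
```

(The generator's default orientation biases are 0.35 for Wall and 0.67 for
Stranger; the recovered difference of 0.22 on this short, smoothed demo sits
close to the post-approach gap between the two conditions.)

Ethogram summaries and inter-rater reliability:

```r
etho <- readr::read_csv(file.path(dir, "ethogram.csv"), show_col_types = FALSE)
head(summarize_ethogram(etho), 4)
#> # A tibble: 4 × 6
#>   behavior        condition   sum  mean   sem     n
#>   <chr>           <chr>     <dbl> <dbl> <dbl> <int>
#> 1 attack          Mirror        2  0.25 0.164     8
#> 2 attack          Stranger      0  0    0         8
#> 3 attack          Wall          0  0    0         8
#> 4 head_scratching Mirror        0  0    0         8

labs <- readr::read_csv(file.path(dir, "ethogram_labels.csv"), show_col_types = FALSE)
cohens_kappa(labs$rater_a, labs$rater_b)
#> <kappa_result> kappa = 0.875 (p_o = 0.928, p_e = 0.422, n = 291, p = 8.26e-88)

index_to_degrees(0.32)
#> [1] 18.66292
```

The whole chain, including figures, CSV outputs, and a run manifest, is also
available as one call (`run_pipeline(run_config(seed = 1, out_dir = "out"))`)
or from the shell via `Rscript inst/cli/mirrorforage.R all --out out --seed 1`.
Identical configuration and seed produce byte-identical CSV outputs.

## Package layout

- `R/`, `src/` — package code (one Rcpp translation unit for the FFBS kernel)
- `tests/testthat/` — unit, property, and acceptance tests
- `vignettes/mirror-foraging-analysis.Rmd` — methods vignette: model,
  assumptions, parameter defaults, numerical choices, and limitations
- `inst/cli/mirrorforage.R` — command-line wrapper
- `scripts/acceptance.R` — acceptance-target computation
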