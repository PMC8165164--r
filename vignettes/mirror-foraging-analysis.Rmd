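---
title: "Methods: analysing mirror and social foraging experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing mirror and social foraging experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical decisions behind
`mirrorforage`: what the statistical model assumes, why the defaults are what
they are, what the synthetic generator does and does not emulate, and where
the analysis has known limits. It is a methods document, not a tutorial; see
the README for a worked example.

## 1. The experiment and the measured quantities

A focal bird forages in a 50 × 60 cm arena whose long wall is a separation
panel: an opaque wall, a mirror, or a transparent barrier with an unfamiliar
conspecific behind it. Each bird runs several sessions per condition. The
behavioural readouts are:

- **Latency to feed** — time from session start to the first sustained
  feeding bout. Right-censored at the session end when the bird never feeds;
  censored sessions are excluded from the mixed models and their count is
  reported.
- **Activity rate** — the natural log of the mean body-center speed (cm/s)
  over non-feeding frames. The log restores approximate normality across
  birds; the mean speed is floored at 10⁻³ cm/s so a stationary bird yields a
  finite value instead of −∞.
- **Body-orientation index** — the cosine of the angle between the
  body-to-head and body-to-feeder vectors, in [−1, 1]. Because the feeder
  sits at the panel, orienting toward the feeder is orienting toward the
  mirror image or the stranger. The index is invariant under rigid motions
  and uniform scaling of the coordinate frame (a property the tests check on
  1,000 random instances).
- **Ethogram counts** — six behaviours (shaking, preening, head scratching,
  wing flapping, pecking the barrier, attack) counted per session by a
  primary rater, with a second rater for reliability (Cohen's kappa).

Index differences are reported in degrees via the sign-preserving arcsine
`asin(x)·180/π`. An arccosine mapping would be the literal inverse of the
index definition, but it maps an index *difference* of 0 to 90° rather than
0°; the arcsine convention keeps 0 ↔ 0° and ±1 ↔ ±90°, which is the only
mapping consistent with reporting a condition difference of 0.32 as 18.66°.
This is a reporting convention for differences, not a claim that the mean
angle itself equals `asin(mean index)`.

## 2. Preprocessing chain

Each session passes through, in order:

1. **Initial trim** (default 2 s): the first moments after placement are not
   comparable across conditions, so frames with `time < 2 s` are dropped;
   times stay relative to the original start so latencies remain comparable.
2. **Likelihood filtering** (threshold 0.6): frames where the tracker
   confidence of a required keypoint falls below the threshold are marked
   missing, then linearly interpolated across gaps up to 0.5 s. Longer gaps
   stay missing and simply drop out of downstream statistics — no
   extrapolation is ever invented.
3. **Pixel-to-cm calibration**: a pure rescaling by the arena's `px_per_cm`.
4. **LOESS smoothing**: locally weighted linear regression (tricube weights,
   degree 1, no robustness iterations) applied per coordinate.

### Why the smoothing window is 0.25 s

`loess_smooth()` takes a span as a fraction of the data, but the pipeline
parameterises smoothing by a *time window* (default 0.25 s, i.e. ~8 frames at
30 fps) and derives the span per session. A plausible-looking alternative —
a span that is a fixed fraction such as 0.05 of the session — corresponds to
a ~30 s window at 600 s × 30 fps. Empirically that window destroys the
signal: the head and body keypoints are only ~5 cm apart, and smoothing each
over 30 s displaces the smoothed head toward the feeder relative to the
smoothed body, inflating the orientation index toward 1 and erasing feeding
bouts entirely. With the 0.25 s window the full chain recovers the
generator's configured orientation bias to within ±0.05 and ground-truth
latencies to within half a second on noise-free input (tested), while still
suppressing frame-level tracker jitter, which is the purpose of the smoother.
The window must stay well below the feeding-bout timescale (~4 s) and the
heading-relaxation timescale (~2 s); 0.25 s leaves an order of magnitude of
margin on both sides.

Feeding bouts are frames with the head inside the feeder zone (6 cm radius),
debounced by removing runs shorter than 0.3 s, so single-frame zone crossings
caused by residual jitter do not count as feeding.

## 3. The condition-comparison model

The per-frame orientation series are averaged into 1 s bins within each
session and then across the sessions of each condition, giving one mean time
course per condition. Two conditions are compared with a Gaussian state-space
model:

$$y^{ref}_t = \mu_t + \varepsilon_t, \qquad
  y^{alt}_t = \mu_t + \delta_t + \varepsilon'_t$$

$$\mu_t = \mu_{t-1} + \eta_t,\ \eta_t \sim N(0, \sigma_\mu^2) \qquad
  \delta_t = \delta_{t-1} + \nu_t,\ \nu_t \sim N(0, \sigma_\delta^2)$$

with \(\varepsilon, \varepsilon' \sim N(0, \sigma_{obs}^2)\) and independent
half-normal(1) priors on the three scales. The shared trend \(\mu_t\) absorbs
within-session structure common to both conditions (approach, settling,
satiation); \(\delta_t\) is the time-varying condition difference. The
scalar summary is the time average \(\bar\Delta = \frac{1}{T}\sum_t \delta_t\),
reported with its posterior mean and central 95% credible interval;
"difference periods" are bins whose pointwise 95% interval excludes 0.

**Assumptions.** Gaussian observation noise with a common scale across
conditions and bins; first-order random-walk dynamics (no mean reversion, no
seasonality); bins treated as conditionally independent given the states.
Bin means of ~30 frames × several sessions justify the Gaussian
approximation for an index bounded in [−1, 1] away from the boundary; at
biases very close to ±1 the model would mis-state the noise.

**Sampler.** A custom Gibbs sampler:

- The joint state path \((\mu, \delta)\) is drawn by forward-filter
  backward-sampling (FFBS) in compiled code, processing the two observations
  of each bin as sequential scalar updates (no 2 × 2 inversions; missing bins
  simply skip their update).
- Each scale is updated by a stepping-out slice sampler on \(\log\sigma\)
  (Neal 2003), which is exact for the non-conjugate half-normal prior and has
  no tuning parameters beyond the step width.
- Plain centered Gibbs is notoriously sticky near \(\sigma = 0\) (the funnel:
  a near-constant sampled path forces a tiny scale, which forces a
  near-constant path). After the centered update, the sampler therefore also
  redraws each random-walk scale in the non-centered parameterisation, where
  the state is linear in the scale given the standardised increments and the
  conditional is Gaussian — the ancillarity–sufficiency interweaving strategy
  (Yu & Meng 2011). With interweaving, split-R̂ on a series whose true
  difference is constant drops from ~3 to below 1.05 at the default settings.
- Defaults: 4 chains × 1,000 draws after 1,000 warmup iterations, overdispersed
  half-normal initial scales per chain, split-R̂ reported for \(\bar\Delta\)
  and the three scales with a warning above 1.05.

**Exact invariances.** Two properties are enforced by construction rather
than numerically: (i) swapping reference and alternative exactly negates
every posterior draw, because the pair is fitted in a fixed canonical
(alphabetical) order and sign-flipped to the requested orientation; (ii) the
prior mean of the initial trend is anchored at the mean of the observed bins,
so adding a constant to both series shifts \(\mu\) and leaves \(\delta\)
invariant (to floating-point accumulation, ~10⁻⁹ in practice — the tests use
a 10⁻⁶ tolerance). One test cross-checks the whole sampler against an
independent JAGS implementation of the same model on a small series.

## 4. Group-level statistics

- **Repeated-measures ANOVA** on per-session behaviour counts: classical
  univariate within-subject analysis with error strata
  `Error(bird/(condition*day))`, giving the design's degrees of freedom
  (2, 14), (5, 35), (10, 70) for 8 birds × 3 conditions × 6 sessions.
  Partial η² is `SS_effect / (SS_effect + SS_error)` within the matching
  stratum. Counts are treated as approximately normal at the per-session
  aggregation level; no sphericity correction is applied (a limitation noted
  below). Tukey-adjusted pairwise condition contrasts come from estimated
  marginal means.
- **Mixed-model LRTs** for latency and log activity: linear mixed models with
  a random intercept per bird, fitted by maximum likelihood (REML likelihoods
  are not comparable across fixed-effect structures), testing condition,
  session, and their interaction by nested likelihood-ratio χ² tests. As an
  effect-size analog we report the Cox–Snell pseudo-R² of the term,
  `1 − exp(−χ²/n)`; the literature offers no single convention here, so the
  formula is stated explicitly wherever the value appears. Condition
  post-hocs are Tukey-adjusted asymptotic z contrasts; within-condition
  session contrasts (the familiarisation question) are adjusted over the 15
  session pairs.
- **Cohen's kappa** with the large-sample null variance of Fleiss, Cohen &
  Everitt (1969) for the z test against κ = 0. When both raters assign a
  single identical label throughout, chance agreement is 1 and kappa is
  returned as undefined (flagged, not an error). The unit of analysis is the
  scored event.

## 5. What the generator emulates — and what it does not

Defaults are the full study design: 8 birds × {Wall, Mirror, Stranger} × 6
sessions, 600 s at 30 fps, 50 × 60 cm arena digitised at 10 px/cm, feeder
zone of 6 cm around a feeder at the panel.

Emulated, with known ground truth:

- A dwell → approach → forage session structure. The entrance dwell is
  gamma-distributed (shape 9) and calibrated so dwell plus approach travel
  matches a per-condition, per-session latency schedule (Mirror highest, with
  a strong session-1 elevation that decays over sessions).
- Heading as direction-to-feeder plus an Ornstein–Uhlenbeck deviation
  (relaxation time 2 s) whose stationary standard deviation is set from
  \(E[\cos\theta] = e^{-s^2/2}\) so the post-approach mean orientation index
  equals the configured bias exactly (Wall 0.35 < Mirror 0.51 < Stranger
  0.67). The head keypoint sits 5 cm from body-center along the heading, so
  orientation ground truth is analytic.
- Feeding bouts (~3/min) alternating with excursions; movement as an
  anchor-pulled step plus isotropic noise, all displacements proportional to
  the condition's speed (Stranger > Wall > Mirror).
- Observation model: Gaussian tracker jitter (0.3 cm), and 2% per-frame,
  per-keypoint dropouts with corrupted coordinates and likelihood below 0.5
  (clean frames report 0.99).
- Ethogram counts as negative binomial draws around condition-specific means
  (fixed per-session means, e.g. 4.75 shaking bouts in the Stranger
  condition), and a
  second rater who relabels each event with 5% probability, making the
  expected kappa controllable.

Not emulated: arena walls as behavioural barriers beyond clipping, posture
beyond two keypoints, inter-bird interaction through the transparent barrier,
diurnal or satiation drift across sessions beyond the latency schedule,
autocorrelated tracker error, or identity switches. The generator is a test
harness with controllable truth, not a behavioural model of real birds.

Determinism: every unit of randomness (session, ethogram, model seed per
comparison) draws its seed from the master seed through a fixed integer hash,
so identical configuration and seed reproduce byte-identical output CSVs, and
any single session can be regenerated in isolation.

## 6. Numerical choices

- FFBS uses sequential scalar observation updates with the Joseph-free
  `P − SkkᵀS` form, a 2 × 2 Cholesky for the backward draw, and R's own RNG
  stream in compiled code, keeping results reproducible under `set.seed()`.
- `stats::lowess` is called with `delta = 0`; its default `delta`
  short-circuits the local fits on long series (it fits a sparse grid and
  interpolates), which measurably biased the orientation index on 18,000
  frame sessions.
- Seeds derived from the master seed stay below 2³¹ − 1.
- Problem sizes used in the test suite are the package's own choice: full
  design sizes where cardinality is the point (144 files), 600-bin series at
  4 × 1,000 draws for parameter recovery, and scaled-down replicates (120
  bins, 2 × 250 draws, 50 runs) for null-calibration checks so the whole
  suite stays within minutes.

## 7. Open questions and limitations

- The dual random-walk form is one defensible concretisation of a
  "time-varying condition difference" model, chosen for
  interpretability (a shared trend plus a drifting difference) and exact
  Gibbs updates. A mean-reverting (AR(1)) difference would be a natural
  alternative and would shrink long-horizon uncertainty faster.
- The wall-clock session alignment assumes sessions are comparable bin by
  bin after the 2 s trim; there is no time warping. If birds pace sessions
  very differently, binned means blur phase structure.
- The RM-ANOVA applies no Greenhouse–Geisser correction and treats counts as
  normal; for strongly skewed counts the mixed-model route (or a GLMM, not
  implemented) is preferable.
- Latency censoring is handled by exclusion plus bookkeeping, not by a
  survival model; with many censored sessions the latency tests lose power
  and can be biased toward fast birds.
- Kappa's unit of analysis is the event; per-video aggregation would give a
  different (typically higher-variance) estimate.
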