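---
title: "Detecting disturbance responses in biologged marine mammal movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting disturbance responses in biologged marine mammal movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moveresponse)
```

## The problem

Tagged cetaceans such as harbour porpoises (*Phocoena phocoena*) are
disturbed twice in a typical controlled exposure experiment: once by the
capture and tagging itself, and once by the experimental stimulus (here,
a short series of airgun pulses). Both disturbances show up as transient
departures from the animal's natural movement pattern. The analytical task
is to *detect* those departures, *time* them (when did the response start,
how long did it last, when was natural behaviour resumed), and keep the two
disturbances from being confounded with each other or with natural diel
variation.

`moveresponse` implements this workflow for the two data streams a typical
archival tag produces:

* a GPS track of surfacing positions (intermittent; roughly one successful
  fix per four surfacings), from which three horizontal parameters are
  derived per step: step length (m), speed (m/s) and absolute turning angle
  (0–180°, 0 = directed movement);
* a 1 Hz time–depth record, from which four vertical parameters are derived
  per dive: dive duration (s), maximum depth (m), bottom-phase wiggliness
  (m; summed absolute vertical displacement, a proxy for prey chasing) and
  post-dive surface duration (s).

## The model

### Diel baseline

Movement varies systematically over the 24 h cycle and between individuals,
so raw parameter values cannot be compared before and after a disturbance
directly. For each parameter and individual we fit a cyclic mean curve
$m(h)$ of local clock hour $h$ and work with the raw residuals
$r_i = y_i - m(h_i)$, so that $r = 0$ is that individual's baseline
behaviour at that time of day.

The smoother is a truncated Fourier (harmonic) regression,
$$m(h) = \beta_0 + \sum_{j=1}^{k}\left[a_j \cos\tfrac{2\pi j h}{24} +
b_j \sin\tfrac{2\pi j h}{24}\right],$$
with the number of harmonics $k \in \{0,\dots,6\}$ selected by generalized
cross-validation, $\mathrm{GCV} = n\,\mathrm{RSS}/(n-p)^2$. We chose the
harmonic basis over a penalized cyclic spline because it is exactly
periodic by construction ($m(0) = m(24)$ with matching derivatives), is
fitted by ordinary least squares, and is functionally equivalent to a
cyclic smoother at these sample sizes; no numerical equality with any
particular spline implementation is claimed. Consecutive observations of
movement data are autocorrelated, so after basis selection the coefficients
are re-estimated by iterated feasible GLS (Prais–Winsten) with an AR(1)
error structure, stopping when the AR(1) coefficient changes by less than
$10^{-4}$. Residuals are always reported on the raw scale (data minus
fitted curve), whatever the error model.

Residuals are then averaged in whole-hour bins of time since release
(half-open bins $[h, h+1)$; hours without observations are left as gaps,
not zero-filled). Hourly averaging balances the irregular GPS sampling and
reduces the remaining temporal autocorrelation. Turning angles are modelled
on their natural [0, 180] scale without a link transformation; their
residuals are somewhat heteroscedastic, which we accept.

### Piecewise regression on hourly residuals

Disturbance responses are assumed to start and end abruptly, so the hourly
residual series $r(t)$ (with $t$ hours since release, release $= 0$) is
modelled as a *continuous piecewise linear* ("broken-line") function with
$k$ breakpoints $\psi_1 < \dots < \psi_k$:
$$E[r(t)] = \beta_0 + \beta_1 t + \sum_{j=1}^k \delta_j (t - \psi_j)_+ .$$
For each $k = 0,\dots,6$ the model is fitted by iterative linearization:
given current breakpoints, the regression of $r$ on $t$, $(t-\psi_j)_+$ and
the gap covariates $-\mathbf{1}(t > \psi_j)$ yields slope-change estimates
$\delta_j$ and gap coefficients $\gamma_j$, and the update
$\psi_j \leftarrow \psi_j + \gamma_j/\delta_j$ is iterated until every
breakpoint moves by less than $10^{-6}$ h (at most 100 iterations).

Numerical choices, made once and kept:

* **Starting values.** Breakpoints start equally spaced over the observed
  range (with three deterministic jitters), at the equivalent quantiles
  when sampling is irregular, and at curvature-informed positions (the $k$
  largest second differences of a lightly smoothed response, plus the
  leave-one-out subsets of the $k+1$ largest — a weak true kink can rank
  below a noise bump). The converged solution with the lowest RSS is kept.
  All starts are deterministic, so fitting needs no seed.
* **Oscillation damping.** The linearized update limit-cycles when the
  optimal breakpoint sits at a kink of the profile RSS (i.e. at an observed
  $t$). A sign-reversing update smaller than the local inter-observation
  gap is therefore damped by a factor 4, monotonically per breakpoint, so
  the movement contracts geometrically once localized. Large reversals are
  left undamped: a trajectory that wanders on featureless data is reported
  as non-converged rather than rescued. This keeps the fitter honest on
  pure noise (overparameterized fits usually fail to converge there) while
  converging reliably when real structure exists.
* **Admissibility.** Breakpoints must stay strictly inside the data range,
  in increasing order, with at least 3 hourly observations per segment;
  a violated update is first step-halved and then reported as failure.
  Failures are logged, never silently absorbed.
* **Degenerate data.** All-equal $t$, too few observations for a given
  $k$, or a vanishing slope change ($|\delta_j| < 10^{-12}$, an
  unidentifiable breakpoint) are reported as errors or failures.

Models are ranked by the corrected Akaike criterion
$$\mathrm{AICc} = n \ln(\mathrm{RSS}/n) + 2p + \frac{2p(p+1)}{n-p-1},
\qquad p = 2 + 2k + 1,$$
counting the intercept, the $k+1$ segment slopes (via $k$ slope changes),
the $k$ breakpoints and the residual variance. The minimum-AICc converged
model is selected; ties within $10^{-6}$ go to fewer breakpoints.

A breakpoint is *validated* when at least one adjacent segment slope
differs from zero (two-sided $t$ test, $\alpha = 0.05$, $n - (2k+2)$ df):
a kink between two flat segments carries no evidence of a behavioural
change. Uncertainty in breakpoint times is quantified by case-resampling
bootstrap (50 replicates, as is conventional for multi-breakpoint models):
pairs are resampled with replacement, the model refit at fixed $k$ from the
original breakpoints, and the 2.5/97.5 percentiles taken per breakpoint,
matched by rank order. Replicates that fail to converge are excluded; if
fewer than 60% converge the interval is flagged unreliable. At $B = 50$
the percentile interval is somewhat anti-conservative, which the bootstrap
coverage test acknowledges (it requires ≥ 85% empirical coverage for a
nominal 95% interval).

### From breakpoints to response durations

With release at 0 h and the exposure at a known time $E$:

* the **capture-recovery duration** is the earliest validated breakpoint —
  the time at which post-release behaviour has decayed back to baseline;
* a **noise-induced response** is declared only if a validated breakpoint
  $\psi_j$ *coincides with the exposure* — within ±2 h, or with its
  bootstrap CI containing $E$ — and the post-$\psi_j$ slope is validated.
  The ±2 h window is our operationalization of "coincides"; no numeric
  criterion is standard, and the CI alternative covers individuals with
  sparse data. Then the **noise-response duration** is
  $\psi_{j+1}-\psi_j$ and the **noise-recovery duration**
  $\psi_{j+2}-\psi_{j+1}$, reported only when those breakpoints exist
  (and, in the default strict mode, are themselves validated).

Absence of any response is a legitimate outcome, as is a behavioural
change at a time unrelated to either disturbance.

### Received noise levels

Received airgun levels at the animal are estimated from back-calculated
source levels (defaults: 216 dB re 1 µPa peak–peak, 195 dB re 1 µPa RMS
over 125 ms, and 186 dB re 1 µPa²s SEL, all at 1 m) and an empirical
log-range transmission loss of $17\log_{10} r$ dB ($r$ in metres),
appropriate for shallow (~15 m) water. The animal's range at exposure is
the great-circle distance (sphere, $R = 6371$ km) from the GPS fix nearest
in time to the exposure (the earlier fix on ties). Because fixes rarely
coincide with the exposure instant, a ±50% range error brackets each
estimate: the maximum level at $0.5r$, the minimum at $1.5r$. Reported
levels are rounded to the nearest integer dB, half away from zero, which
reproduces the printed values of the study this model is calibrated to.
Audiogram (frequency) weighting requires band-level source spectra and is
deliberately exposed only as a scalar offset hook, with no claim of
reproducing weighted levels.

## The synthetic data generator

Because the original tag records are not public, every stage is validated
against synthetic data with known injected responses ([sim_config()],
[simulate_track()], [simulate_depth_series()]). The generator emulates:

* diel (24 h cyclic) variation in each parameter, with configurable
  amplitude and phase;
* individual baselines and AR(1) autocorrelation at the observation
  (per-step / per-dive) level — where movement autocorrelation actually
  arises — not at the hourly scale;
* a capture response: the full effect at release decaying linearly to zero
  at `capture_recovery`;
* an optional noise response: an abrupt offset at `exposure_time`, held for
  `noise_plateau` hours, then a linear return over `noise_recovery` hours
  (the detector is linear-piecewise, so the injected shape is too —
  exponential decays were deliberately not used);
* elevated heading concentration (directed movement) while any response
  offset is active;
* Bernoulli GPS fix thinning at 0.25 per surfacing, and continuous 1 Hz
  depth sampling with alternating dive/surface cycles.

Default effect magnitudes follow the responses reported for wild harbour
porpoises: capture effects of +5 m/s speed, −5 s dive duration, −2 m
maximum depth, −5 m wiggliness and −10 s post-dive interval, recovering
within ~12–27 h (default 18 h); noise effects of +2 m/s speed, −5 s
duration, −2 m depth and −15 s post-dive held for 4–8 h (default 6 h) with
a 17–35 h recovery (default 24 h); exposure ~4 days after release
(default 96 h). Baseline levels (speed 1.4 m/s, dive duration 60 s, depth
15 m, wiggliness 10 m, post-dive 30 s) are field-plausible values chosen
once; no published baseline distributions exist to calibrate against.
A single master seed drives everything; the track and depth generators use
deterministically derived sub-streams, so outputs are byte-identical across
runs.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: prey fields, tides and currents,
hydrodynamically realistic locomotion, position error in the GPS fixes,
depth-sensor drift (a linear corrector is provided but off by default, as
short deployments rarely need one), and behavioural states beyond the
baseline/response dichotomy.

## Known limitations

* **Baseline absorption.** The diel smoother is fitted to the whole record,
  responses included. If a response repeatedly occupies the same clock
  hours — e.g. an exposure an exact multiple of 24 h after a midday
  release — part of it is absorbed into the diel curve, biasing residuals
  and breakpoint locations. This is inherent to baselining over the full
  track; it is mild when responses are short relative to the record.
* **Abrupt onsets.** The generator's noise onset is a jump; the detector is
  continuous. At hourly resolution the jump becomes a steep one-bin
  segment, so onset breakpoints are recovered at hourly-bin precision, and
  a short plateau can merge with the onset into a single breakpoint.
* **Local optima.** The fitter is deliberately local (see damping above):
  a breakpoint with weak curvature next to a strong one can be missed at
  the selected $k$. A global search would find it — and would also halve
  the white-noise specificity of model selection. We chose specificity.
* **Bootstrap at B = 50.** Percentile intervals at 50 replicates are
  noisy and somewhat anti-conservative; they are used for coincidence
  checks and flagged when under-converged, not as exact inference.

## Problem sizes used for validation

The test-suite simulations use 240 h records at hourly resolution
(n = 240 hourly residuals; ~9,000 dives; ~5,000 GPS fixes before
thinning), 50-seed specificity runs on white noise, 100 random small
datasets (n ≤ 60) for the grid-oracle comparison, and 200 moderate-SNR
hinge simulations for bootstrap CI coverage — sizes at which each check is
informative while the whole suite stays quick to run.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(rng_seed = 5)
rec <- simulate_and_recover(cfg)
print(rec$run)
rec$responses$dive_duration

# received levels at the four exposed individuals' ranges
exposure_table(source_levels(), c(ID1 = 690, ID2 = 610, ID3 = 420,
                                  ID4 = 550))
```
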