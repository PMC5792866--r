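# moveresponse

Detecting and timing behavioural responses of tagged marine mammals to
discrete disturbance events — capture/tagging and short underwater noise
exposures — from biologging data.

## The problem

Controlled exposure experiments on free-ranging cetaceans (e.g. harbour
porpoises, *Phocoena phocoena*) produce two data streams per animal: a GPS
track of surfacing positions and a 1 Hz time–depth record. Both capture/
tagging and the experimental noise stimulus perturb the animal's movement
for hours, and those perturbations must be detected against strong natural
diel and individual variation — without confounding the two disturbances
with each other. `moveresponse` is for movement ecologists and
bioacousticians running or re-analysing such experiments.

## The method

For each movement parameter (step length, speed, absolute turning angle;
dive duration, maximum depth, bottom wiggliness, post-dive surface
duration) and each individual:

1. **Diel baseline.** The parameter is regressed on local clock hour with a
   GCV-selected cyclic harmonic smoother under AR(1) errors; raw residuals
   r = data − fit measure deviation from baseline behaviour (r = 0).
   Residuals are averaged in 1 h bins of time since release.
2. **Broken-line regression.** The hourly residuals r(t) are fitted with
   continuous piecewise linear models,
   E[r(t)] = β₀ + β₁t + Σⱼ δⱼ(t − ψⱼ)₊, for k = 0…6 breakpoints ψⱼ,
   ranked by AICc (p = 2k + 3). Breakpoints are validated by
   adjacent-segment slope t tests and given 95% case-resampling bootstrap
   CIs (B = 50).
3. **Classification.** The earliest validated breakpoint times the recovery
   from capture/tagging; a noise-induced response is declared only when a
   validated breakpoint coincides with the exposure instant (±2 h or CI
   coverage), and the following breakpoints time the response and recovery
   durations.
4. **Exposure levels.** Received airgun levels at the animal follow
   L(r) = L_source − 17·log₁₀(r) for range r in metres (source levels
   216 dB re 1 µPa pp, 195 dB re 1 µPa RMS over 125 ms, 186 dB re 1 µPa²s
   SEL, at 1 m), with a ±50% range error bracketing each estimate.

A synthetic biologging generator (`sim_config()`, `simulate_track()`,
`simulate_depth_series()`) injects known diel structure, AR(1)
autocorrelation and capture/noise responses so that every stage can be
validated against ground truth.

## Worked example

Received levels for an animal exposed at a nominal 420 m:

```r
library(moveresponse)
exposure_with_range_error(source_levels(), 420)
#> Exposure at 420 m [210-630 m]
#>   L_pp      171 [168-177] dB re 1 uPa pp
#>   L_eq-fast 150 [147-156] dB re 1 uPa (125 ms RMS)
#>   SEL       141 [138-147] dB re 1 uPa^2 s
```

The animal was estimated to receive a sound exposure level of 141 dB re
1 µPa²s, between 138 dB (if it was 50% farther than the nominal range) and
147 dB (if 50% nearer).

Breakpoint detection on hourly residuals shaped like a full
capture-plus-noise response (capture effect decaying to 0 by 12 h, exposure
at 96 h, 4 h response, 30 h recovery), with realistic hourly-mean noise:

```r
x <- 0:239 + 0.5
set.seed(2)
y <- ifelse(x < 12, 5 * (1 - x / 12),
     ifelse(x < 96, 0,
     ifelse(x < 100, 2 * (x - 96) / 4,
     ifelse(x < 130, 2 * (1 - (x - 100) / 30), 0)))) + rnorm(240, 0, 0.05)
rk <- rank_models(x, y, kmax = 6)
rk$selected
#> Piecewise fit, k = 4, n = 240, RSS = 0.6655, AICc = -1389.93
#>   breakpoints (h): 12.08, 95.76, 100.21, 129.74
#>   segment slopes : -0.4121, -0.0002919, 0.4573, -0.06816, -6.655e-05

est <- bootstrap_breakpoints(x, y, k = 4, fit = rk$selected, B = 50, seed = 1)
classify_response(est, exposure_time = 96)
#> Response summary
#>   capture-recovery duration : 12.1 h
#>   noise-induced response    : present
#>   noise-response duration   : 4.4 h
#>   noise-recovery duration   : 29.5 h
```

All four breakpoints are recovered within half an hour of their true
positions (12, 96, 100, 130 h), the capture recovery is timed at ~12 h,
and the noise response (4 h) with its recovery ramp (~30 h) is attributed
to the exposure because the second breakpoint coincides with it.

The full per-individual pipeline — screening, step/dive extraction,
baselining, breakpoints, classification, exposure levels — is
`run_individual()`; `simulate_and_recover()` runs it end-to-end on
synthetic data and reports breakpoint timing errors against the injected
truth. The methods vignette
(`vignettes/disturbance-response-detection.Rmd`) documents the model,
parameter defaults, numerical choices and limitations.

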