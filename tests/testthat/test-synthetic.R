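zero_vec <- c(speed = 0, dive_duration = 0, max_depth = 0, wiggliness = 0,
              post_dive = 0)

quiet_config <- function(...) {
  sim_config(diel_amplitude = zero_vec, residual_sd = zero_vec,
             capture_effect = zero_vec, noise_effect = zero_vec, ...)
}

test_that("the response profile follows the plateau-then-ramp shape", {
  cfg <- sim_config(capture_recovery = 18, exposure_time = 96,
                    noise_plateau = 6, noise_recovery = 24,
                    capture_effect = c(speed = 5),
                    noise_effect = c(speed = -4))
  # full capture effect at release, linear decay, zero at recovery
  expect_equal(response_profile(0, cfg, "speed"), 5)
  expect_equal(response_profile(9, cfg, "speed"), 2.5)
  expect_equal(response_profile(18, cfg, "speed"), 0)
  expect_equal(response_profile(19, cfg, "speed"), 0)
  # plateau holds the full noise effect from the exposure instant
  expect_equal(response_profile(96, cfg, "speed"), -4)
  expect_equal(response_profile(102, cfg, "speed"), -4)
  # halfway down the recovery ramp: half the effect
  expect_equal(response_profile(96 + 6 + 12, cfg, "speed"), -2)
  expect_equal(response_profile(96 + 6 + 24, cfg, "speed"), 0)
  expect_equal(response_profile(200, cfg, "speed"), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(capture_recovery = -1), "non-negative")
  expect_error(sim_config(noise_recovery = -2), "non-negative")
  expect_error(sim_config(duration = 100, exposure_time = 120))
  expect_error(sim_config(exposure_time = 10, capture_recovery = 18))
  expect_error(sim_config(gps_fix_prob = 0))
  expect_error(sim_config(ar1_phi = 1))
})

test_that("truth breakpoints mirror the injected profile", {
  cfg <- sim_config(capture_recovery = 18, exposure_time = 96,
                    noise_plateau = 6, noise_recovery = 24)
  tr <- sim_truth(cfg)
  expect_equal(tr$dive_duration$breakpoints, c(18, 96, 102, 126))
  expect_true(all(diff(tr$dive_duration$breakpoints) > 0))
  # no wiggliness noise effect by default: capture breakpoint only
  expect_equal(tr$wiggliness$breakpoints, 18)
  # zero effects: no breakpoints at all
  cfg0 <- quiet_config()
  expect_equal(length(sim_truth(cfg0)$speed$breakpoints), 0L)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(duration = 30, exposure_time = 24, capture_recovery = 12,
                    rng_seed = 77)
  a <- simulate_track(cfg)
  b <- simulate_track(cfg)
  expect_identical(a$track, b$track)
  da <- simulate_depth_series(cfg)
  db <- simulate_depth_series(cfg)
  expect_identical(da$series, db$series)
  # a different seed gives a different realization
  c2 <- simulate_track(sim_config(duration = 30, exposure_time = 24,
                                  capture_recovery = 12, rng_seed = 78))
  expect_false(identical(a$track$lat, c2$track$lat))
})

test_that("a zero-effect, zero-noise walk moves at constant speed in a straight line", {
  cfg <- quiet_config(duration = 26, exposure_time = 25,
                      capture_recovery = 12, gps_fix_prob = 1, rng_seed = 3)
  out <- simulate_track(cfg, turn_sd_baseline = 0)
  st <- compute_steps(out$track)
  expect_lt(diff(range(st$speed_ms)), 1e-6)
  expect_equal(mean(st$speed_ms), 1.4, tolerance = 1e-3)
  turns <- st$turning_angle_deg[-1]
  expect_lt(stats::sd(turns), 0.05)   # straight up to map curvature
})

test_that("GPS thinning retains roughly one fix in four", {
  cfg <- sim_config(duration = 60, exposure_time = 48, capture_recovery = 12,
                    rng_seed = 10)
  out <- simulate_track(cfg)
  n_surf <- nrow(out$full)
  frac <- nrow(out$track) / n_surf
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.3)
})

test_that("the injected capture speed offset is recovered as a Monte-Carlo mean", {
  offsets <- numeric(20)
  for (i in 1:20) {
    cfg <- sim_config(duration = 40, exposure_time = 30,
                      capture_recovery = 12,
                      diel_amplitude = zero_vec,
                      capture_effect = c(speed = 5),
                      noise_effect = zero_vec, rng_seed = 100 + i)
    out <- simulate_track(cfg)
    first_hour <- out$full$speed[out$full$t_h < 1]
    base <- out$full$speed[out$full$t_h > 15 & out$full$t_h < 29]
    offsets[i] <- mean(first_hour) - mean(base)
  }
  expected <- 5 * (1 - 0.5 / 12)   # mean profile over the first hour
  se <- stats::sd(offsets) / sqrt(length(offsets))
  expect_lt(abs(mean(offsets) - expected), 3 * se + 0.05)
})

test_that("the injected noise depth offset is recovered in the plateau window", {
  deltas <- numeric(20)
  for (i in 1:20) {
    cfg <- sim_config(duration = 60, exposure_time = 36,
                      capture_recovery = 12,
                      diel_amplitude = zero_vec,
                      capture_effect = zero_vec,
                      noise_effect = c(max_depth = -2),
                      noise_plateau = 8, rng_seed = 200 + i)
    dp <- simulate_depth_series(cfg)
    cy <- dp$cycles
    plateau <- cy$max_depth[cy$t_h >= 36 & cy$t_h < 44]
    base <- cy$max_depth[cy$t_h > 14 & cy$t_h < 34]
    deltas[i] <- mean(plateau) - mean(base)
  }
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - (-2)), 3 * se + 0.05)
})

test_that("depth traces are physical and dives carry the diel/AR structure", {
  cfg <- sim_config(duration = 30, exposure_time = 24, capture_recovery = 12,
                    rng_seed = 55)
  dp <- simulate_depth_series(cfg)
  expect_true(all(dp$series$depth_m >= 0))
  expect_true(all(diff(as.numeric(dp$series$timestamp)) == 1))
  dv <- detect_dives(dp$series)
  expect_gt(nrow(dv), 500)
  # detected dives reproduce the generated cycle parameters closely
  expect_equal(mean(dv$max_depth_m), mean(dp$cycles$max_depth),
               tolerance = 0.05)
})

test_that("truth and config serialize to JSON", {
  cfg <- sim_config(duration = 30, exposure_time = 24, capture_recovery = 12)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_truth_json(sim_truth(cfg), f1)
  write_config_json(cfg, f2)
  tr <- jsonlite::read_json(f1, simplifyVector = TRUE)
  expect_equal(tr$dive_duration$breakpoints, c(12, 24, 30, 54))
  cfg2 <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(cfg2$exposure_time, 24)
  unlink(c(f1, f2))
})
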