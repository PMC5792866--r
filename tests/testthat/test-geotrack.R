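test_that("step lengths match the haversine closed form", {
  # 1 degree of latitude at the equator on the 6371 km sphere
  tr <- geotrack(ts_utc(c(0, 3600)), c(0, 1), c(10, 10))
  st <- compute_steps(tr)
  expect_equal(st$step_length_m, pi * 6371000 / 180, tolerance = 1e-6)
  expect_equal(st$speed_ms, st$step_length_m / 3600)
  # 1 degree of longitude at 55 N
  tr2 <- geotrack(ts_utc(c(0, 3600)), c(55, 55), c(11, 12))
  st2 <- compute_steps(tr2)
  expect_equal(st2$step_length_m, haversine_oracle(55, 11, 55, 12),
               tolerance = 1e-6)
  expect_equal(st2$step_length_m / 1000, 63.78, tolerance = 0.01)
})

test_that("turning angles: collinear = 0, out-and-back = 180, rotation-invariant", {
  tr <- geotrack(ts_utc(c(0, 60, 120)), c(56, 56.01, 56.02), c(11, 11, 11))
  expect_equal(compute_steps(tr)$turning_angle_deg[2], 0, tolerance = 1e-6)

  back <- geotrack(ts_utc(c(0, 60, 120)), c(56, 56.01, 56), c(11, 11, 11))
  expect_equal(compute_steps(back)$turning_angle_deg[2], 180,
               tolerance = 1e-6)

  bearings <- c(10, 75, 170, 290, 355)
  dists <- c(500, 800, 300, 650, 400)
  base_turn <- compute_steps(walk_track(bearings, dists))$turning_angle_deg
  rot_turn <- compute_steps(walk_track((bearings + 53) %% 360,
                                       dists))$turning_angle_deg
  # spherical meridian convergence perturbs bearings by ~0.1 degree at this
  # latitude and step length; rotation invariance holds to that scale
  expect_equal(base_turn, rot_turn, tolerance = 0.5)
})

test_that("haversine distance is symmetric and satisfies the triangle inequality", {
  set.seed(7)
  for (i in 1:25) {
    p <- matrix(c(runif(3, 50, 60), runif(3, 5, 15)), ncol = 2)
    dab <- haversine_oracle(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    dba <- haversine_oracle(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    dac <- haversine_oracle(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    dcb <- haversine_oracle(p[3, 1], p[3, 2], p[2, 1], p[2, 2])
    tr <- geotrack(ts_utc(c(0, 60)), p[1:2, 1], p[1:2, 2])
    expect_equal(compute_steps(tr)$step_length_m, dab, tolerance = 1e-6)
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("outlier screening removes an out-and-back spike and nothing else", {
  # A -> B 5 km away in 60 s (300 km/h) -> back to A: B removed
  spike <- walk_track(c(0, 180), c(5000, 5000), dt_s = 60)
  scr <- screen_outliers(spike)
  expect_equal(attr(scr, "removed"), 1L)
  expect_equal(nrow(scr), 2L)

  # steady 10 km/h transit: nothing removed
  transit <- walk_track(rep(45, 9), rep(10000 / 60, 9), dt_s = 60)
  expect_equal(attr(screen_outliers(transit), "removed"), 0L)

  # stationary track: nothing removed
  still <- geotrack(ts_utc(seq(0, 240, by = 60)), rep(56, 5), rep(11, 5))
  expect_equal(attr(screen_outliers(still), "removed"), 0L)

  # idempotence once converged (2 fixes left: screening is a no-op)
  expect_warning(scr2 <- screen_outliers(scr), "fewer than 3")
  expect_equal(nrow(scr2), nrow(scr))
  expect_equal(attr(scr2, "removed"), 0L)

  expect_warning(screen_outliers(geotrack(ts_utc(c(0, 60)), c(56, 56.1),
                                          c(11, 11))), "fewer than 3")
})

test_that("iterative re-screening catches a spike masked by another", {
  # two separate out-and-back excursions: removing the first spike exposes
  # the second on the rescan
  A <- c(lat = 56, lon = 11)
  pt <- function(b, d) {
    p <- geosphere::destPoint(cbind(A[["lon"]], A[["lat"]]), b, d,
                              r = 6371000)
    c(p[1, 2], p[1, 1])
  }
  B <- pt(0, 5000); C <- pt(5, 150); D <- pt(90, 5000); E <- pt(40, 150)
  lat <- c(A[["lat"]], B[1], C[1], D[1], E[1])
  lon <- c(A[["lon"]], B[2], C[2], D[2], E[2])
  tr <- geotrack(ts_utc(seq(0, 240, by = 60)), lat, lon)
  scr <- screen_outliers(tr)
  expect_equal(attr(scr, "removed"), 2L)
  expect_equal(attr(screen_outliers(scr), "removed"), 0L)
})

test_that("displacement distances and net headings behave as expected", {
  tr <- walk_track(rep(0, 12), rep(2000, 12), dt_s = 3600)
  d <- displacement(tr, c(tr$lat[1], tr$lon[1]))
  expect_equal(d$distance_km[1], 0)
  expect_true(all(diff(d$distance_km) > 0))     # monotone transit
  # heading defined only once a fix >= 10 h old exists; due north walk
  expect_true(all(is.na(d$net_heading_deg[1:10])))
  expect_equal(d$net_heading_deg[12], 0, tolerance = 0.5)

  tr2 <- geotrack(ts_utc(0), 55, 12)
  d2 <- displacement(tr2, c(55, 11))
  expect_equal(d2$distance_km, haversine_oracle(55, 11, 55, 12) / 1000,
               tolerance = 1e-9)
})

test_that("geotrack CSV round-trips and the constructor enforces invariants", {
  tr <- walk_track(c(10, 80), c(400, 900))
  f <- tempfile(fileext = ".csv")
  write_geotrack_csv(tr, f)
  tr2 <- read_geotrack_csv(f)
  expect_equal(tr2$lat, tr$lat, tolerance = 1e-6)
  expect_equal(tr2$lon, tr$lon, tolerance = 1e-6)
  expect_equal(as.numeric(tr2$timestamp), as.numeric(tr$timestamp))
  unlink(f)
  expect_error(geotrack(ts_utc(c(0, 0)), c(56, 56), c(11, 11)), "increasing")
  expect_error(geotrack(ts_utc(c(0, 60)), c(56, 99), c(11, 11)), "range")
})
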