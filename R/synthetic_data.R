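#' Simulation configuration for synthetic biologging data
#'
#' Defines the study conditions emulated by the generator: diel (24 h
#' cyclic) variation in every movement parameter, individual baselines,
#' AR(1) autocorrelation of residuals at the observation (step/dive) level,
#' a capture/tagging response decaying linearly to baseline, and an optional
#' abrupt noise-induced response at the exposure time with a plateau and a
#' linear recovery ramp. Horizontal data are thinned to intermittent GPS
#' fixes (about one success per four surfacings); depth is sampled
#' continuously at 1 Hz.
#'
#' Parameters are named vectors over `"speed"` (m/s; drives the horizontal
#' walk), `"dive_duration"` (s), `"max_depth"` (m), `"wiggliness"` (m) and
#' `"post_dive"` (s). Effect defaults follow the response magnitudes
#' reported for tagged harbour porpoises: capture effects of +5 m/s speed,
#' -5 s dive duration, -2 m depth, -5 m wiggliness, -10 s post-dive
#' interval; noise effects of +2 m/s speed, -5 s duration, -2 m depth,
#' -15 s post-dive and no wiggliness change.
#'
#' @param duration tracking period, hours (default 240).
#' @param exposure_time airgun exposure, hours since release (default 96).
#' @param gps_fix_prob Bernoulli success probability per surfacing (0.25).
#' @param surfacing_interval mean seconds between surfacings (40).
#' @param depth_rate depth samples per second (1).
#' @param baseline,diel_amplitude,residual_sd,capture_effect,noise_effect
#'   named numeric vectors over the five parameters (units of the
#'   parameter).
#' @param diel_phase clock hour of the diel maximum (default 14).
#' @param ar1_phi AR(1) coefficient of observation-level residuals,
#'   in `[0, 1)` (default 0.3).
#' @param capture_recovery hours until the capture effect decays to 0 (18).
#' @param noise_plateau hours the noise effect is held (6).
#' @param noise_recovery hours of the linear return to baseline (24).
#' @param rng_seed integer master seed; sub-streams for the track and depth
#'   generators are derived from it deterministically.
#' @param release_time POSIXct release instant (UTC).
#' @param release_site `c(lat, lon)` of the release, degrees.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(duration = 240,
                       exposure_time = 96,
                       gps_fix_prob = 0.25,
                       surfacing_interval = 40,
                       depth_rate = 1,
                       baseline = c(speed = 1.4, dive_duration = 60,
                                    max_depth = 15, wiggliness = 10,
                                    post_dive = 30),
                       diel_amplitude = c(speed = 0.3, dive_duration = 10,
                                          max_depth = 3, wiggliness = 2,
                                          post_dive = 5),
                       diel_phase = 14,
                       residual_sd = c(speed = 0.5, dive_duration = 8,
                                       max_depth = 2.5, wiggliness = 3,
                                       post_dive = 6),
                       ar1_phi = 0.3,
                       capture_effect = c(speed = 5, dive_duration = -5,
                                          max_depth = -2, wiggliness = -5,
                                          post_dive = -10),
                       capture_recovery = 18,
                       noise_effect = c(speed = 2, dive_duration = -5,
                                        max_depth = -2, wiggliness = 0,
                                        post_dive = -15),
                       noise_plateau = 6,
                       noise_recovery = 24,
                       rng_seed = 1L,
                       release_time = as.POSIXct("2014-06-02 12:00:00",
                                                 tz = "UTC"),
                       release_site = c(lat = 56.2, lon = 11.3)) {
  pars <- c("speed", "dive_duration", "max_depth", "wiggliness", "post_dive")
  fill <- function(v) {
    out <- stats::setNames(rep(0, length(pars)), pars)
    out[names(v)] <- v
    out
  }
  cfg <- list(duration = duration, exposure_time = exposure_time,
              gps_fix_prob = gps_fix_prob,
              surfacing_interval = surfacing_interval,
              depth_rate = depth_rate,
              baseline = fill(baseline),
              diel_amplitude = fill(diel_amplitude),
              diel_phase = diel_phase,
              residual_sd = fill(residual_sd),
              ar1_phi = ar1_phi,
              capture_effect = fill(capture_effect),
              capture_recovery = capture_recovery,
              noise_effect = fill(noise_effect),
              noise_plateau = noise_plateau,
              noise_recovery = noise_recovery,
              rng_seed = as.integer(rng_seed),
              release_time = release_time,
              release_site = release_site,
              parameters = pars)
  if (!(cfg$capture_recovery >= 0 && cfg$noise_plateau >= 0 &&
        cfg$noise_recovery >= 0))
    stop("recovery/plateau durations must be non-negative")
  if (!(cfg$duration > cfg$exposure_time &&
        cfg$exposure_time > cfg$capture_recovery))
    stop("need duration > exposure_time > capture_recovery")
  if (!(cfg$gps_fix_prob > 0 && cfg$gps_fix_prob <= 1))
    stop("gps_fix_prob must be in (0, 1]")
  if (!(cfg$ar1_phi >= 0 && cfg$ar1_phi < 1))
    stop("ar1_phi must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Injected response offset at a given time
#'
#' The piecewise-linear disturbance profile added to a parameter's baseline:
#' the full capture effect at release (t = 0) decaying linearly to 0 at
#' `capture_recovery`; zero until `exposure_time`; the full noise effect
#' held over `[exposure_time, exposure_time + noise_plateau]`; a linear
#' return to 0 over `noise_recovery`; zero afterwards.
#'
#' @param t hours since release (vectorised, >= 0).
#' @param config a [sim_config()].
#' @param parameter one of the config's parameter names.
#' @return offset in the parameter's units.
#' @export
response_profile <- function(t, config, parameter) {
  stopifnot(inherits(config, "sim_config"), all(t >= 0),
            parameter %in% config$parameters)
  ce <- config$capture_effect[[parameter]]
  ne <- config$noise_effect[[parameter]]
  cr <- config$capture_recovery
  ex <- config$exposure_time
  pl <- config$noise_plateau
  rec <- config$noise_recovery
  off <- numeric(length(t))
  if (ce != 0 && cr > 0) {
    w <- t < cr
    off[w] <- off[w] + ce * (1 - t[w] / cr)
  }
  if (ne != 0) {
    w <- t >= ex & t <= ex + pl
    off[w] <- off[w] + ne
    if (rec > 0) {
      w <- t > ex + pl & t < ex + pl + rec
      off[w] <- off[w] + ne * (1 - (t[w] - ex - pl) / rec)
    }
  }
  off
}

# true breakpoint times and segment slopes implied by the injected profile
truth_for_parameter <- function(config, parameter) {
  ce <- config$capture_effect[[parameter]]
  ne <- config$noise_effect[[parameter]]
  bp <- numeric(0)
  slopes <- numeric(0)
  if (ce != 0 && config$capture_recovery > 0) {
    bp <- config$capture_recovery
    slopes <- -ce / config$capture_recovery
  }
  slopes <- c(slopes, 0)
  if (ne != 0) {
    ex <- config$exposure_time
    pl <- config$noise_plateau
    rec <- config$noise_recovery
    bp <- c(bp, ex, ex + pl)
    slopes <- c(slopes, 0)      # plateau (abrupt onset, flat hold)
    if (rec > 0) {
      bp <- c(bp, ex + pl + rec)
      slopes <- c(slopes, -ne / rec, 0)
    } else {
      slopes <- c(slopes, 0)
    }
  }
  list(breakpoints = bp, slopes = slopes)
}

#' True breakpoints implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return list of class `sim_truth`, one element per parameter with
#'   `breakpoints` (hours since release, strictly increasing) and `slopes`.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(config$parameters, truth_for_parameter, config = config)
  names(out) <- config$parameters
  structure(out, class = "sim_truth")
}

# derived sub-stream seeds; kept well below 2^31
substream_seed <- function(seed, stream) {
  (seed * 7 + stream * 104729) %% 2000000011
}

# diel baseline + AR(1) residual + injected response for one parameter,
# evaluated at observation times t_h (hours since release)
param_process <- function(t_h, config, parameter) {
  release_hod <- as.POSIXlt(config$release_time)$hour +
    as.POSIXlt(config$release_time)$min / 60
  hod <- (release_hod + t_h) %% 24
  m <- config$baseline[[parameter]] +
    config$diel_amplitude[[parameter]] *
    cos(2 * pi * (hod - config$diel_phase) / 24)
  n <- length(t_h)
  sd <- config$residual_sd[[parameter]]
  phi <- config$ar1_phi
  e <- numeric(n)
  if (sd > 0 && n > 0) {
    e[1] <- stats::rnorm(1, 0, sd)
    if (n > 1) {
      innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
      for (i in 2:n) e[i] <- phi * e[i - 1] + innov[i - 1]
    }
  }
  m + e + response_profile(t_h, config, parameter)
}

#' Simulate a GPS surfacing track
#'
#' Correlated random walk at surfacing resolution: per-step speed follows
#' diel baseline + AR(1) noise + the injected response profile, and heading
#' changes are drawn with a smaller turning spread while any response offset
#' is active (directed movement away from the disturbance). Fixes are
#' thinned by a Bernoulli trial per surfacing with probability
#' `gps_fix_prob`; the release fix is always retained. Reproducible for a
#' fixed `rng_seed`.
#'
#' @param config a [sim_config()].
#' @param turn_sd_baseline,turn_sd_directed s.d. of per-step heading change,
#'   degrees, during baseline and while responding.
#' @return list: `track` (a [geotrack()]), `truth` (a [sim_truth()]),
#'   `full` (unthinned positions with the true per-step speed).
#' @export
simulate_track <- function(config, turn_sd_baseline = 45,
                           turn_sd_directed = 8) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$rng_seed, 1L))
  total_s <- config$duration * 3600
  n_guess <- ceiling(total_s / config$surfacing_interval * 1.5) + 10
  gaps <- pmax(stats::rgamma(n_guess, shape = 4,
                             rate = 4 / config$surfacing_interval), 2)
  t_s <- cumsum(gaps)
  t_s <- t_s[t_s <= total_s]
  t_s <- c(0, t_s)
  n <- length(t_s)
  t_h <- t_s / 3600

  speed <- pmax(param_process(t_h, config, "speed"), 0.05)
  offset <- response_profile(t_h, config, "speed")
  turn_sd <- ifelse(abs(offset) > 0, turn_sd_directed, turn_sd_baseline)
  heading <- numeric(n)
  heading[1] <- stats::runif(1, 0, 360)
  if (n > 1) {
    turns <- stats::rnorm(n - 1, 0, turn_sd[-1])
    heading <- (heading[1] + c(0, cumsum(turns))) %% 360
  }
  # step i covers [t_i, t_{i+1})
  d_m <- speed[-n] * diff(t_s)
  brad <- heading[-n] * pi / 180
  dy <- d_m * cos(brad)
  dx <- d_m * sin(brad)
  m_per_deg <- pi * EARTH_RADIUS_M / 180
  lat <- config$release_site[["lat"]] + c(0, cumsum(dy)) / m_per_deg
  lon <- config$release_site[["lon"]] +
    c(0, cumsum(dx / (m_per_deg * cos(lat[-n] * pi / 180))))

  keep <- stats::runif(n) < config$gps_fix_prob
  keep[1] <- TRUE
  track <- geotrack(config$release_time + t_s[keep], lat[keep], lon[keep])
  list(track = track, truth = sim_truth(config),
       full = data.frame(t_h = t_h, lat = lat, lon = lon, speed = speed))
}

#' Simulate a 1 Hz time-depth record
#'
#' Alternating dive/surface cycles: per cycle, dive duration, maximum depth,
#' bottom wiggliness and post-dive surface interval each follow their diel
#' baseline + AR(1) noise + injected response. Each dive has a constant-rate
#' descent and ascent and a sinusoidally wiggling bottom phase whose total
#' vertical displacement matches the cycle's wiggliness target; depths are
#' never negative. Reproducible for a fixed `rng_seed`.
#'
#' @param config a [sim_config()].
#' @param descent_rate vertical transit rate, m/s (default 1.5).
#' @return list: `series` (a [depth_series()]), `truth` (a [sim_truth()]),
#'   `cycles` (per-dive data.frame of the generated parameter values).
#' @export
simulate_depth_series <- function(config, descent_rate = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$rng_seed, 2L))
  total_s <- config$duration * 3600
  mean_cycle <- config$baseline[["dive_duration"]] +
    config$baseline[["post_dive"]]
  n_guess <- ceiling(total_s / max(mean_cycle, 10) * 1.6) + 10

  t_h_planned <- numeric(n_guess)
  # draw each cycle's parameters sequentially so the AR(1) chains advance
  # per dive; times depend on the realized durations
  vals <- matrix(NA_real_, nrow = n_guess, ncol = 4,
                 dimnames = list(NULL, c("dive_duration", "max_depth",
                                         "wiggliness", "post_dive")))
  e <- stats::setNames(rep(0, 4), colnames(vals))
  phi <- config$ar1_phi
  release_hod <- as.POSIXlt(config$release_time)$hour +
    as.POSIXlt(config$release_time)$min / 60
  t_s <- 0
  i <- 0L
  while (t_s < total_s && i < n_guess) {
    i <- i + 1L
    t_h <- t_s / 3600
    t_h_planned[i] <- t_h
    hod <- (release_hod + t_h) %% 24
    for (p in colnames(vals)) {
      sd <- config$residual_sd[[p]]
      e[p] <- if (i == 1L) stats::rnorm(1, 0, sd) else
        phi * e[p] + stats::rnorm(1, 0, sd * sqrt(1 - phi^2))
      vals[i, p] <- config$baseline[[p]] +
        config$diel_amplitude[[p]] *
        cos(2 * pi * (hod - config$diel_phase) / 24) +
        e[p] + response_profile(t_h, config, p)
    }
    dur <- max(round(vals[i, "dive_duration"]), 10)
    post <- max(round(vals[i, "post_dive"]), 5)
    vals[i, "dive_duration"] <- dur
    vals[i, "post_dive"] <- post
    vals[i, "max_depth"] <- max(vals[i, "max_depth"], 3)
    vals[i, "wiggliness"] <- max(vals[i, "wiggliness"], 0)
    t_s <- t_s + dur + post
  }
  n_cyc <- i
  vals <- vals[seq_len(n_cyc), , drop = FALSE]
  t_h_planned <- t_h_planned[seq_len(n_cyc)]

  segs <- vector("list", n_cyc)
  for (j in seq_len(n_cyc)) {
    dur <- vals[j, "dive_duration"]
    M <- vals[j, "max_depth"]
    W <- vals[j, "wiggliness"]
    post <- vals[j, "post_dive"]
    n_desc <- max(ceiling(M / descent_rate), 1)
    if (2 * n_desc + 3 > dur) n_desc <- max(floor((dur - 3) / 2), 1)
    n_bot <- dur - 2 * n_desc + 1
    # steady descent to 75% of max depth, then a final lunge to the apex:
    # keeps transit samples out of the (>= 80% of max) bottom window so the
    # bottom-phase wiggliness of the dive is governed by W alone
    desc <- if (n_desc > 1)
      c(0.75 * M * seq_len(n_desc - 1) / (n_desc - 1), M)
    else M
    a <- 0.08 * M
    n_cycles_w <- W / (2 * a)
    u <- if (n_bot > 1) seq(0, 1, length.out = n_bot) else 0
    bot <- M - (a / 2) * (1 - cos(2 * pi * n_cycles_w * u))
    segs[[j]] <- c(desc, bot[-1], rev(desc)[-1], rep(0, post))
  }
  depth <- c(0, unlist(segs))
  ts <- config$release_time + seq_along(depth) - 1
  series <- depth_series(ts, pmax(depth, 0))
  list(series = series, truth = sim_truth(config),
       cycles = data.frame(t_h = t_h_planned, vals))
}
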