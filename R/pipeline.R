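#' Analyse one movement parameter end to end
#'
#' Diel-baseline removal, hourly mean residuals, piecewise model ranking,
#' slope validation with bootstrap CIs for the selected model, and response
#' classification — the per-parameter unit of the full pipeline.
#'
#' @param series a [movement_series()].
#' @param exposure_time_h exposure instant, hours since release.
#' @param kmax maximum breakpoints (default 6).
#' @param B bootstrap replicates (default 50).
#' @param seed seed for the bootstrap.
#' @param tolerance exposure-coincidence tolerance, hours (default 2).
#' @param max_harmonics,use_ar1 passed to [fit_cyclic_baseline()].
#' @param strict passed to [classify_response()].
#' @return list of class `parameter_analysis`: `baseline`, `hourly`,
#'   `ranking`, `breakpoints`, `response`.
#' @export
analyse_parameter <- function(series, exposure_time_h, kmax = 6, B = 50,
                              seed = 1L, tolerance = 2, max_harmonics = 6,
                              use_ar1 = TRUE, strict = TRUE) {
  fit <- fit_cyclic_baseline(series, max_harmonics = max_harmonics,
                             use_ar1 = use_ar1)
  hr <- hourly_mean_residuals(fit)
  rk <- rank_models(hr$hour, hr$mean_residual, kmax = kmax)
  est <- bootstrap_breakpoints(hr$hour, hr$mean_residual, k = rk$selected_k,
                               fit = rk$selected, B = B, seed = seed)
  resp <- classify_response(est, exposure_time_h, tolerance = tolerance,
                            strict = strict)
  structure(list(baseline = fit, hourly = hr, ranking = rk,
                 breakpoints = est, response = resp),
            class = "parameter_analysis")
}

#' Run the full response-detection pipeline for one individual
#'
#' Accepts a GPS track, a depth series, or both (at least one is required:
#' partial tag failures are common, e.g. a working GPS with a dead depth
#' logger). Horizontal parameters (step length, speed, turning angle) are
#' derived from the screened track; vertical parameters (dive duration,
#' maximum depth, wiggliness, post-dive duration) from detected dives. Each
#' parameter is analysed separately with [analyse_parameter()]. When the
#' track and an exposure site are available, the received noise levels at
#' the fix nearest the exposure are estimated.
#'
#' @param track a [geotrack()] or NULL.
#' @param depth a [depth_series()] or NULL.
#' @param release_time POSIXct release instant.
#' @param exposure_time_h exposure, hours since release.
#' @param exposure_site `c(lat, lon)` or NULL.
#' @param src a [source_levels()] object for exposure estimation.
#' @param screen screen the track for outliers first (default TRUE).
#' @param seed seed for all stochastic steps (bootstrap).
#' @param ... further arguments to [analyse_parameter()].
#' @return list of class `individual_run`: `parameters` (named list of
#'   `parameter_analysis`), `steps`, `dives`, `exposure`, `skipped`
#'   (character log of streams or parameters not analysed), `seed`.
#' @export
run_individual <- function(track = NULL, depth = NULL, release_time,
                           exposure_time_h, exposure_site = NULL,
                           src = source_levels(), screen = TRUE,
                           seed = 1L, ...) {
  if (is.null(track) && is.null(depth))
    stop("need at least one of a GPS track or a depth series")
  skipped <- character(0)
  steps <- NULL
  dives <- NULL
  analyses <- list()

  series_for <- function(x, hour, value, parameter)
    movement_series(x, hour, value, parameter = parameter)

  if (!is.null(track)) {
    if (screen) track <- screen_outliers(track)
    steps <- compute_steps(track, release_time = release_time)
    horiz <- list(
      step_length = steps$step_length_m,
      speed = steps$speed_ms,
      turning_angle = steps$turning_angle_deg)
    for (p in names(horiz)) {
      ms <- series_for(steps$time_since_release_h, steps$hour_mid,
                       horiz[[p]], p)
      analyses[[p]] <- tryCatch(
        analyse_parameter(ms, exposure_time_h, seed = seed, ...),
        error = function(e) {
          skipped <<- c(skipped, sprintf("%s: %s", p, conditionMessage(e)))
          NULL
        })
    }
  } else {
    skipped <- c(skipped,
                 "horizontal parameters: no location data available")
  }

  if (!is.null(depth)) {
    dives <- detect_dives(depth, release_time = release_time)
    vert <- list(
      dive_duration = dives$duration_s,
      max_depth = dives$max_depth_m,
      wiggliness = dives$wiggliness_m,
      post_dive = dives$post_dive_s)
    for (p in names(vert)) {
      ms <- series_for(dives$time_since_release_h, dives$hour_mid,
                       vert[[p]], p)
      analyses[[p]] <- tryCatch(
        analyse_parameter(ms, exposure_time_h, seed = seed, ...),
        error = function(e) {
          skipped <<- c(skipped, sprintf("%s: %s", p, conditionMessage(e)))
          NULL
        })
    }
  } else {
    skipped <- c(skipped, "vertical parameters: no dive data available")
  }

  exposure <- NULL
  if (!is.null(track) && !is.null(exposure_site)) {
    rte <- range_to_exposure(track, exposure_site,
                             release_time + exposure_time_h * 3600)
    exposure <- if (rte$r >= 2) {
      exposure_with_range_error(src, rte$r)
    } else {
      skipped <- c(skipped,
                   "exposure levels: fix within 2 m of the source, range error bound below 1 m")
      NULL
    }
    if (!is.null(exposure)) attr(exposure, "range_info") <- rte
  } else if (!is.null(exposure_site)) {
    skipped <- c(skipped,
                 "exposure levels: unavailable without location data")
  }

  structure(list(parameters = Filter(Negate(is.null), analyses),
                 steps = steps, dives = dives, exposure = exposure,
                 skipped = skipped, seed = seed),
            class = "individual_run")
}

#' @export
print.individual_run <- function(x, ...) {
  cat("Individual pipeline run:", length(x$parameters),
      "parameter(s) analysed\n")
  for (p in names(x$parameters)) {
    a <- x$parameters[[p]]
    cat(sprintf("- %s: k = %d; capture recovery %s; noise response %s\n", p,
                a$ranking$selected_k,
                ifelse(is.na(a$response$capture_recovery_h), "absent",
                       sprintf("%.1f h", a$response$capture_recovery_h)),
                if (a$response$noise_response) "present" else "absent"))
  }
  if (length(x$skipped)) cat("Skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Simulate data with known responses and measure recovery of the truth
#'
#' Generates a track and depth series from `config`, runs the full pipeline,
#' and compares the detected validated breakpoints with the injected truth:
#' for each true breakpoint, the absolute timing error to the nearest
#' detected breakpoint (NA when none was detected for that parameter).
#'
#' @param config a [sim_config()].
#' @param ... passed to [run_individual()].
#' @return list of class `recovery_report`: `run` (the [run_individual()]
#'   output), `truth`, `errors` (data.frame: parameter, true breakpoint,
#'   nearest detected breakpoint, absolute error in hours) and `responses`
#'   (per-parameter [classify_response()] summaries).
#' @export
simulate_and_recover <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  tr <- simulate_track(config)
  dp <- simulate_depth_series(config)
  run <- run_individual(track = tr$track, depth = dp$series,
                        release_time = config$release_time,
                        exposure_time_h = config$exposure_time,
                        seed = config$rng_seed, ...)
  truth <- tr$truth
  # horizontal parameters inherit the truth of the speed process
  truth_map <- list(step_length = "speed", speed = "speed",
                    turning_angle = "speed",
                    dive_duration = "dive_duration", max_depth = "max_depth",
                    wiggliness = "wiggliness", post_dive = "post_dive")
  rows <- list()
  for (p in names(run$parameters)) {
    tb <- truth[[truth_map[[p]]]]$breakpoints
    if (!length(tb)) next
    est <- run$parameters[[p]]$breakpoints
    det <- est$psi[est$validated]
    for (b in tb) {
      nearest <- if (length(det)) det[which.min(abs(det - b))] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, true_bp = b, detected_bp = nearest,
        abs_error_h = abs(nearest - b))
    }
  }
  errors <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(), true_bp = numeric(),
               detected_bp = numeric(), abs_error_h = numeric())
  structure(list(run = run, truth = truth, errors = errors,
                 responses = lapply(run$parameters, `[[`, "response")),
            class = "recovery_report")
}

#' Diagnostic plot of hourly residuals with the fitted segments
#'
#' @param hr an [hourly_mean_residuals()] result.
#' @param fit a converged [fit_piecewise()] result.
#' @param ... passed to [plot()].
#' @export
plot_segments <- function(hr, fit, ...) {
  stopifnot(inherits(hr, "hourly_residuals"), inherits(fit, "piecewise_fit"),
            isTRUE(fit$converged))
  plot(hr$hour, hr$mean_residual, col = "grey50", pch = 16,
       xlab = "time since release (h)", ylab = "hourly mean residual", ...)
  xx <- seq(min(hr$hour), max(hr$hour), length.out = 400)
  graphics::lines(xx, fit$predict(xx), lwd = 2)
  if (fit$k > 0) graphics::abline(v = fit$psi, lty = 3)
  invisible(NULL)
}

#' Write simulation truth or configuration to JSON
#'
#' @param truth a [sim_truth()].
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @param config a [sim_config()].
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- unclass(config)
  cfg$release_time <- format(cfg$release_time, "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
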