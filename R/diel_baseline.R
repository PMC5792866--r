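#' Movement parameter series for one individual
#'
#' One observed movement parameter (one value per step or per dive) with the
#' timing information needed to remove diel variation: fractional clock hour
#' of day (local time) and hours since release.
#'
#' @param time_since_release_h numeric, non-decreasing, hours.
#' @param hour_of_day numeric in [0, 24).
#' @param value numeric, parameter units.
#' @param parameter parameter name (e.g. `"speed"`).
#' @param id individual identifier.
#' @return data.frame of class `movement_series`.
#' @export
movement_series <- function(time_since_release_h, hour_of_day, value,
                            parameter = "value", id = "ind1") {
  stopifnot(length(time_since_release_h) == length(hour_of_day),
            length(hour_of_day) == length(value))
  keep <- is.finite(time_since_release_h) & is.finite(hour_of_day) &
    is.finite(value)
  d <- data.frame(time_since_release_h = time_since_release_h[keep],
                  hour_of_day = hour_of_day[keep] %% 24,
                  value = value[keep])
  d <- d[order(d$time_since_release_h), ]
  rownames(d) <- NULL
  structure(d, class = c("movement_series", "data.frame"),
            parameter = parameter, id = id)
}

# harmonic (truncated Fourier) design matrix in hour-of-day, period 24 h;
# cyclic by construction: every column has m(0) = m(24) and matching slope
harmonic_basis <- function(hour, k) {
  X <- matrix(1, nrow = length(hour), ncol = 1 + 2 * k)
  if (k > 0) {
    for (j in seq_len(k)) {
      w <- 2 * pi * j * hour / 24
      X[, 2 * j] <- cos(w)
      X[, 2 * j + 1] <- sin(w)
    }
  }
  X
}

#' Fit the diel baseline for one movement parameter
#'
#' Regresses a movement parameter on hour of day with a cyclic smoother and
#' extracts raw residuals (data minus fitted values), the deviation from the
#' individual's baseline behaviour. The smoother is a truncated Fourier
#' (harmonic) regression with period 24 h — exactly cyclic by construction —
#' whose basis size (0..`max_harmonics` harmonics) is selected by generalized
#' cross-validation, GCV = n RSS / (n - p)^2. Temporal dependence between
#' consecutive observations is handled with an AR(1) error structure: the
#' coefficients are re-estimated by iterative feasible GLS (Prais-Winsten)
#' until the AR(1) coefficient changes by less than 1e-4. Residuals are
#' always reported on the raw scale, value minus fitted curve.
#'
#' @param series a [movement_series()] with >= 48 observations spanning
#'   >= 24 h.
#' @param max_harmonics largest number of harmonics tried (default 6).
#' @param use_ar1 re-estimate under AR(1) errors (default TRUE).
#' @return object of class `baseline_fit`: `coefficients`, `k` (harmonics),
#'   `gcv` (per candidate k), `phi` (AR(1) coefficient; 0 if disabled),
#'   `fitted`, `residuals`, `series`, and `m` — the fitted cyclic mean
#'   function of clock hour.
#' @export
fit_cyclic_baseline <- function(series, max_harmonics = 6, use_ar1 = TRUE) {
  stopifnot(inherits(series, "movement_series"))
  n <- nrow(series)
  if (n < 48L)
    stop("need at least 48 observations to fit a diel baseline")
  span <- diff(range(series$time_since_release_h))
  if (span < 24)
    stop("series spans less than 24 h: the diel cycle is not identifiable")
  y <- series$value
  hour <- series$hour_of_day

  # basis size by OLS GCV
  gcv <- rep(NA_real_, max_harmonics + 1)
  for (k in 0:max_harmonics) {
    p <- 1 + 2 * k
    if (n <= p + 1) break
    X <- harmonic_basis(hour, k)
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    gcv[k + 1] <- n * rss / (n - p)^2
  }
  k_best <- which.min(gcv) - 1L
  X <- harmonic_basis(hour, k_best)
  beta <- stats::lm.fit(X, y)$coefficients

  phi <- 0
  if (use_ar1 && n > 4L) {
    # Prais-Winsten feasible GLS, iterated to convergence in phi
    for (iter in 1:50) {
      e <- y - drop(X %*% beta)
      denom <- sum(e[-n]^2)
      if (denom < 1e-12 * max(1, sum(y^2))) break   # (near-)perfect fit
      phi_new <- sum(e[-1] * e[-n]) / denom
      phi_new <- max(min(phi_new, 0.99), 0)
      ys <- c(sqrt(1 - phi_new^2) * y[1], y[-1] - phi_new * y[-n])
      Xs <- rbind(sqrt(1 - phi_new^2) * X[1, , drop = FALSE],
                  X[-1, , drop = FALSE] - phi_new * X[-n, , drop = FALSE])
      beta <- stats::lm.fit(Xs, ys)$coefficients
      if (abs(phi_new - phi) < 1e-4) {
        phi <- phi_new
        break
      }
      phi <- phi_new
    }
  }

  fitted <- drop(X %*% beta)
  structure(list(
    coefficients = beta, k = k_best, gcv = gcv, phi = phi,
    fitted = fitted, residuals = y - fitted, series = series,
    m = function(hour) drop(harmonic_basis(hour %% 24, k_best) %*% beta)
  ), class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("Diel baseline for '%s' (%s): %d harmonic(s), phi = %.3f, n = %d\n",
              attr(x$series, "parameter"), attr(x$series, "id"),
              x$k, x$phi, length(x$residuals)))
  invisible(x)
}

#' Hourly mean residuals
#'
#' Averages the raw residuals of a diel-baseline fit within whole-hour bins
#' of time since release (`[h, h+1)`), reducing temporal autocorrelation and
#' balancing irregular GPS sampling. Hours without observations are absent,
#' not zero-filled.
#'
#' @param fit a [fit_cyclic_baseline()] result.
#' @return data.frame of class `hourly_residuals`: `hour` (bin start, hours
#'   since release), `mean_residual`, `n`.
#' @export
hourly_mean_residuals <- function(fit) {
  stopifnot(inherits(fit, "baseline_fit"))
  h <- floor(fit$series$time_since_release_h)
  agg <- tapply(fit$residuals, h, mean)
  cnt <- tapply(fit$residuals, h, length)
  out <- data.frame(hour = as.numeric(names(agg)),
                    mean_residual = as.numeric(agg),
                    n = as.integer(cnt))
  out <- out[order(out$hour), ]
  rownames(out) <- NULL
  structure(out, class = c("hourly_residuals", "data.frame"),
            parameter = attr(fit$series, "parameter"),
            id = attr(fit$series, "id"))
}
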