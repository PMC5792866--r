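#' Continuous piecewise (broken-line) linear regression
#'
#' Fits `y` on `x` as a continuous piecewise-linear function with `k`
#' breakpoints by iterative linearization: the model is reparameterized with
#' slope-change terms `(x - psi_j)+` and gap terms whose coefficients drive
#' the breakpoint update `psi_j <- psi_j + gamma_j / delta_j`, iterated until
#' `max |delta psi| < 1e-6` h or 100 iterations. A failure to converge, a
#' breakpoint leaving the admissible range, breakpoints crossing, or a
#' segment collapsing below `min_seg` observations is reported as a failed
#' fit, never silently absorbed.
#'
#' Starting breakpoints default to equally spaced positions over the data
#' range; three additional deterministically jittered starts are tried and
#' the converged solution with the lowest RSS is kept.
#'
#' @param x sorted numeric predictor (hours since release).
#' @param y numeric response (hourly mean residuals).
#' @param k number of breakpoints (>= 0).
#' @param init optional numeric vector of k starting breakpoints.
#' @param extra_starts optional list of additional length-k starting
#'   breakpoint vectors to try (inadmissible ones are dropped).
#' @param min_seg minimum observations per segment (default 3).
#' @param tol convergence tolerance on breakpoint moves, hours (1e-6).
#' @param max_iter maximum iterations (100).
#' @return object of class `piecewise_fit` with elements `converged`,
#'   `reason` (when failed), `k`, `psi`, `intercept`, `slopes` (k+1 segment
#'   slopes), `slope_se`, `rss`, `n`, `p` (parameter count incl. residual
#'   variance), `aicc`, `fitted`, `residuals`, `coefficients`, `vcov`,
#'   `iterations`, and `predict` — the fitted continuous function.
#' @export
fit_piecewise <- function(x, y, k, init = NULL, min_seg = 3,
                          tol = 1e-6, max_iter = 100, extra_starts = list()) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            k >= 0, k == round(k))
  n <- length(x)
  if (is.unsorted(x)) stop("x must be sorted")
  if (diff(range(x)) <= 0) stop("all x values are equal")
  if (n < 3 * (k + 1) + k)
    stop(sprintf("need at least %d observations for k = %d", 3 * (k + 1) + k, k))

  if (k == 0) return(finish_piecewise(x, y, numeric(0), min_seg))

  starts <- piecewise_starts(x, k, init, min_seg = min_seg, y = y)
  if (length(extra_starts))
    starts <- c(starts, Filter(function(s)
      length(s) == k && psi_valid(x, s, min_seg), extra_starts))
  best <- NULL
  reasons <- character(0)
  for (s in starts) {
    res <- muggeo_iterate(x, y, s, min_seg, tol, max_iter)
    if (res$converged) {
      fit <- finish_piecewise(x, y, res$psi, min_seg, res$iterations)
      if (is.null(best) || fit$rss < best$rss) best <- fit
    } else {
      reasons <- c(reasons, res$reason)
    }
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, k = k, n = n,
                          reason = paste(unique(reasons), collapse = "; ")),
                     class = "piecewise_fit"))
  }
  best
}

# equally spaced starting breakpoints plus three deterministic jitters and,
# when no explicit init is given, one curvature-informed start (the k largest
# local slope changes of a lightly smoothed response)
piecewise_starts <- function(x, k, init = NULL, min_seg = 3, y = NULL) {
  rng <- range(x)
  sp <- diff(rng) / (k + 1)
  base <- if (is.null(init)) seq(rng[1], rng[2], length.out = k + 2)[2:(k + 1)]
          else sort(init)
  jit <- function(f) base + f * sp
  alt <- base + 0.2 * sp * rep_len(c(1, -1), k)
  out <- list(base, jit(-0.15), jit(0.15), alt)
  # quantile seeding; coincides with the equispaced start when x is regular
  qs <- unname(stats::quantile(x, probs = seq_len(k) / (k + 1), type = 7))
  if (is.null(init) && max(abs(qs - base)) > 1e-8 * diff(rng))
    out <- c(out, list(qs, qs - 0.15 * sp, qs + 0.15 * sp))
  if (is.null(init) && !is.null(y)) {
    # curvature candidates: a weak true kink can rank below a noise bump,
    # so also try the leave-one-out k-subsets of the k+1 strongest
    ks <- kink_start(x, y, k + 1)
    if (is.null(ks)) ks <- kink_start(x, y, k)
    if (!is.null(ks)) {
      sets <- if (length(ks) > k)
        lapply(seq_along(ks), function(j) ks[-j])
      else list(ks)
      for (s in sets)
        if (psi_valid(x, s, min_seg)) out <- c(out, list(s))
    }
  }
  out
}

# starting breakpoints at the k largest |second difference| of a smoothed y,
# kept a minimum spacing apart
kink_start <- function(x, y, k) {
  n <- length(y)
  if (n < 7 || k < 1) return(NULL)
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys <- as.numeric(ys)
  ys[is.na(ys)] <- y[is.na(ys)]
  d2 <- abs(diff(ys, differences = 2))
  # the unsmoothed ends produce spurious curvature; never seed there
  edge <- min(4L, floor((n - 1) / 4))
  d2[seq_len(edge)] <- 0
  d2[seq(length(d2) - edge + 1L, length(d2))] <- 0
  ord <- order(d2, decreasing = TRUE) + 1L
  # breakpoints only need min_seg observations between them, so candidate
  # kinks may sit close together (abrupt onsets are two nearby kinks)
  spacing <- 3 * stats::median(diff(x))
  picked <- numeric(0)
  for (i in ord) {
    cand <- x[i]
    if (all(abs(cand - picked) > spacing)) picked <- c(picked, cand)
    if (length(picked) == k) break
  }
  if (length(picked) < k) return(NULL)
  sort(picked)
}

# psi admissible: strictly inside the x range, strictly increasing, and
# every segment holds at least min_seg observations
psi_valid <- function(x, psi, min_seg) {
  if (any(!is.finite(psi))) return(FALSE)
  if (is.unsorted(psi, strictly = TRUE)) return(FALSE)
  if (psi[1] <= min(x) || psi[length(psi)] >= max(x)) return(FALSE)
  cuts <- c(-Inf, psi, Inf)
  counts <- tabulate(findInterval(x, cuts, left.open = TRUE),
                     nbins = length(psi) + 1)
  all(counts >= min_seg)
}

muggeo_iterate <- function(x, y, psi, min_seg, tol, max_iter) {
  k <- length(psi)
  if (!psi_valid(x, psi, min_seg))
    return(list(converged = FALSE, reason = "invalid starting breakpoints"))
  damp <- rep(1, k)
  prev_step <- rep(0, k)
  # scale below which a sign-alternating update is treated as oscillation
  # around a kink of the profile objective rather than genuine exploration;
  # the profile RSS has kinks at observed x, so the cycle amplitude is
  # bounded by the local inter-observation gap
  xs <- sort(unique(x))
  local_gap <- function(p) {
    i <- findInterval(p, xs)
    if (i < 1 || i >= length(xs)) return(Inf)
    xs[i + 1] - xs[i]
  }
  for (iter in seq_len(max_iter)) {
    U <- outer(x, psi, function(xx, p) pmax(xx - p, 0))
    V <- outer(x, psi, function(xx, p) -as.numeric(xx > p))
    Z <- cbind(1, x, U, V)
    qf <- tryCatch(stats::lm.fit(Z, y), error = function(e) NULL)
    if (is.null(qf) || qf$rank < ncol(Z))
      return(list(converged = FALSE, reason = "rank-deficient design"))
    cf <- qf$coefficients
    delta <- cf[3:(2 + k)]
    gamma <- cf[(3 + k):(2 + 2 * k)]
    if (any(!is.finite(delta)) || any(abs(delta) < 1e-12))
      return(list(converged = FALSE,
                  reason = "breakpoint with vanishing slope change"))
    step <- unname(gamma / delta)
    # damp breakpoints whose update direction reverses at sub-observation
    # scale: the linearized update cycles when the optimum sits at a kink
    # of the profile objective. Damping is monotone (never regrown) so the
    # breakpoint movement contracts geometrically once localized; large
    # reversals are left undamped (genuine exploration).
    osc <- vapply(psi, local_gap, numeric(1))
    rev <- prev_step * step < 0 & abs(step) < osc & abs(prev_step) < osc
    damp[rev] <- damp[rev] / 4
    prev_step <- step
    step <- step * damp
    # step-halve towards an admissible update before declaring failure
    ok <- FALSE
    for (h in 0:6) {
      psi_new <- psi + step / 2^h
      if (psi_valid(x, psi_new, min_seg)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      return(list(converged = FALSE,
                  reason = "breakpoint left admissible range or segment collapsed"))
    if (max(abs(psi_new - psi)) < tol)
      return(list(converged = TRUE, psi = psi_new, iterations = iter))
    psi <- psi_new
  }
  list(converged = FALSE, reason = "no convergence within iteration limit")
}

# final continuous fit at fixed psi: slopes, standard errors, AICc
finish_piecewise <- function(x, y, psi, min_seg, iterations = 0L) {
  n <- length(x)
  k <- length(psi)
  X <- if (k > 0) cbind(1, x, outer(x, psi, function(xx, p) pmax(xx - p, 0)))
       else cbind(1, x)
  qf <- stats::lm.fit(X, y)
  cf <- qf$coefficients
  rss <- sum(qf$residuals^2)
  p_reg <- 2 + k                        # regression coefficients
  p <- 2 + 2 * k + 1                    # + breakpoints + residual variance
  sigma2 <- if (n > p_reg) rss / (n - p_reg) else NA_real_
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  vc <- if (!is.null(XtX_inv)) sigma2 * XtX_inv else
    matrix(NA_real_, p_reg, p_reg)
  # segment slope m = beta_x + sum_{j<=m} delta_j ; SE by linear combination
  slopes <- numeric(k + 1)
  slope_se <- numeric(k + 1)
  for (m in 0:k) {
    L <- numeric(p_reg)
    L[2] <- 1
    if (m > 0) L[3:(2 + m)] <- 1
    slopes[m + 1] <- sum(L * cf)
    slope_se[m + 1] <- sqrt(drop(t(L) %*% vc %*% L))
  }
  aicc_val <- if (n > p + 1) {
    n * log(max(rss, 1e-300) / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  } else NA_real_
  pred <- function(x0) {
    X0 <- if (k > 0)
      cbind(1, x0, outer(x0, psi, function(xx, pp) pmax(xx - pp, 0)))
    else cbind(1, x0)
    drop(X0 %*% cf)
  }
  structure(list(
    converged = TRUE, k = k, psi = psi,
    intercept = cf[1], slopes = slopes, slope_se = slope_se,
    rss = rss, n = n, p = p, aicc = aicc_val,
    fitted = drop(X %*% cf), residuals = qf$residuals,
    coefficients = cf, vcov = vc, iterations = iterations,
    predict = pred
  ), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Piecewise fit, k = %d: NOT converged (%s)\n", x$k, x$reason))
    return(invisible(x))
  }
  cat(sprintf("Piecewise fit, k = %d, n = %d, RSS = %.4g, AICc = %.2f\n",
              x$k, x$n, x$rss, x$aicc))
  if (x$k > 0)
    cat("  breakpoints (h):", paste(sprintf("%.2f", x$psi), collapse = ", "), "\n")
  cat("  segment slopes :", paste(sprintf("%.4g", x$slopes), collapse = ", "), "\n")
  invisible(x)
}

#' Corrected Akaike information criterion for a piecewise fit
#'
#' `AICc = n ln(RSS/n) + 2p + 2p(p+1)/(n - p - 1)` with parameter count
#' `p = 2 + 2k + 1`: intercept, k+1 segment slopes (via k slope changes),
#' k breakpoints, and the residual variance.
#'
#' @param fit a converged [fit_piecewise()] result.
#' @return the AICc score.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "piecewise_fit"), isTRUE(fit$converged))
  if (fit$n <= fit$p + 1)
    stop(sprintf("model with k = %d inadmissible: n = %d <= p + 1 = %d",
                 fit$k, fit$n, fit$p + 1))
  fit$aicc
}

#' Fit and rank piecewise models with 0..kmax breakpoints
#'
#' Fits [fit_piecewise()] for each breakpoint count and selects the model
#' with the smallest AICc among the converged, admissible fits.
#' Non-converged fits are skipped with a logged reason. When two models are
#' within 1e-6 AICc of each other the one with fewer breakpoints wins
#' (parsimony).
#'
#' @inheritParams fit_piecewise
#' @param kmax maximum number of breakpoints (default 6).
#' @return object of class `model_ranking`: `fits` (list indexed by k+1),
#'   `table` (k, converged, rss, aicc, reason), `selected` (best fit) and
#'   `selected_k`.
#' @export
rank_models <- function(x, y, kmax = 6, min_seg = 3) {
  n <- length(x)
  fits <- vector("list", kmax + 1)
  rows <- list()
  for (k in 0:kmax) {
    p <- 2 + 2 * k + 1
    if (n < 3 * (k + 1) + k || n <= p + 1) {
      rows[[k + 1]] <- data.frame(k = k, converged = FALSE, rss = NA_real_,
                                  aicc = NA_real_,
                                  reason = "insufficient observations")
      next
    }
    # forward seeding: extend the previous converged solution with the
    # strongest kink remaining in its residuals
    extra <- list()
    if (k >= 1) {
      prev <- fits[[k]]
      if (!is.null(prev) && isTRUE(prev$converged)) {
        cand <- kink_start(x, prev$residuals, 1)
        psi_prev <- if (k == 1) numeric(0) else prev$psi
        if (!is.null(cand) && all(abs(cand - psi_prev) >
                                  3 * stats::median(diff(x))))
          extra <- list(sort(c(psi_prev, cand)))
      }
    }
    f <- fit_piecewise(x, y, k, min_seg = min_seg, extra_starts = extra)
    fits[[k + 1]] <- f
    rows[[k + 1]] <- data.frame(
      k = k, converged = f$converged,
      rss = if (f$converged) f$rss else NA_real_,
      aicc = if (f$converged) f$aicc else NA_real_,
      reason = if (f$converged) "" else f$reason)
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged & is.finite(tab$aicc) | tab$converged &
                tab$aicc == -Inf)
  if (!length(ok)) stop("no piecewise model converged")
  # parsimony tie-break: sort by AICc then k; ties within 1e-6 go to lower k
  cand <- tab[ok, ]
  cand <- cand[order(cand$aicc, cand$k), ]
  best <- cand[1, ]
  near <- cand[is.finite(cand$aicc) & is.finite(best$aicc) &
                 abs(cand$aicc - best$aicc) < 1e-6 |
                 (cand$aicc == -Inf & best$aicc == -Inf), ]
  if (nrow(near)) best <- near[which.min(near$k), ]
  structure(list(fits = fits, table = tab,
                 selected = fits[[best$k + 1]], selected_k = best$k),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Piecewise model ranking (selected k =", x$selected_k, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Validate breakpoints by adjacent-segment slope tests
#'
#' A breakpoint is accepted when at least one of its two adjacent segment
#' slopes differs significantly from 0 (two-sided t test at `alpha`,
#' `n - (2k + 2)` residual df): a flat-to-flat kink carries no evidence of a
#' behavioural change.
#'
#' @param fit a converged [fit_piecewise()] result with k >= 1.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `psi`, `left_sig`, `right_sig`, `validated`.
#' @export
validate_breakpoints <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "piecewise_fit"), isTRUE(fit$converged))
  k <- fit$k
  if (k == 0)
    return(data.frame(psi = numeric(0), left_sig = logical(0),
                      right_sig = logical(0), validated = logical(0)))
  df <- fit$n - (2 * k + 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  tstat <- abs(fit$slopes / fit$slope_se)
  sig <- is.finite(tstat) & tstat > tcrit
  data.frame(psi = fit$psi,
             left_sig = sig[1:k],
             right_sig = sig[2:(k + 1)],
             validated = sig[1:k] | sig[2:(k + 1)])
}

#' Bootstrap confidence intervals for breakpoint times
#'
#' Case resampling: pairs `(x, y)` are resampled with replacement `B` times
#' and the model refit at fixed `k` with the original breakpoints as
#' starting values. The 95% CI of each breakpoint is the 2.5/97.5 percentile
#' of its position across converged replicates, matched by rank order.
#' Replicates that fail to converge are logged and excluded; if fewer than
#' `min_converged` of the replicates converge the CIs are flagged
#' unreliable.
#'
#' @inheritParams fit_piecewise
#' @param fit optional pre-computed converged fit at `k` (refit if NULL).
#' @param B bootstrap replicates (default 50).
#' @param seed integer seed for reproducibility.
#' @param level confidence level (default 0.95).
#' @param min_converged minimum fraction of converged replicates (0.6).
#' @param alpha slope-validation level passed to [validate_breakpoints()].
#' @return data.frame of class `breakpoint_estimates`: `psi`, `lo`, `hi`,
#'   `validated`; attributes `conv_rate`, `unreliable`, `B`.
#' @export
bootstrap_breakpoints <- function(x, y, k, fit = NULL, B = 50, seed = NULL,
                                  level = 0.95, min_converged = 0.6,
                                  min_seg = 3, alpha = 0.05) {
  if (is.null(fit)) fit <- fit_piecewise(x, y, k, min_seg = min_seg)
  stopifnot(inherits(fit, "piecewise_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit")
  if (k == 0) {
    out <- data.frame(psi = numeric(0), lo = numeric(0), hi = numeric(0),
                      validated = logical(0))
    attr(out, "conv_rate") <- 1
    attr(out, "unreliable") <- FALSE
    attr(out, "B") <- B
    class(out) <- c("breakpoint_estimates", "data.frame")
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  psi_mat <- matrix(NA_real_, nrow = B, ncol = k)
  for (b in seq_len(B)) {
    idx <- sort(sample.int(n, n, replace = TRUE))
    fb <- tryCatch(
      fit_piecewise(x[idx], y[idx], k, init = fit$psi, min_seg = min_seg),
      error = function(e) NULL)
    if (!is.null(fb) && fb$converged) psi_mat[b, ] <- sort(fb$psi)
  }
  ok <- stats::complete.cases(psi_mat)
  conv_rate <- mean(ok)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- if (any(ok))
    apply(psi_mat[ok, , drop = FALSE], 2, stats::quantile, probs = pr)
  else matrix(NA_real_, 2, k)
  val <- validate_breakpoints(fit, alpha)
  out <- data.frame(psi = fit$psi, lo = ci[1, ], hi = ci[2, ],
                    validated = val$validated)
  attr(out, "conv_rate") <- conv_rate
  attr(out, "unreliable") <- conv_rate < min_converged
  attr(out, "B") <- B
  attr(out, "left_sig") <- val$left_sig
  attr(out, "right_sig") <- val$right_sig
  class(out) <- c("breakpoint_estimates", "data.frame")
  out
}
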