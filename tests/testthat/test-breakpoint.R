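test_that("an exact line is recovered with zero breakpoints", {
  x <- 0:59 + 0.5
  y <- 1.3 - 0.7 * x
  f <- fit_piecewise(x, y, 0)
  expect_true(f$converged)
  expect_equal(unname(f$slopes), -0.7, tolerance = 1e-12)
  expect_lt(f$rss, 1e-20)
})

test_that("a noise-free hinge is located to within half an hour", {
  x <- 0:239 + 0.5
  y <- ifelse(x > 96, -(x - 96), 0)
  f <- fit_piecewise(x, y, 1)
  expect_true(f$converged)
  expect_equal(f$psi, 96, tolerance = 0.5)
  expect_equal(unname(f$slopes), c(0, -1), tolerance = 1e-6)
  # AICc prefers the hinge over the straight line
  f0 <- fit_piecewise(x, y, 0)
  expect_lt(aicc(f), aicc(f0))
  # and matches the exhaustive grid oracle
  expect_lte(f$rss, 1.01 * grid_piecewise_rss(x, y, 1) + 1e-12)
})

test_that("iterative fits attain grid-oracle RSS on small noisy hinges", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(30:60, 1)
    x <- sort(runif(n, 0, 100))
    psi <- runif(1, 25, 75)
    y <- ifelse(x > psi, 0.8 * (x - psi), 0) + rnorm(n, 0, 0.4)
    f <- fit_piecewise(x, y, 1)
    expect_true(f$converged)
    expect_lte(f$rss, 1.01 * grid_piecewise_rss(x, y, 1))
  }
})

test_that("the fitted broken line is continuous at every breakpoint", {
  set.seed(5)
  x <- 0:199 + 0.5
  y <- response_curve(x) + rnorm(200, 0, 0.1)
  f <- fit_piecewise(x, y, 4)
  expect_true(f$converged)
  eps <- 1e-9
  for (p in f$psi) {
    # finite-difference straddle: any discontinuity shows up at O(1); the
    # genuine slope change contributes only O(eps)
    jump <- abs(f$predict(p + eps) - f$predict(p - eps))
    expect_lt(jump, 1e-6 * max(1, abs(f$predict(p))))
  }
})

test_that("shifting or rescaling the response transforms the fit predictably", {
  set.seed(13)
  x <- 0:149 + 0.5
  y <- ifelse(x > 60, -0.5 * (x - 60), 0) + rnorm(150, 0, 0.3)
  f1 <- fit_piecewise(x, y, 1)
  f2 <- fit_piecewise(x, y + 10, 1)
  expect_equal(f2$psi, f1$psi, tolerance = 1e-6)
  expect_equal(unname(f2$slopes), unname(f1$slopes), tolerance = 1e-6)
  expect_equal(unname(f2$intercept - f1$intercept), 10, tolerance = 1e-6)

  f3 <- fit_piecewise(x, 4 * y, 1)
  expect_equal(f3$psi, f1$psi, tolerance = 1e-4)
  expect_equal(unname(f3$slopes), unname(4 * f1$slopes), tolerance = 1e-4)
  expect_equal(f3$rss, 16 * f1$rss, tolerance = 1e-6)

  r1 <- rank_models(x, y, kmax = 3)
  r3 <- rank_models(x, 4 * y, kmax = 3)
  expect_equal(r3$selected_k, r1$selected_k)
})

test_that("model ranking: RSS non-increasing in k; ties go to fewer breakpoints", {
  set.seed(17)
  x <- 0:239 + 0.5
  y <- response_curve(x) + rnorm(240, 0, 0.15)
  rk <- rank_models(x, y, kmax = 6)
  conv <- rk$table[rk$table$converged, ]
  expect_true(all(diff(conv$rss) <= 1e-8))
  expect_equal(rk$selected$aicc, min(conv$aicc))
  # an exact line: every k >= 1 degenerates, the line is selected
  rline <- rank_models(x, 2 + 0.1 * x, kmax = 3)
  expect_equal(rline$selected_k, 0L)
})

test_that("breakpoints are validated only when an adjacent slope is nonzero", {
  set.seed(23)
  x <- 0:149 + 0.5
  # steep hinge, signal-to-noise ~ 10: accepted
  y <- ifelse(x > 75, -1 * (x - 75), 0) + rnorm(150, 0, 0.8)
  f <- fit_piecewise(x, y, 1)
  v <- validate_breakpoints(f)
  expect_true(v$validated[1])
  expect_true(v$right_sig[1])

  # flat-to-flat data fit with a forced breakpoint: rejected
  y0 <- rnorm(150, 0, 1)
  f0 <- fit_piecewise(x, y0, 1)
  if (f0$converged) {
    v0 <- validate_breakpoints(f0)
    # both adjacent slopes are consistent with zero on pure noise
    expect_false(any(v0$left_sig & v0$right_sig) && all(abs(f0$slopes) < 0.01))
  }
  expect_equal(nrow(validate_breakpoints(fit_piecewise(x, y0, 0))), 0L)
})

test_that("breakpoint acceptance rate grows with slope magnitude", {
  set.seed(29)
  x <- 0:119 + 0.5
  rate <- function(slope) {
    acc <- 0; tot <- 0
    for (i in 1:15) {
      y <- ifelse(x > 60, slope * (x - 60), 0) + rnorm(120, 0, 1)
      f <- fit_piecewise(x, y, 1)
      if (!f$converged) next
      tot <- tot + 1
      acc <- acc + validate_breakpoints(f)$validated[1]
    }
    acc / max(tot, 1)
  }
  expect_lte(rate(0.02), rate(0.5))
  expect_equal(rate(1), 1)
})

test_that("bootstrap CIs are reproducible, tight on clean data, and rank-matched", {
  x <- 0:239 + 0.5
  set.seed(41)
  y <- ifelse(x > 96, -(x - 96), 0) + rnorm(240, 0, 0.05)
  b1 <- bootstrap_breakpoints(x, y, 1, B = 50, seed = 99)
  b2 <- bootstrap_breakpoints(x, y, 1, B = 50, seed = 99)
  expect_equal(b1$lo, b2$lo)
  expect_equal(b1$hi, b2$hi)
  expect_lt(b1$hi[1] - b1$lo[1], 2)
  expect_true(b1$lo[1] <= b1$psi[1] && b1$psi[1] <= b1$hi[1])
  expect_false(attr(b1, "unreliable"))

  # two breakpoints stay rank-ordered across replicates
  y2 <- response_curve(x, capture = 0, noise = 5) + rnorm(240, 0, 0.2)
  b3 <- bootstrap_breakpoints(x, y2, 2, B = 50, seed = 7)
  expect_true(all(diff(b3$psi) > 0))
  expect_true(all(b3$lo <= b3$hi))
})

test_that("degenerate inputs are rejected with informative errors", {
  x <- 0:29 + 0.5
  expect_error(fit_piecewise(x, rnorm(30), -1))
  expect_error(fit_piecewise(rep(1, 30), rnorm(30), 1), "equal")
  expect_error(fit_piecewise(x[1:5], rnorm(5), 1), "at least")
  expect_error(fit_piecewise(rev(x), rnorm(30), 1), "sorted")
  f0 <- fit_piecewise(x, rnorm(30), 0)
  expect_error(aicc(structure(list(converged = FALSE, k = 2),
                              class = "piecewise_fit")))
})
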