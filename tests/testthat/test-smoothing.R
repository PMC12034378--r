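# Penalized B-spline smoothing: basis identities, GCV, noise estimation,
# and whole-cell smoothing quality.

test_that("basis satisfies partition of unity and derivative identities", {
  tg <- seq(0, 10, length.out = 41)
  basis <- build_basis(c(0, 2, 5, 7, 10), tg)
  expect_equal(rowSums(basis$B), rep(1, 41))
  expect_equal(rowSums(basis$Bdot), rep(0, 41), tolerance = 1e-12)
  # analytic derivative matches finite differences of the basis
  h <- 1e-6
  mid <- seq(0.5, 9.5, by = 0.5)
  Bp <- eval_basis(basis, mid + h)
  Bm <- eval_basis(basis, mid - h)
  expect_equal(eval_basis(basis, mid, deriv = 1), (Bp - Bm) / (2 * h),
               tolerance = 1e-5)
  # straight lines live in the null space of the roughness penalty
  cf_line <- as.numeric(qr.solve(basis$B, 2 + 3 * tg))
  expect_lt(abs(t(cf_line) %*% basis$penalty %*% cf_line), 1e-8)
  expect_error(build_basis(seq(0, 10, by = 0.1), tg), "too many knots")
})

test_that("unpenalized fit interpolates representable curves", {
  tg <- seq(0, 1, length.out = 7)
  y <- 1 - 2 * tg + 0.5 * tg^2 + tg^3          # a cubic: exactly representable
  basis <- build_basis(c(0, 0.5, 1), tg)
  fit <- fit_penalized(y, basis, 1, 0)
  expect_lt(max(abs(fit$fitted - y)), 1e-10)
  expect_equal(fit$fitted_deriv, -2 + tg + 3 * tg^2, tolerance = 1e-8)
})

test_that("infinite penalty collapses to the weighted least-squares line", {
  set.seed(3)
  tg <- seq(0, 10, length.out = 31)
  y <- 1 + 0.7 * tg + rnorm(31, 0, 0.3)
  w <- runif(31, 0.5, 2)
  basis <- build_basis(c(0, 3, 6, 10), tg)
  fit <- fit_penalized(y, basis, w, 1e10)
  line <- lm.wfit(cbind(1, tg), y, w)
  expect_equal(fit$fitted, as.numeric(cbind(1, tg) %*% line$coefficients),
               tolerance = 1e-4)
})

test_that("smoother is linear in the data for fixed weights and penalty", {
  tg <- seq(0, 10, length.out = 21)
  basis <- build_basis(c(0, 4, 8, 10), tg)
  set.seed(8)
  y1 <- rnorm(21); y2 <- rnorm(21)
  f1 <- fit_penalized(y1, basis, 1, 0.5)$fitted
  f2 <- fit_penalized(y2, basis, 1, 0.5)$fitted
  f12 <- fit_penalized(2 * y1 - 3 * y2, basis, 1, 0.5)$fitted
  expect_equal(f12, 2 * f1 - 3 * f2, tolerance = 1e-10)
})

test_that("coefficient covariance matches the brute-force formula and MC", {
  tg <- seq(0, 10, length.out = 25)
  basis <- build_basis(c(0, 3, 7, 10), tg)
  y <- sin(tg / 2)
  fit <- fit_penalized(y, basis, 1, 0, noise_var = rep(1, 25))
  brute <- solve(crossprod(basis$B))
  expect_equal(fit$coef_cov, brute, tolerance = 1e-8)

  # Monte-Carlo: empirical coefficient covariance over noise replicates
  sigma <- 0.2
  truth <- 2 + tg - 0.05 * tg^2
  fits <- replicate(500, {
    yr <- truth + rnorm(25, 0, sigma)
    fit_penalized(yr, basis, 1, 0.1)$coef
  })
  emp <- cov(t(fits))
  theo <- fit_penalized(truth, basis, 1, 0.1,
                        noise_var = rep(sigma^2, 25))$coef_cov
  expect_lt(norm(emp - theo, "F") / norm(theo, "F"), 0.25)
})

test_that("GCV penalizes noise more than clean signal", {
  tg <- seq(0, 10, length.out = 51)
  basis <- build_basis(seq(0, 10, by = 1), tg)
  signal <- sin(tg) + 0.3 * tg
  lam_clean <- select_lambda(signal, basis)
  set.seed(21)
  y_noisy <- signal + rnorm(51, 0, 0.5)
  lam_noisy <- select_lambda(y_noisy, basis)
  expect_gt(lam_noisy, lam_clean)
  # the noisy fit actually smooths: fitted curve is closer to the signal
  # than the data are
  f <- fit_penalized(y_noisy, basis, 1, lam_noisy)
  expect_lt(mean((f$fitted - signal)^2), mean((y_noisy - signal)^2))
  # the selected value minimizes the GCV score over its grid (oracle recompute)
  grid <- 10^seq(-6, 3, length.out = 40)
  scores <- vapply(grid, function(lam) {
    fit <- fit_penalized(y_noisy, basis, 1, lam)
    51 * sum((y_noisy - fit$fitted)^2) / (51 - fit$edf)^2
  }, numeric(1))
  expect_equal(lam_noisy, grid[which.min(scores)])
  expect_identical(select_lambda(sin(tg), basis), select_lambda(sin(tg), basis))
})

test_that("noise parameters are recovered by the residual regression", {
  # a ramp makes (1, xhat^2) well separated, so sigma and tau are identifiable
  tg <- seq_len(200)
  basis <- build_basis(c(1, 50, 100, 150, 200), tg)
  truth <- seq(1, 20, length.out = 200)
  # multiplicative-only noise
  set.seed(31)
  tau_hats <- replicate(200, {
    y <- truth * (1 + rnorm(200, 0, 0.05))
    f <- fit_penalized(y, basis, 1, 1)
    estimate_noise(y, f)$tau_hat
  })
  expect_lt(abs(mean(tau_hats) - 0.05), 0.005)
  # additive-only noise
  set.seed(32)
  res <- replicate(200, {
    y <- truth + rnorm(200, 0, 0.4)
    f <- fit_penalized(y, basis, 1, 1)
    ns <- estimate_noise(y, f)
    c(ns$sigma_hat, ns$tau_hat)
  })
  expect_lt(abs(mean(res[1, ]) - 0.4), 0.04)
  expect_lt(mean(res[2, ]) * 10, 0.2 * 0.4)  # tau contribution stays small
  # noiseless, exactly representable data leave no residual variance
  y <- as.numeric(basis$B %*% sin(seq_len(basis$n_basis)))
  f <- fit_penalized(y, basis, 1, 0)
  ns <- estimate_noise(y, f)
  expect_lt(ns$sigma_hat + ns$tau_hat, 1e-6)
})

test_that("auto_knots is deterministic and feature-aware", {
  tg <- seq(0, 10, length.out = 41)
  mono <- exp(0.3 * tg)
  kn <- auto_knots(mono, tg)
  expect_lte(length(kn) - 2, 3)
  expect_identical(kn, auto_knots(mono, tg))
  # one full oscillation: knots bracket the extrema within one step
  osc <- sin(2 * pi * tg / 10)
  kn2 <- auto_knots(osc, tg)
  interior <- kn2[-c(1, length(kn2))]
  step <- diff(tg)[1]
  expect_true(any(abs(interior - 2.5) <= 1.25 + step))
  expect_true(any(abs(interior - 7.5) <= 1.25 + step))
  expect_lte(length(interior), floor(41 / 2))
})

test_that("smooth_cell recovers noiseless states and gradients", {
  fx <- lv_dense_fixture()
  Xdot <- t(sapply(seq_along(fx$tgrid),
                   function(j) rhs(fx$model, fx$X[j, ], fx$beta_true)))
  for (k in c(4, 10, 16)) {
    f <- fx$fits[[k]]
    expect_lt(max(abs(f$fitted - fx$X[, k])) / diff(range(fx$X[, k])), 0.01)
    inner <- 10:192                      # derivative quality away from ends
    expect_lt(max(abs(f$fitted_deriv - Xdot[, k])[inner]) /
                diff(range(Xdot[, k])), 0.05)
  }
})

test_that("reweighting reaches a fixed point", {
  ds <- lv_small_fixture()
  sm1 <- smooth_cell(ds$cells[[1]])
  # second pass starting from the converged weights changes nothing material
  lam <- vapply(sm1$fits, `[[`, numeric(1), "lambda")
  kn <- lapply(sm1$fits, function(f) f$basis$knots)
  sm2 <- smooth_cell(ds$cells[[1]], knots = kn, lambda = lam)
  for (k in c(1, 8)) {
    expect_equal(sm2$fits[[k]]$fitted, sm1$fits[[k]]$fitted, tolerance = 0.02)
  }
})

test_that("fitted values and derivatives are exact basis expansions", {
  ds <- lv_small_fixture()
  sm <- smooth_cell(ds$cells[[2]])
  f <- sm$fits[[3]]
  expect_equal(f$fitted, as.numeric(f$basis$B %*% f$coef))
  expect_equal(f$fitted_deriv, as.numeric(f$basis$Bdot %*% f$coef))
  ev <- eigen(f$coef_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12 * max(abs(ev)))
})
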