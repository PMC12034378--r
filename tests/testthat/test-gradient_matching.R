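# Stage I with full state information: system assembly, GLS algebra,
# delta-method residual covariance, FGLS recovery, and interval coverage.

test_that("assembled system has the structure of the linear model", {
  ds <- lv_small_fixture()
  sm <- smooth_cell(ds$cells[[1]])
  sys <- assemble_system(ds$model, sm$fits)
  expect_equal(dim(sys$Gmat), c(21 * 16, 4))
  # row for state n carries -xhat_n xhat_{n+1} in its tied parameter column
  j <- 5; n <- 7
  row <- sys$Gmat[(j - 1) * 16 + n, ]
  pidx <- ((n - 1) %% 4) + 1
  expect_equal(row[pidx], -sys$Xhat[j, n] * sys$Xhat[j, n + 1])
  expect_true(all(row[-pidx] == 0))
  # response is xdot - r x for the Lotka-Volterra h
  expect_equal(sys$dvec[(j - 1) * 16 + n],
               sys$Xdot[j, n] - n / 80 * sys$Xhat[j, n])
  expect_error(assemble_system(ds$model, sm$fits[1:15]), "one spline fit")
})

test_that("gls_solve reproduces brute-force solutions", {
  set.seed(51)
  n <- 40; p <- 3
  G <- matrix(rnorm(n * p), n, p)
  d <- rnorm(n)
  sys <- structure(list(Gmat = G, dvec = d, V = diag(1, n), K = n, T = 1),
                   class = "gls_system")
  ols <- solve(crossprod(G), crossprod(G, d))
  expect_equal(gls_solve(sys)$beta, as.numeric(ols))
  # scalar GLS closed form with diagonal V
  v <- runif(n, 0.5, 3)
  sys1 <- structure(list(Gmat = G[, 1, drop = FALSE], dvec = d,
                         V = diag(v), K = n, T = 1), class = "gls_system")
  expect_equal(gls_solve(sys1)$beta,
               sum(G[, 1] * d / v) / sum(G[, 1]^2 / v))
  # consistency: exact linear data is recovered under any valid V
  V <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
  b0 <- c(1, -2, 0.5)
  sysx <- structure(list(Gmat = G, dvec = as.numeric(G %*% b0), V = V,
                         K = n, T = 1), class = "gls_system")
  expect_equal(gls_solve(sysx)$beta, b0)
  # rank deficiency is reported
  G2 <- cbind(G[, 1], G[, 1])
  sysr <- structure(list(Gmat = G2, dvec = d, V = diag(1, n), K = n, T = 1),
                    class = "gls_system")
  expect_error(gls_solve(sysr), "rank deficient")
})

test_that("GLS estimate minimizes the generalized residual quadratic form", {
  set.seed(52)
  n <- 30
  G <- matrix(rnorm(n * 2), n, 2)
  d <- as.numeric(G %*% c(1, 2)) + rnorm(n)
  V <- crossprod(matrix(rnorm(n * n), n)) / n + diag(0.5, n)
  sys <- structure(list(Gmat = G, dvec = d, V = V, K = n, T = 1),
                   class = "gls_system")
  beta <- gls_solve(sys)$beta
  Vi <- solve(V)
  obj <- function(b) {
    r <- d - G %*% b
    as.numeric(t(r) %*% Vi %*% r)
  }
  opt <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(beta, opt$par, tolerance = 1e-3)
  expect_lte(obj(beta), opt$value + 1e-8)
})

test_that("delta-method residual covariance special cases", {
  ds <- lv_small_fixture()
  sm <- smooth_cell(ds$cells[[1]])
  sys <- assemble_system(ds$model, sm$fits)
  # beta = NULL: J = 0, so V is exactly Bdot Sigma_c Bdot' blockwise
  V0 <- residual_covariance(ds$model, sys, beta = NULL, structure = "full",
                            ridge_scale = 0)
  k <- 2
  rows <- (seq_len(21) - 1) * 16 + k
  direct <- sys$Bdot[[k]] %*% sys$Sigma_c[[k]] %*% t(sys$Bdot[[k]])
  expect_equal(V0[rows, rows], direct, tolerance = 1e-10)
  # zero coefficient covariance: only the ridge remains
  sys0 <- sys
  sys0$Sigma_c <- lapply(sys0$Sigma_c, function(S) S * 0)
  Vr <- residual_covariance(ds$model, sys0, beta = rep(0.02, 4),
                            structure = "full")
  expect_equal(Vr, diag(Vr[1, 1], 21 * 16))
  # the blocked covariance agrees with the full matrix on its blocks
  beta <- rep(0.02, 4)
  Vfull <- residual_covariance(ds$model, sys, beta, structure = "full")
  Vblk <- residual_covariance(ds$model, sys, beta, structure = "time_blocks")
  j <- 3
  rows <- (j - 1) * 16 + 1:16
  expect_equal(Vblk[rows, rows], Vfull[rows, rows], tolerance = 1e-8)
})

test_that("delta-method covariance matches Monte-Carlo residual covariance", {
  # fixed basis, penalty, and weights make the smoother an exact linear map
  # of the data, so the first-order propagation (linearized around the fit of
  # the noiseless truth) must reproduce the empirical residual covariance up
  # to Monte-Carlo error and second-order terms in the 5% noise
  model <- make_lotka_volterra(2)
  tg <- 0:20
  beta_true <- c(0.02, 0.02)
  X <- simulate_individual(model, beta_true, tg)
  tau <- 0.05
  basis <- build_basis(seq(0, 20, by = 2), tg)
  nv <- lapply(1:16, function(k) (tau * X[, k])^2)
  meas <- measurement_model(diag(1, 16), sigma = 0, tau = tau)
  mkfits <- function(Y) lapply(1:16, function(k) {
    fit_penalized(Y[, k], basis, 1 / nv[[k]], 0.01, noise_var = nv[[k]])
  })
  deltas <- sapply(1:500, function(r) {
    sys <- assemble_system(model, mkfits(observe(X, meas, seed = 1000 + r)))
    sys$dvec - sys$Gmat %*% beta_true
  })
  emp <- cov(t(deltas))
  sys0 <- assemble_system(model, mkfits(X))
  V <- residual_covariance(model, sys0, beta_true, structure = "full")
  # compare on the per-time diagonal blocks used by the FGLS weighting
  num <- den <- 0
  for (j in 1:21) {
    rows <- (j - 1) * 16 + 1:16
    num <- num + norm(emp[rows, rows] - V[rows, rows], "F")^2
    den <- den + norm(V[rows, rows], "F")^2
  }
  expect_lt(sqrt(num / den), 0.15)
})

test_that("FGLS recovers parameters from noiseless dense data", {
  fx <- lv_dense_fixture()
  est <- fgls_fit(fx$model, fx$fits)
  expect_rel_error(est$beta_hat, fx$beta_true, 0.01)
  expect_true(est$converged)
  # the first iterate is the ordinary least-squares solution
  sys <- assemble_system(fx$model, fx$fits)
  expect_equal(est$history[[1]], gls_solve(sys)$beta)
})

test_that("FGLS iterates settle down on a noisy cell", {
  ds <- lv_small_fixture()
  sm <- smooth_cell(ds$cells[[3]])
  est <- fgls_fit(ds$model, sm$fits)
  expect_true(est$converged)
  steps <- vapply(seq_len(length(est$history) - 1), function(i) {
    sqrt(sum((est$history[[i + 1]] - est$history[[i]])^2))
  }, numeric(1))
  if (length(steps) >= 2) {
    expect_lt(steps[length(steps)], steps[1])
  }
  ev <- eigen(est$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})

test_that("confidence intervals from C have near-nominal coverage", {
  model <- make_lotka_volterra(1)
  tg <- 0:20
  beta_true <- 0.02
  X <- simulate_individual(model, beta_true, tg)
  meas <- measurement_model(diag(1, 16), sigma = 0, tau = 0.05)
  cell0 <- cell_measurements("cov", tg, observe(X, meas, seed = 2))
  sm0 <- smooth_cell(cell0)
  kn <- lapply(sm0$fits, function(f) f$basis$knots)
  lam <- vapply(sm0$fits, `[[`, numeric(1), "lambda")
  hits <- vapply(1:300, function(r) {
    cell <- cell_measurements("cov", tg, observe(X, meas, seed = 5000 + r))
    sm <- smooth_cell(cell, knots = kn, lambda = lam, max_rounds = 2)
    est <- fgls_fit(model, sm$fits, max_iter = 8)
    half <- 1.96 * sqrt(est$C[1, 1])
    abs(est$beta_hat - beta_true) <= half
  }, logical(1))
  expect_gte(mean(hits), 0.88)
  expect_lte(mean(hits), 0.99)
})

test_that("unit rescaling transforms LV estimates as dimensional analysis says", {
  # concentrations x -> c x turns rates k into k / c
  fx <- lv_dense_fixture()
  cconst <- 2.5
  cell2 <- cell_measurements("scaled", fx$tgrid, fx$X * cconst)
  model2 <- make_lotka_volterra(4, x0 = rep(cconst, 16))
  sm2 <- smooth_cell(cell2, knots = seq(0, 20, by = 1))
  est2 <- fgls_fit(model2, sm2$fits)
  est1 <- fgls_fit(fx$model, fx$fits)
  expect_equal(est2$beta_hat, est1$beta_hat / cconst, tolerance = 1e-3)
})
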