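# Model containers, built-in systems, simulation, and the noise model.

test_that("rhs evaluates the printed right-hand sides", {
  lv <- make_lotka_volterra(1)
  expect_equal(rhs(lv, rep(1, 16), 0.02), (1:16) / 80 - 0.02)

  fp <- make_fp_maturation(1)
  expect_equal(rhs(fp, c(1, 1, 1), c(0.025, 0.05)),
               c(0.1 - 0.074, 0.025 - 0.054, 0.05 - 0.004))

  # Hill-form repressilator mRNA rate at zero protein: leak + full activation
  hill <- make_repressilator(expanded = FALSE)
  x <- c(0.5, 0, 0, 0, 0, 0)
  beta <- c(rep(0.16, 3), rep(0.0693, 3))
  expect_equal(rhs(hill, x, beta)[1], 0.0005 + 0.5 - 0.3466 * 0.5)

  # beta = 0 isolates h for any linear model
  x <- runif(16, 0.5, 2)
  expect_equal(rhs(lv, x, 0), (1:16) / 80 * x)
})

test_that("rhs validates input dimensions with informative errors", {
  lv <- make_lotka_volterra(2)
  expect_error(rhs(lv, rep(1, 15), c(0.02, 0.02)), "'x'")
  expect_error(rhs(lv, rep(1, 16), 0.02), "'beta'")
  expect_error(make_lotka_volterra(3), "divide 16")
  expect_error(make_fp_maturation(3), "steps")
})

test_that("every builtin linear model is affine in its parameters", {
  models <- list(make_lotka_volterra(1), make_lotka_volterra(8),
                 make_repressilator(TRUE), make_fp_maturation(1),
                 make_fp_maturation(2))
  set.seed(11)
  for (m in models) {
    for (rep in 1:3) {
      x <- runif(m$K, 0.2, 3)
      b1 <- runif(m$P, 0.01, 0.3)
      b2 <- runif(m$P, 0.01, 0.3)
      gap <- rhs(m, x, b1 + b2) - rhs(m, x, b1) - rhs(m, x, b2) +
        rhs(m, x, numeric(m$P))
      expect_lt(max(abs(gap)), 1e-10)
    }
  }
})

test_that("analytic state Jacobians match finite differences", {
  set.seed(12)
  models <- list(make_lotka_volterra(4), make_repressilator(TRUE),
                 make_fp_maturation(1), make_fp_maturation(2))
  betas <- list(runif(4, 0.01, 0.03),
                c(runif(3, 0.12, 0.2), runif(3, 0.05, 0.09)),
                c(0.025, 0.05), c(0.025, 0.05))
  for (i in seq_along(models)) {
    m <- models[[i]]
    x <- runif(m$K, 0.3, 2)
    Jfd <- gmgts:::fd_jacobian(function(z) rhs(m, z, betas[[i]]), x)
    expect_lt(max(abs(m$jac(x, betas[[i]], 0) - Jfd)), 1e-6)
  }
})

test_that("parameter tying in the Lotka-Volterra family follows n mod m", {
  lv2 <- make_lotka_volterra(2)
  x <- runif(16, 0.5, 2)
  G <- lv2$g(x, 0)
  # states 1, 3, 5, ... share column 1; states 2, 4, ... column 2
  expect_true(all(G[seq(1, 15, 2), 2] == 0))
  expect_true(all(G[seq(2, 16, 2), 1] == 0))
  nxt <- c(2:16, 1)
  expect_equal(G[cbind(1:16, rep(1:2, 8))], -x * x[nxt])
})

test_that("sample_parameters is reproducible and honours degenerate D", {
  d0 <- population_distribution("normal", b = c(1, 2), D = matrix(0, 2, 2))
  expect_equal(sample_parameters(d0, 5, seed = 1),
               matrix(rep(c(1, 2), each = 5), 5))
  d <- population_distribution("normal", 0.5, matrix(0.0156))
  A <- sample_parameters(d, 1e5, seed = 3)
  expect_lt(abs(mean(A) - 0.5), 3 * sqrt(0.0156 / 1e5))
  expect_identical(sample_parameters(d, 10, seed = 9),
                   sample_parameters(d, 10, seed = 9))
  dl <- population_distribution("lognormal", b = c(0, 1), D = diag(0, 2))
  expect_equal(sample_parameters(dl, 3, seed = 1)[1, ], exp(c(0, 1)))
  expect_error(population_distribution("normal", c(0, 0),
                                       matrix(c(1, 2, 2, 1), 2)),
               "semi-definite")
})

test_that("simulation reduces to exponential growth without interactions", {
  lv <- make_lotka_volterra(1)
  X <- simulate_individual(lv, 0, 0:10)
  expect_equal(unname(X[11, ]), exp((1:16) / 80 * 10), tolerance = 1e-6)
})

test_that("halving integration tolerances changes little; failures carry beta", {
  fp <- make_fp_maturation(1)
  tg <- seq(0, 200, by = 5)
  X1 <- simulate_individual(fp, c(0.025, 0.05), tg, rtol = 1e-6, atol = 1e-8)
  X2 <- simulate_individual(fp, c(0.025, 0.05), tg, rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(X1 - X2)), 1e-6)
  expect_error(simulate_individual(make_lotka_volterra(1), -5, 0:20), "-5")
})

test_that("repressilator expansion approaches the Hill form as kappa grows", {
  hill <- make_repressilator(expanded = FALSE)
  exp500 <- make_repressilator(expanded = TRUE, kappa = 500)
  beta <- c(rep(0.16, 3), rep(0.0693, 3))
  tg <- seq(0, 100, by = 2)
  Xh <- simulate_individual(hill, beta, tg)
  Xe <- simulate_individual(exp500, beta, tg)
  rel <- abs(Xe[, 1:6] - Xh) / (abs(Xh) + 1e-8)
  expect_lt(max(rel), 0.02)
  # quasi-steady-state occupancy matches the Hill denominator
  rep_of <- c(3, 1, 2)
  p <- Xe[30, 4:6]
  c_qss <- 0.00025 * p[rep_of]^2 / (0.00025 * p[rep_of]^2 + beta[1:3])
  expect_equal(unname(Xe[30, 7:9]), unname(c_qss), tolerance = 0.02)
})

test_that("repressilator expansion rhs at a steady state vanishes", {
  m <- make_repressilator(TRUE)
  beta <- c(rep(0.16, 3), rep(0.0693, 3))
  # symmetric equilibrium: solve numerically from a symmetric start
  f_sym <- function(z) {
    # z = (m, p, c) for all three genes simultaneously
    x <- c(rep(z[1], 3), rep(z[2], 3), rep(z[3], 3))
    rhs(m, x, beta)[c(1, 4, 7)]
  }
  z <- c(0.3, 80, 0.9)
  for (i in 1:50) {                     # damped fixed-point/Newton hybrid
    J <- gmgts:::fd_jacobian(f_sym, z)
    z <- z - as.numeric(solve(J, f_sym(z)))
  }
  x_star <- c(rep(z[1], 3), rep(z[2], 3), rep(z[3], 3))
  expect_lt(max(abs(rhs(m, x_star, beta))), 1e-9)
})

test_that("FP maturation model has the right asymptotics", {
  fp <- make_fp_maturation(1)
  X <- simulate_individual(fp, c(0.025, 0.05), seq(0, 2000, by = 100))
  expect_equal(unname(X[21, 1]), 0.1 / (0.07 + 0.004), tolerance = 1e-4)
  # absorbing zero state when transcription is off
  fp0 <- make_fp_maturation(1, k_r = 0)
  X0 <- simulate_individual(fp0, c(0.025, 0.05), 0:10)
  expect_true(all(abs(X0) < 1e-12))
})

test_that("observe applies the additive-plus-multiplicative noise model", {
  traj <- matrix(10, 1e5, 1)
  meas <- measurement_model(matrix(1), sigma = 1, tau = 0.05)
  y <- observe(traj, meas, seed = 5)
  v <- var(as.numeric(y))
  se <- 1.25 * sqrt(2 / (1e5 - 1))      # SE of a variance estimate
  expect_lt(abs(v - 1.25), 3 * se)
  # noiseless case is exact selection
  meas0 <- measurement_model(diag(1, 3)[2:3, ], sigma = 0, tau = 0)
  tr <- matrix(rnorm(30), 10, 3)
  expect_equal(observe(tr, meas0, seed = 1), tr[, 2:3])
  expect_error(measurement_model(matrix(c(1, 1, 0, 0, 0, 0), 2, 3)),
               "distinct")
})

test_that("generate_scenario reproduces the study conditions", {
  ds <- lv_small_fixture()
  expect_length(ds$cells[[1]]$t, 21)
  expect_equal(ds$cells[[1]]$t, 0:20)
  expect_equal(ncol(ds$cells[[1]]$y), 16)
  expect_equal(ds$generating_distribution$b, rep(0.02, 4))
  expect_equal(ds$generating_distribution$D, diag(0.005^2, 4))

  dsp <- generate_scenario("lotka_volterra_partial", seed = 1,
                           overrides = list(N = 2))
  expect_equal(ncol(dsp$cells[[1]]$y), 12)
  expect_equal(gmgts:::observed_indices(dsp$measurement), 5:16)
  expect_length(dsp$cells[[1]]$true_beta, 4)

  expect_error(generate_scenario("nope"), "lotka_volterra_full")

  # determinism
  d1 <- generate_scenario("fp_one_step", seed = 4, overrides = list(N = 3))
  d2 <- generate_scenario("fp_one_step", seed = 4, overrides = list(N = 3))
  expect_identical(d1$cells[[3]]$y, d2$cells[[3]]$y)
})

test_that("integrating then differentiating matches the rhs", {
  lv <- make_lotka_volterra(4)
  beta <- rep(0.02, 4)
  tg <- seq(0, 20, by = 0.05)
  X <- simulate_individual(lv, beta, tg)
  j <- 201
  num <- unname((X[j + 1, ] - X[j - 1, ]) / (2 * 0.05))
  expect_equal(num, rhs(lv, X[j, ], beta), tolerance = 1e-3)
})
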