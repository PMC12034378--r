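# Shared fixtures, built in code and cached per test run.

# A noiseless, densely sampled Lotka-Volterra cell (m = 4) with smoothing
# flexible enough to act as a near-interpolant; used as the Stage I oracle.
lv_dense_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- make_lotka_volterra(4)
      tg <- seq(0, 20, length.out = 201)
      beta_true <- c(0.021, 0.018, 0.022, 0.02)
      X <- simulate_individual(model, beta_true, tg)
      cell <- cell_measurements("dense", tg, X)
      sm <- smooth_cell(cell, knots = seq(0, 20, by = 1))
      cache <<- list(model = model, tgrid = tg, beta_true = beta_true,
                     X = X, cell = cell, fits = sm$fits)
    }
    cache
  }
})

# A small noisy LV dataset shared by several tests.
lv_small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scenario("lotka_volterra_full", seed = 42,
                                  overrides = list(N = 12))
    }
    cache
  }
})

# Quick constructor for individual estimates in Stage II tests.
mk_est <- function(beta, C, id = NA) {
  individual_estimate(beta, as.matrix(C), n_iter = 1, converged = TRUE,
                      cell_id = id)
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(sqrt(sum((value - truth)^2)) / sqrt(sum(truth^2)), tol)
}
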