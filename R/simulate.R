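# Forward simulation of individual cells and synthetic-data generation for
# the built-in scenarios.

#' Sample cell-specific parameter vectors from a population distribution
#'
#' @param dist a [population_distribution].
#' @param N number of cells.
#' @param seed integer seed; the same seed reproduces the same draws.
#' @return `N x P` matrix, one parameter vector per row. For the log-normal
#'   family the rows are `exp` of multivariate normal draws.
#' @export
sample_parameters <- function(dist, N, seed = NULL) {
  stopifnot(inherits(dist, "population_dist"))
  B <- with_seed(seed, rmvnorm_psd(N, dist$b, dist$D))
  if (dist$family == "lognormal") B <- exp(B)
  colnames(B) <- NULL
  B
}

#' Numerically integrate one cell's ODE system
#'
#' Solves `xdot = g(x) beta + h(x)` from the model's known initial condition
#' with a stiff-capable solver ([deSolve::lsoda]).
#'
#' @param model an [ode_model].
#' @param beta free-parameter vector (length `model$P`).
#' @param tgrid increasing time grid starting at the model's initial time.
#' @param rtol,atol relative/absolute integration tolerances. Defaults are
#'   tight (1e-8 / 1e-10) because generated data must be more accurate than
#'   any downstream inference; inference loops use looser tolerances.
#' @return `T x K` matrix of states on `tgrid`.
#' @export
simulate_individual <- function(model, beta, tgrid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"))
  if (length(beta) != model$P) {
    stop("'beta' has length ", length(beta), ", expected P = ", model$P)
  }
  tgrid <- as.numeric(tgrid)
  if (any(diff(tgrid) <= 0)) stop("'tgrid' must be strictly increasing")
  derivs <- function(t, x, parms) list(rhs(model, x, parms, t))
  # capture.output: keep solver diagnostics out of the console; failures are
  # reported through the R error below
  utils::capture.output(
    sol <- suppressWarnings(
      deSolve::lsoda(y = model$x0, times = tgrid, func = derivs,
                     parms = as.numeric(beta), rtol = rtol, atol = atol)))
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(tgrid) ||
      !all(is.finite(sol[, -1]))) {
    stop("ODE integration failed for beta = (",
         paste(signif(beta, 6), collapse = ", "), ")")
  }
  X <- unname(sol[, -1, drop = FALSE])
  colnames(X) <- model$state_names
  X
}

#' Apply the measurement model to a trajectory
#'
#' Selects observed states with `Q` and adds independent Gaussian noise with
#' variance `sigma_k^2 + tau_k^2 * x_k(t_j)^2` per observation.
#'
#' @param traj `T x K` state matrix (noise-free trajectory).
#' @param meas a [measurement_model].
#' @param seed integer seed for reproducibility.
#' @return `T x K_obs` matrix of noisy observations.
#' @export
observe <- function(traj, meas, seed = NULL) {
  stopifnot(inherits(meas, "measurement_model"))
  traj <- as.matrix(traj)
  if (!all(is.finite(traj))) stop("'traj' must be finite")
  if (ncol(traj) != ncol(meas$Q)) {
    stop("'traj' has ", ncol(traj), " states but Q has ", ncol(meas$Q),
         " columns")
  }
  Xobs <- traj %*% t(meas$Q)
  sdmat <- sqrt(matrix(meas$sigma^2, nrow(Xobs), ncol(Xobs), byrow = TRUE) +
                  matrix(meas$tau^2, nrow(Xobs), ncol(Xobs), byrow = TRUE) *
                  Xobs^2)
  eps <- with_seed(seed,
                   matrix(stats::rnorm(length(Xobs)), nrow(Xobs)) * sdmat)
  Xobs + eps
}

#' Scenario registry (defaults for the built-in simulation studies)
#' @keywords internal
#' @noRd
scenario_defaults <- function(name) {
  switch(name,
    lotka_volterra_full = list(
      model_args = list(m = 4),
      model_fun = "make_lotka_volterra",
      N = 100, tgrid = 0:20, tau = 0.05, sigma = 0,
      observed = 1:16,
      dist = function(args) population_distribution(
        "normal", b = rep(0.02, args$m), D = diag(0.005^2, args$m))
    ),
    lotka_volterra_partial = list(
      model_args = list(m = 4),
      model_fun = "make_lotka_volterra",
      N = 100, tgrid = 0:20, tau = 0.05, sigma = 0,
      observed = 5:16,  # first four states hidden
      dist = function(args) population_distribution(
        "normal", b = rep(0.02, args$m), D = diag(0.005^2, args$m))
    ),
    repressilator = list(
      model_args = list(expanded = TRUE),
      model_fun = "make_repressilator",
      N = 100, tgrid = seq(0, 100, by = 5), tau = 0.05, sigma = 0,
      observed = 1:6,   # mRNAs and proteins measured; complexes hidden
      dist = function(args) {
        b <- c(rep(0.16, 3), rep(0.0693, 3))
        sds <- 0.1 * b                      # CV 0.1 for every parameter
        R <- diag(1, 6)
        for (n in 1:3) {                    # corr 0.5 within (alpha_n, beta_n)
          R[n, n + 3] <- R[n + 3, n] <- 0.5
        }
        population_distribution("normal", b = b, D = outer(sds, sds) * R)
      }
    ),
    fp_one_step = list(
      model_args = list(steps = 1),
      model_fun = "make_fp_maturation",
      N = 500, tgrid = seq(0, 200, by = 5), tau = 0.05, sigma = 0,
      observed = 3,     # only mature fluorescent protein measured
      dist = function(args) population_distribution(
        "normal", b = c(0.025, 0.05),
        D = diag((0.25 * c(0.025, 0.05))^2))  # CV 0.25
    ),
    fp_two_step = list(
      model_args = list(steps = 2),
      model_fun = "make_fp_maturation",
      N = 500, tgrid = seq(0, 200, by = 5), tau = 0.05, sigma = 0,
      observed = 4,
      dist = function(args) population_distribution(
        "normal", b = c(0.025, 0.05),
        D = diag((0.25 * c(0.025, 0.05))^2))
    ),
    stop("unknown scenario '", name, "'; valid ids: lotka_volterra_full, ",
         "lotka_volterra_partial, repressilator, fp_one_step, fp_two_step")
  )
}

#' Generate a synthetic population dataset for a built-in scenario
#'
#' Samples `N` cell-specific parameter vectors from the scenario's population
#' distribution, integrates each cell's ODE system, and applies the
#' measurement model. Scenario defaults (sample sizes, time grids, noise
#' levels, population distributions) follow the simulation studies the
#' built-in systems come from; see the package vignette.
#'
#' @param name scenario id: one of `"lotka_volterra_full"`,
#'   `"lotka_volterra_partial"`, `"repressilator"`, `"fp_one_step"`,
#'   `"fp_two_step"`.
#' @param seed integer seed controlling both parameter sampling and noise.
#' @param overrides named list overriding defaults; recognized keys:
#'   `N`, `tgrid`, `tau`, `sigma`, `model_args` (list passed to the model
#'   constructor), `observed` (state indices), `dist`
#'   (a [population_distribution]).
#' @return A [population_dataset] with ground-truth parameters stored per cell
#'   and the generating distribution attached.
#' @export
generate_scenario <- function(name, seed = 1, overrides = list()) {
  def <- scenario_defaults(name)
  for (key in intersect(names(overrides),
                        c("N", "tgrid", "tau", "sigma", "observed"))) {
    def[[key]] <- overrides[[key]]
  }
  if (!is.null(overrides$model_args)) {
    def$model_args <- utils::modifyList(def$model_args, overrides$model_args)
  }
  model <- do.call(def$model_fun, def$model_args)
  dist <- if (!is.null(overrides$dist)) overrides$dist
          else def$dist(def$model_args)
  Q <- diag(1, model$K)[def$observed, , drop = FALSE]
  meas <- measurement_model(Q, sigma = def$sigma, tau = def$tau)

  betas <- sample_parameters(dist, def$N, seed = seed)
  cells <- vector("list", def$N)
  noise_seeds <- with_seed(seed + 1L,
                           sample.int(.Machine$integer.max - 1L, def$N))
  for (i in seq_len(def$N)) {
    traj <- simulate_individual(model, betas[i, ], def$tgrid)
    y <- observe(traj, meas, seed = noise_seeds[i])
    cells[[i]] <- cell_measurements(cell_id = sprintf("cell%03d", i),
                                    t = def$tgrid, y = y,
                                    true_beta = betas[i, ])
  }
  population_dataset(cells, model, meas, generating_distribution = dist,
                     seed = seed, scenario = name)
}
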