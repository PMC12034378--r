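# Model containers for nonlinear mixed-effects ODE systems that are linear in
# their free kinetic parameters: xdot = g(x) %*% beta + h(x).

#' Define an ODE model that is linear in its free parameters
#'
#' Represents a K-dimensional ODE system whose right-hand side decomposes as
#' `g(x) %*% beta + h(x)`, where `beta` is the vector of free (cell-specific)
#' kinetic parameters. Mass-action kinetics produce systems of this form,
#' which is what makes gradient matching a linear regression problem.
#'
#' @param g function of `(x, t)` returning the `K x P` coefficient matrix
#'   multiplying `beta`. Must not depend on `beta`.
#' @param h function of `(x, t)` returning the length-`K` parameter-free part
#'   of the right-hand side.
#' @param x0 numeric vector of length `K`; the known initial condition.
#' @param state_names,param_names character identifiers (lengths `K` and `P`).
#' @param fixed_params named numeric vector of rate constants folded into
#'   `g`/`h` (kept for bookkeeping and serialization).
#' @param f optional function `(x, beta, t)` giving the right-hand side
#'   directly, for models that are *not* linear in their parameters (such
#'   models can be simulated and fit by trajectory matching, but not by
#'   gradient matching).
#' @param jac optional analytic state Jacobian `(x, beta, t) -> K x K`
#'   (`d rhs / d x`); a central finite-difference Jacobian is used when
#'   absent.
#' @param name short model identifier used in dataset sidecar files.
#' @param t0 initial time of the system (default 0).
#'
#' @return An object of class `ode_model` with fields `K`, `P`,
#'   `state_names`, `param_names`, `g`, `h`, `x0`, `fixed_params`, `linear`.
#' @export
ode_model <- function(g = NULL, h = NULL, x0, state_names, param_names,
                      fixed_params = numeric(), f = NULL, name = "custom",
                      t0 = 0, jac = NULL) {
  K <- length(state_names)
  P <- length(param_names)
  if (length(x0) != K) {
    stop("'x0' must have length K = ", K, " (one value per state)")
  }
  linear <- !is.null(g) && !is.null(h)
  if (!linear && is.null(f)) {
    stop("either both 'g' and 'h', or 'f', must be supplied")
  }
  if (linear) {
    gfun <- if (length(formals(g)) >= 2) g else function(x, t) g(x)
    hfun <- if (length(formals(h)) >= 2) h else function(x, t) h(x)
  } else {
    gfun <- NULL
    hfun <- NULL
  }
  structure(
    list(K = K, P = P, state_names = state_names, param_names = param_names,
         g = gfun, h = hfun, f = f, x0 = as.numeric(x0),
         fixed_params = fixed_params, linear = linear, name = name, t0 = t0,
         jac = jac),
    class = "ode_model"
  )
}

#' Evaluate the ODE right-hand side
#'
#' For linear-in-parameters models this is exactly `g(x) %*% beta + h(x)`.
#'
#' @param model an [ode_model].
#' @param x numeric state vector of length `model$K`.
#' @param beta numeric free-parameter vector of length `model$P`.
#' @param t time (only relevant for time-gated inputs; default 0).
#' @return numeric vector of length `model$K`.
#' @export
rhs <- function(model, x, beta, t = 0) {
  stopifnot(inherits(model, "ode_model"))
  if (length(x) != model$K) {
    stop("'x' has length ", length(x), " but the model has K = ", model$K,
         " states")
  }
  if (length(beta) != model$P) {
    stop("'beta' has length ", length(beta), " but the model has P = ",
         model$P, " free parameters")
  }
  if (model$linear) {
    as.numeric(model$g(x, t) %*% beta + model$h(x, t))
  } else {
    as.numeric(model$f(x, beta, t))
  }
}

#' Jacobian of the right-hand side with respect to the state
#' @keywords internal
#' @noRd
rhs_jacobian_x <- function(model, x, beta, t = 0) {
  if (!is.null(model$jac)) {
    model$jac(x, beta, t)
  } else {
    fd_jacobian(function(z) rhs(model, z, beta, t), x)
  }
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, ": K = ", x$K, " states, P = ", x$P,
      " free parameters (", if (x$linear) "linear" else "nonlinear",
      " in parameters)\n", sep = "")
  cat("  states:     ", paste(x$state_names, collapse = ", "), "\n")
  cat("  parameters: ", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Define a measurement model (state selection plus Gaussian noise)
#'
#' Observations are `y(t_j) = Q x(t_j) + eps(t_j)` where `Q` is a binary
#' selection matrix and the noise component for observed state k has variance
#' `sigma_k^2 + tau_k^2 * x_k(t_j)^2` (additive plus multiplicative).
#'
#' @param Q binary `K_obs x K` selection matrix; each row must contain exactly
#'   one 1 and rows must be pairwise distinct.
#' @param sigma nonnegative additive noise SDs (length `K_obs` or 1, recycled).
#' @param tau nonnegative multiplicative noise factors (length `K_obs` or 1).
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(Q, sigma = 0, tau = 0) {
  Q <- as.matrix(Q)
  if (!all(Q %in% c(0, 1)) || any(rowSums(Q) != 1)) {
    stop("every row of 'Q' must be a unit selection row (exactly one 1)")
  }
  if (anyDuplicated(apply(Q, 1, which.max))) {
    stop("rows of 'Q' must select pairwise distinct states")
  }
  K_obs <- nrow(Q)
  sigma <- rep_len(as.numeric(sigma), K_obs)
  tau <- rep_len(as.numeric(tau), K_obs)
  if (any(sigma < 0) || any(tau < 0)) {
    stop("'sigma' and 'tau' must be nonnegative")
  }
  structure(list(Q = Q, sigma = sigma, tau = tau, K_obs = K_obs),
            class = "measurement_model")
}

#' Indices of observed states encoded by the selection matrix
#' @keywords internal
#' @noRd
observed_indices <- function(meas) apply(meas$Q, 1, which.max)

#' Define a population distribution of cell-specific parameters
#'
#' Cell-specific parameter vectors are modeled as draws from a multivariate
#' normal `N(b, D)` (fixed effects `b`, random-effects covariance `D`), or as
#' exponentials of such draws for the log-normal family (in which case `b` and
#' `D` are the log-mean and log-covariance).
#'
#' @param family `"normal"` or `"lognormal"`.
#' @param b fixed-effects vector (log-mean for the log-normal family).
#' @param D symmetric positive semi-definite random-effects covariance.
#' @return An object of class `population_dist`.
#' @export
population_distribution <- function(family = c("normal", "lognormal"), b, D) {
  family <- match.arg(family)
  b <- as.numeric(b)
  D <- as.matrix(D)
  if (nrow(D) != length(b) || ncol(D) != length(b)) {
    stop("'D' must be ", length(b), " x ", length(b))
  }
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1e-300))) {
    stop("'D' must be positive semi-definite")
  }
  structure(list(family = family, b = b, D = (D + t(D)) / 2),
            class = "population_dist")
}

#' Bundle one cell's measurements
#'
#' @param cell_id identifier.
#' @param t strictly increasing vector of `T` observation times.
#' @param y `T x K_obs` matrix of observed values.
#' @param true_beta optional ground-truth parameter vector (simulations only).
#' @return An object of class `cell_measurements`.
#' @export
cell_measurements <- function(cell_id, t, y, true_beta = NULL) {
  t <- as.numeric(t)
  y <- as.matrix(y)
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing")
  if (nrow(y) != length(t)) {
    stop("'y' must have one row per time point (", length(t), ")")
  }
  structure(list(cell_id = cell_id, t = t, y = y,
                 true_beta = if (is.null(true_beta)) NULL
                             else as.numeric(true_beta)),
            class = "cell_measurements")
}

#' Bundle a population of measured cells with its model
#'
#' @param cells list of [cell_measurements] sharing the same number of
#'   observed states.
#' @param model the generating / assumed [ode_model].
#' @param measurement the [measurement_model].
#' @param generating_distribution optional [population_distribution]
#'   (ground truth; simulations only).
#' @param seed integer seed used for generation (bookkeeping).
#' @param scenario optional scenario identifier.
#' @return An object of class `population_dataset`.
#' @export
population_dataset <- function(cells, model, measurement,
                               generating_distribution = NULL, seed = NA,
                               scenario = NULL) {
  if (length(cells) < 1) stop("need at least one cell")
  kobs <- vapply(cells, function(c) ncol(c$y), integer(1))
  if (length(unique(kobs)) != 1) {
    stop("all cells must share the same number of observed states")
  }
  if (kobs[1] != measurement$K_obs) {
    stop("cells have ", kobs[1], " observed states but Q selects ",
         measurement$K_obs)
  }
  structure(list(cells = cells, model = model, measurement = measurement,
                 generating_distribution = generating_distribution,
                 seed = seed, scenario = scenario),
            class = "population_dataset")
}

#' @export
print.population_dataset <- function(x, ...) {
  cat("<population_dataset> ", length(x$cells), " cells, model '",
      x$model$name, "' (K = ", x$model$K, ", observed = ",
      x$measurement$K_obs, "), T = ", length(x$cells[[1]]$t),
      " time points\n", sep = "")
  invisible(x)
}
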