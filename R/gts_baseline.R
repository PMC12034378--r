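# Trajectory-matching baseline: classical first stage that fits each cell by
# weighted nonlinear least squares against numerically integrated ODE
# solutions, with multistart initialization. Shares Stage II (EM) with the
# gradient-matching pipeline.

#' Fit one cell by trajectory matching (multistart nonlinear least squares)
#'
#' Minimizes `sum_jk (y_jk - [Q x(t_j; beta)]_k)^2 / (sigma_k^2 +
#' tau_k^2 xhat_jk^2)` over `beta` with Levenberg-Marquardt
#' ([minpack.lm::nls.lm]), restarting from `n_starts` log-uniform draws around
#' a data-informed center. The observation weights reuse the noise parameters
#' estimated during smoothing so that the baseline and the gradient-matching
#' pipeline weight the data identically.
#'
#' @param cell a [cell_measurements].
#' @param model an [ode_model] (need not be linear in parameters).
#' @param weights `T x K_obs` matrix of observation weights (typically
#'   `1 / (sigma_hat^2 + tau_hat^2 xhat^2)` from [smooth_cell]).
#' @param obs_idx indices of the observed states.
#' @param center data-informed center of the multistart cloud; defaults to
#'   the absolute structural initial guess when the model is linear in
#'   parameters, otherwise to 1s.
#' @param n_starts number of starting points.
#' @param spread half-width (in log10 units) of the log-uniform start cloud.
#' @param seed seed for the start draws.
#' @param rtol integration tolerance inside the optimizer.
#' @return An object of class `trajectory_fit` with `beta_hat`, `C` (inverse
#'   Gauss-Newton information at the optimum), `best_objective`, `n_starts`,
#'   and `n_integrations`.
#' @export
trajectory_fit <- function(cell, model, weights, obs_idx,
                           center = NULL, n_starts = 10, spread = 1,
                           seed = NULL, rtol = 1e-6) {
  y <- cell$y
  sw <- sqrt(as.matrix(weights))
  n_integrations <- 0L
  # optimized over log-parameters: rate constants stay positive and the
  # multistart cloud is log-uniform by construction
  resid_fun <- function(theta) {
    X <- tryCatch(simulate_individual(model, exp(theta), cell$t,
                                      rtol = rtol, atol = rtol * 1e-2),
                  error = function(e) NULL)
    n_integrations <<- n_integrations + 1L
    if (is.null(X)) return(rep(1e6, length(y)))
    as.numeric((y - X[, obs_idx, drop = FALSE]) * sw)
  }
  if (is.null(center)) {
    center <- rep(1, model$P)
  }
  center <- pmax(abs(center), 1e-6)
  starts <- with_seed(seed, {
    U <- matrix(stats::runif(n_starts * model$P, -spread, spread),
                n_starts, model$P)
    sweep(U * log(10), 2, log(center), `+`)  # log10-uniform around center
  })
  starts[1, ] <- log(center)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ptol = 1e-8, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par))) next
    obj <- sum(fit$fvec^2)
    if (obj >= 1e10) next               # stuck in a non-integrable region
    if (is.null(best) || obj < best$obj) {
      best <- list(par = as.numeric(fit$par), obj = obj)
    }
  }
  if (is.null(best)) {
    stop("all ", n_starts, " trajectory-matching starts failed for cell ",
         cell$cell_id)
  }
  Jt <- fd_jacobian(resid_fun, best$par)
  beta_hat <- exp(best$par)
  J <- Jt %*% diag(1 / beta_hat, length(beta_hat))  # back to natural scale
  C <- tryCatch(chol2inv(chol(crossprod(J))),
                error = function(e) {
                  MASS_like <- crossprod(J) + diag(1e-10, ncol(J))
                  tryCatch(qr.solve(MASS_like), error = function(e2) {
                    diag(beta_hat^2, length(beta_hat))
                  })
                })
  if (!all(is.finite(C))) C <- diag(beta_hat^2, length(beta_hat))
  structure(list(beta_hat = beta_hat, C = (C + t(C)) / 2,
                 best_objective = best$obj, n_starts = n_starts,
                 n_integrations = n_integrations,
                 cell_id = cell$cell_id),
            class = "trajectory_fit")
}

#' Full trajectory-matching (GTS) pipeline
#'
#' Smooths the data (only to estimate noise parameters for the weights), fits
#' every cell by [trajectory_fit], and combines the estimates with the same
#' Stage II EM as the gradient-matching pipeline. Cells whose fits fail are
#' skipped with a warning provided they are fewer than 10%.
#'
#' @param dataset a [population_dataset].
#' @param family `"normal"` or `"lognormal"` Stage II.
#' @param n_starts,spread,rtol passed to [trajectory_fit].
#' @param seed seed for the multistart draws.
#' @param smoothing optional precomputed [smooth_dataset] result.
#' @return list with `population` (a `population_estimate`), `individual`
#'   (list of per-cell results), and `n_integrations` (total).
#' @export
gts_pipeline <- function(dataset, family = c("normal", "lognormal"),
                         n_starts = 10, spread = 1, rtol = 1e-6, seed = 1,
                         smoothing = NULL) {
  family <- match.arg(family)
  obs_idx <- observed_indices(dataset$measurement)
  sm <- smoothing %||% smooth_dataset(dataset)
  N <- length(dataset$cells)
  start_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, N))
  fits <- vector("list", N)
  failed <- logical(N)
  for (i in seq_len(N)) {
    cf <- sm$cells[[i]]
    W <- vapply(seq_along(obs_idx), function(u) {
      nv <- cf$noise[[u]]$sigma_hat^2 +
        cf$noise[[u]]$tau_hat^2 * cf$fits[[u]]$fitted^2
      1 / pmax(nv, 1e-12 * max(mean(dataset$cells[[i]]$y[, u]^2), 1e-12))
    }, numeric(length(dataset$cells[[i]]$t)))
    center <- if (dataset$model$linear) {
      abs(default_initial_guess(dataset$model, cf$fits, obs_idx))
    } else NULL
    fits[[i]] <- tryCatch(
      trajectory_fit(dataset$cells[[i]], dataset$model, W, obs_idx,
                     center = center, n_starts = n_starts, spread = spread,
                     seed = start_seeds[i], rtol = rtol),
      error = function(e) NULL)
    failed[i] <- is.null(fits[[i]])
  }
  if (any(failed)) {
    if (mean(failed) >= 0.1) {
      stop(sum(failed), " of ", N, " cells failed trajectory matching")
    }
    warning(sum(failed), " cells failed trajectory matching and were skipped")
  }
  ok <- which(!failed)
  ests <- lapply(ok, function(i) {
    f <- fits[[i]]
    individual_estimate(f$beta_hat, f$C, n_iter = NA, converged = TRUE,
                        cell_id = f$cell_id,
                        n_integrations = f$n_integrations)
  })
  pop <- if (family == "normal") em_fit(ests) else lognormal_fit(ests)
  list(population = pop, individual = fits,
       n_integrations = sum(vapply(fits[ok], `[[`, integer(1),
                                   "n_integrations")))
}
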