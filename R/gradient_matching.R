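# Stage I with full state information: gradient matching by feasible
# generalized least squares (FGLS). Writing the smoothed gradients against the
# model right-hand side gives the linear model
#   xdot_hat(t_j) - h(xhat(t_j)) = g(xhat(t_j)) beta + Delta,
# stacked over time points (row block j holds the K states at t_j). The
# residual covariance Var(Delta) is inherited from the spline-coefficient
# uncertainty through a first-order delta method and is re-estimated in
# alternation with the GLS solve.
#
# The full (TK x TK) delta-method covariance is rank deficient: the residuals
# are driven by only n_basis coefficients per state, so most of the TK
# directions carry (numerically) zero claimed variance, and generalized least
# squares against it amplifies smoothing bias without bound. The FGLS
# weighting therefore uses the covariance restricted to its per-time-point
# K x K diagonal blocks (cross-state correlation and heteroscedasticity kept,
# cross-time correlation dropped), which is well conditioned; the full matrix
# remains available for uncertainty validation.

#' Assemble the stacked gradient-matching linear system
#'
#' @param model a linear-in-parameters [ode_model].
#' @param fits list of `model$K` [fit_penalized] objects (one per state, in
#'   state order; full observation).
#' @param V optional initial residual covariance (defaults to the identity).
#' @return An object of class `gls_system` with `Gmat` ((T K) x P stacked
#'   design), `dvec` (stacked response), `V`, and the smoothing ingredients
#'   (`Xhat`, `Xdot`, per-state bases and coefficient covariances) needed for
#'   the delta-method covariance update.
#' @export
assemble_system <- function(model, fits, V = NULL) {
  stopifnot(inherits(model, "ode_model"))
  if (!model$linear) stop("gradient matching requires g/h decomposition")
  if (length(fits) != model$K) {
    stop("need one spline fit per state: got ", length(fits),
         ", expected K = ", model$K)
  }
  Tn <- length(fits[[1]]$fitted)
  K <- model$K; P <- model$P
  Xhat <- vapply(fits, `[[`, numeric(Tn), "fitted")
  Xdot <- vapply(fits, `[[`, numeric(Tn), "fitted_deriv")
  tgrid <- fits[[1]]$basis$tgrid
  Gmat <- matrix(0, Tn * K, P)
  dvec <- numeric(Tn * K)
  for (j in seq_len(Tn)) {
    rows <- (j - 1) * K + seq_len(K)
    xj <- Xhat[j, ]
    Gmat[rows, ] <- model$g(xj, tgrid[j])
    dvec[rows] <- Xdot[j, ] - model$h(xj, tgrid[j])
  }
  structure(list(Gmat = Gmat, dvec = dvec,
                 V = V %||% diag(1, Tn * K),
                 Xhat = Xhat, Xdot = Xdot, tgrid = tgrid,
                 T = Tn, K = K, P = P,
                 B = lapply(fits, function(f) f$basis$B),
                 Bdot = lapply(fits, function(f) f$basis$Bdot),
                 Sigma_c = lapply(fits, `[[`, "coef_cov")),
            class = "gls_system")
}

#' Generalized least-squares solve of an assembled system
#'
#' Computes `beta = (G' V^-1 G)^-1 G' V^-1 d` through a Cholesky
#' factorization of `V`; when `V` is a list of per-time-point blocks the
#' factorization is done block by block and the full (TK)-dimensional matrix
#' is never formed.
#'
#' @param sys a [assemble_system] result (its `V` field is used; either a
#'   (TK x TK) matrix or a list of T matrices of dimension K x K).
#' @return list with `beta` and `C = (G' V^-1 G)^-1`.
#' @export
gls_solve <- function(sys) {
  if (is.list(sys$V)) {
    K <- sys$K
    Gw <- sys$Gmat
    dw <- sys$dvec
    for (j in seq_along(sys$V)) {
      rows <- (j - 1) * K + seq_len(K)
      Rt <- t(chol((sys$V[[j]] + t(sys$V[[j]])) / 2))
      Gw[rows, ] <- forwardsolve(Rt, Gw[rows, , drop = FALSE])
      dw[rows] <- forwardsolve(Rt, dw[rows])
    }
  } else {
    Rt <- t(chol((sys$V + t(sys$V)) / 2))
    Gw <- forwardsolve(Rt, sys$Gmat)
    dw <- forwardsolve(Rt, sys$dvec)
  }
  qrG <- qr(Gw)
  if (qrG$rank < ncol(Gw)) {
    bad <- paste(setdiff(seq_len(ncol(Gw)), qrG$pivot[seq_len(qrG$rank)]),
                 collapse = ", ")
    stop("design matrix is rank deficient (near-collinear columns: ",
         bad, ")")
  }
  beta <- qr.coef(qrG, dw)
  C <- chol2inv(chol(crossprod(Gw)))
  list(beta = as.numeric(beta), C = (C + t(C)) / 2)
}

#' Per-time-point delta-method covariance blocks of the residuals
#'
#' For time point j the residual error is, to first order,
#' `sum_k' m_{j,k'} delta_c_{k'}` with
#' `m_{j,k'} = e_{k'} Bdot[j,] - J[, k'] B[j,]`, giving the K x K block
#' `sum_k' m_{j,k'} Sigma_c_{k'} m_{j,k'}'`.
#' @keywords internal
#' @noRd
delta_V_blocks <- function(model, sys, beta = NULL, ridge_scale = 1e-8) {
  Tn <- sys$T; K <- sys$K
  blocks <- vector("list", Tn)
  tr_total <- 0
  for (j in seq_len(Tn)) {
    J <- if (is.null(beta)) matrix(0, K, K) else
      rhs_jacobian_x(model, sys$Xhat[j, ], beta, sys$tgrid[j])
    Vj <- matrix(0, K, K)
    for (kp in seq_len(K)) {
      Sc <- sys$Sigma_c[[kp]]
      if (is.null(Sc)) next
      bj <- sys$B[[kp]][j, ]
      bdj <- sys$Bdot[[kp]][j, ]
      q1 <- Sc %*% bj
      a <- sum(bj * q1)           # Var xhat_k'(t_j)
      bq <- sum(bdj * q1)         # Cov(xdot_k', xhat_k')
      c2 <- sum(bdj * (Sc %*% bdj))  # Var xdot_k'(t_j)
      Jc <- J[, kp]
      Vj <- Vj + outer(Jc, Jc) * a
      Vj[, kp] <- Vj[, kp] - Jc * bq
      Vj[kp, ] <- Vj[kp, ] - Jc * bq
      Vj[kp, kp] <- Vj[kp, kp] + c2
    }
    blocks[[j]] <- (Vj + t(Vj)) / 2
    tr_total <- tr_total + sum(diag(Vj))
  }
  ridge <- ridge_scale * max(tr_total, 1e-300) / (Tn * K)
  lapply(blocks, function(Vj) Vj + diag(ridge, K))
}

#' Delta-method residual covariance for the gradient-matching system
#'
#' First-order propagation of the spline-coefficient uncertainty to both
#' sides of the linear model: the residual error is approximately
#' `(Bdot_blk - J(xhat, beta) B_blk) delta_c`, where `J` is the state Jacobian
#' of the right-hand side at the current parameter estimate, so
#' `Var(Delta) = M Sigma_c M' + ridge I` with `Sigma_c` block-diagonal over
#' states. The ridge (`1e-8 * trace / (T K)`) guards positive definiteness.
#'
#' With `structure = "time_blocks"` (the default used inside FGLS) the
#' covariance is restricted to its per-time-point K x K diagonal blocks; the
#' rank-deficient cross-time part, against which generalized least squares is
#' ill posed, is dropped. `structure = "full"` returns the complete matrix
#' (used for Monte-Carlo validation of the uncertainty propagation).
#'
#' @param model the [ode_model].
#' @param sys the [assemble_system] result.
#' @param beta current parameter estimate (NULL for the initialization stage,
#'   in which case the Jacobian coupling is zero).
#' @param structure `"time_blocks"` or `"full"`.
#' @param ridge_scale relative ridge size.
#' @return `(T K) x (T K)` covariance matrix.
#' @export
residual_covariance <- function(model, sys, beta = NULL,
                                structure = c("time_blocks", "full"),
                                ridge_scale = 1e-8) {
  structure <- match.arg(structure)
  Tn <- sys$T; K <- sys$K
  TK <- Tn * K
  if (structure == "time_blocks") {
    blocks <- delta_V_blocks(model, sys, beta, ridge_scale)
    V <- matrix(0, TK, TK)
    for (j in seq_len(Tn)) {
      rows <- (j - 1) * K + seq_len(K)
      V[rows, rows] <- blocks[[j]]
    }
    return(V)
  }
  Jarr <- array(0, c(K, K, Tn))
  if (!is.null(beta)) {
    for (j in seq_len(Tn)) {
      Jarr[, , j] <- rhs_jacobian_x(model, sys$Xhat[j, ], beta, sys$tgrid[j])
    }
  }
  V <- matrix(0, TK, TK)
  for (kp in seq_len(K)) {
    Sc <- sys$Sigma_c[[kp]]
    if (is.null(Sc)) next
    nb <- ncol(sys$B[[kp]])
    M <- matrix(0, TK, nb)
    for (k in seq_len(K)) {
      rows <- (seq_len(Tn) - 1) * K + k
      M[rows, ] <- -Jarr[k, kp, ] * sys$B[[kp]]
      if (k == kp) M[rows, ] <- M[rows, ] + sys$Bdot[[kp]]
    }
    V <- V + M %*% Sc %*% t(M)
  }
  V <- (V + t(V)) / 2
  ridge <- ridge_scale * max(sum(diag(V)), 1e-300) / TK
  V + diag(ridge, TK)
}

#' Whitened design `W G` with `W` the inverse of the working covariance
#' @keywords internal
#' @noRd
whiten_design <- function(sys) {
  U <- sys$Gmat
  if (is.list(sys$V)) {
    K <- sys$K
    for (j in seq_along(sys$V)) {
      rows <- (j - 1) * K + seq_len(K)
      U[rows, ] <- solve(sys$V[[j]], U[rows, , drop = FALSE])
    }
  } else {
    U <- solve(sys$V, U)
  }
  U
}

#' Sandwich parameter covariance of the GLS estimator
#'
#' The working covariance used for the FGLS weighting keeps only the
#' per-time-point blocks, so `(G' W G)^-1` understates the estimator variance:
#' the spline coefficients tie residuals at different time points together.
#' The correct first-order variance of `beta = (G' W G)^-1 G' W d` is the
#' sandwich `A^-1 (G' W V_full W G) A^-1` with `A = G' W G` and `V_full` the
#' complete delta-method residual covariance.
#' @keywords internal
#' @noRd
sandwich_covariance <- function(sys, Vfull) {
  U <- whiten_design(sys)
  A <- crossprod(sys$Gmat, U)
  Ainv <- chol2inv(chol((A + t(A)) / 2))
  C <- Ainv %*% (crossprod(U, Vfull) %*% U) %*% Ainv
  (C + t(C)) / 2
}

#' Stage I estimate of one fully observed cell by FGLS gradient matching
#'
#' Alternates the GLS solve with the delta-method update of the residual
#' covariance until the relative change in the parameter estimate drops below
#' `tol`. The first iterate (identity covariance) is the ordinary
#' least-squares solution. The parameter covariance is the sandwich
#' `A^-1 (G' W V_full W G) A^-1` at convergence, which accounts for the
#' cross-time residual correlation that the block working covariance drops.
#'
#' @param model a linear-in-parameters [ode_model].
#' @param fits per-state spline fits (see [assemble_system]).
#' @param tol relative l2 convergence tolerance on beta.
#' @param max_iter maximum FGLS iterations.
#' @param cell_id identifier carried into the result.
#' @return An object of class `individual_estimate` with `beta_hat`, `C`,
#'   `n_iter`, `converged`, and the per-iteration `history`.
#' @export
fgls_fit <- function(model, fits, tol = 1e-3, max_iter = 20,
                     cell_id = NA) {
  sys <- assemble_system(model, fits)
  sol <- gls_solve(sys)                       # V = I: OLS initialization
  history <- list(sol$beta)
  converged <- FALSE
  n_iter <- 1L
  for (it in seq_len(max_iter - 1)) {
    sys$V <- delta_V_blocks(model, sys, sol$beta)
    new <- gls_solve(sys)
    n_iter <- n_iter + 1L
    rel <- sqrt(sum((new$beta - sol$beta)^2)) /
      max(sqrt(sum(sol$beta^2)), 1e-12)
    sol <- new
    history[[n_iter]] <- sol$beta
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  Vfull <- residual_covariance(model, sys, sol$beta, structure = "full")
  individual_estimate(beta_hat = sol$beta,
                      C = sandwich_covariance(sys, Vfull),
                      n_iter = n_iter, converged = converged,
                      history = history, cell_id = cell_id)
}

#' Container for one cell's Stage I estimate
#' @param beta_hat estimated parameter vector.
#' @param C its covariance matrix.
#' @param n_iter iterations used.
#' @param converged logical convergence flag.
#' @param history list of per-iteration estimates.
#' @param cell_id identifier.
#' @param n_integrations number of ODE integrations spent (0 for gradient
#'   matching with full observation).
#' @return object of class `individual_estimate`.
#' @export
individual_estimate <- function(beta_hat, C, n_iter, converged,
                                history = NULL, cell_id = NA,
                                n_integrations = 0L) {
  structure(list(beta_hat = as.numeric(beta_hat), C = (C + t(C)) / 2,
                 n_iter = n_iter, converged = converged, history = history,
                 cell_id = cell_id, n_integrations = n_integrations),
            class = "individual_estimate")
}
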