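# Stage I for partially observed systems. Unobserved states are treated as
# latent variables: gradient matching is alternated with reconstruction of the
# hidden states by numerical integration at the current parameter estimate,
# and with uncertainty propagation through the forward sensitivities. The
# alternation is a fixed-point iteration; a handful of integrations per cell
# replaces the hundreds required by trajectory matching.

#' Structural initial guess for partially observed gradient matching
#'
#' Solves a restricted ordinary least-squares gradient-matching problem built
#' only from ODE rows of observed states whose `g` row and `h` component do
#' not involve any hidden state (detected numerically by perturbing the
#' hidden coordinates at random points). Parameters that do not appear in any
#' such row are initialized at 1 in model units.
#'
#' @param model a linear-in-parameters [ode_model].
#' @param fits_observed spline fits of the observed states (in the order of
#'   `obs_idx`).
#' @param obs_idx indices of the observed states.
#' @param n_probe number of random probe points for the structure detection.
#' @return initial parameter vector of length `model$P`.
#' @export
default_initial_guess <- function(model, fits_observed, obs_idx,
                                  n_probe = 5) {
  K <- model$K; P <- model$P
  hid_idx <- setdiff(seq_len(K), obs_idx)
  if (length(hid_idx) == 0) {
    sys <- assemble_system(model, fits_observed)
    return(gls_solve(sys)$beta)
  }
  # detect which rows depend on hidden coordinates
  depends_hidden <- rep(FALSE, K)
  probes <- with_seed(1L, matrix(stats::runif(n_probe * K, 0.5, 2), n_probe))
  for (p in seq_len(n_probe)) {
    x1 <- probes[p, ]
    x2 <- x1
    x2[hid_idx] <- x2[hid_idx] * 1.7 + 0.3
    g1 <- model$g(x1, 0); g2 <- model$g(x2, 0)
    h1 <- model$h(x1, 0); h2 <- model$h(x2, 0)
    changed <- rowSums(abs(g1 - g2)) + abs(h1 - h2) > 1e-12
    depends_hidden <- depends_hidden | changed
  }
  usable <- intersect(obs_idx, which(!depends_hidden))
  beta0 <- rep(1, P)
  if (length(usable) == 0) return(beta0)

  Tn <- length(fits_observed[[1]]$fitted)
  tgrid <- fits_observed[[1]]$basis$tgrid
  Xobs <- vapply(fits_observed, `[[`, numeric(Tn), "fitted")
  Xdot <- vapply(fits_observed, `[[`, numeric(Tn), "fitted_deriv")
  Gr <- matrix(0, Tn * length(usable), P)
  dr <- numeric(Tn * length(usable))
  for (j in seq_len(Tn)) {
    x <- rep(1, K)                       # hidden coords irrelevant here
    x[obs_idx] <- Xobs[j, ]
    gj <- model$g(x, tgrid[j]); hj <- model$h(x, tgrid[j])
    for (u in seq_along(usable)) {
      k <- usable[u]
      row <- (j - 1) * length(usable) + u
      Gr[row, ] <- gj[k, ]
      dr[row] <- Xdot[j, match(k, obs_idx)] - hj[k]
    }
  }
  ident <- which(colSums(abs(Gr)) > 1e-10)
  if (length(ident) > 0) {
    cf <- qr.coef(qr(Gr[, ident, drop = FALSE]), dr)
    cf[is.na(cf)] <- 1
    beta0[ident] <- cf
  }
  beta0
}

#' Integrate the system and its forward parameter sensitivities
#'
#' Solves the augmented system `xdot = f(x, beta)`,
#' `Sdot = (df/dx) S + df/dbeta` with `S(0) = 0`, giving the states, their
#' gradients, and the sensitivities `S(t_j) = dx(t_j)/dbeta` used for
#' uncertainty propagation to hidden states.
#'
#' @param model a linear-in-parameters [ode_model].
#' @param beta parameter vector.
#' @param tgrid time grid.
#' @param rtol,atol integration tolerances (looser than data generation;
#'   these integrations sit inside the inference loop).
#' @return An object of class `hidden_state_estimate` with `X` (T x K states),
#'   `Xdot` (T x K gradients), and `S` (T x K x P sensitivity array).
#' @export
integrate_hidden <- function(model, beta, tgrid, rtol = 1e-6, atol = 1e-8) {
  K <- model$K; P <- model$P
  derivs <- function(t, y, parms) {
    x <- y[seq_len(K)]
    S <- matrix(y[-seq_len(K)], K, P)
    G <- model$g(x, t)
    J <- rhs_jacobian_x(model, x, parms, t)
    list(c(G %*% parms + model$h(x, t), as.numeric(J %*% S + G)))
  }
  # the dominant eigenstructure of the augmented system is block-diagonal in
  # the state Jacobian; supplying it analytically spares the implicit solver
  # a (K(P+1))^2 finite-difference Jacobian
  jacf <- function(t, y, parms) {
    J <- rhs_jacobian_x(model, y[seq_len(K)], parms, t)
    A <- matrix(0, K * (P + 1), K * (P + 1))
    for (b in 0:P) A[b * K + seq_len(K), b * K + seq_len(K)] <- J
    A
  }
  y0 <- c(model$x0, rep(0, K * P))
  # capture.output: silence solver diagnostics for non-integrable parameter
  # proposals (rejected by the caller's step control)
  utils::capture.output(
    sol <- suppressWarnings(
      deSolve::vode(y = y0, times = as.numeric(tgrid), func = derivs,
                    parms = as.numeric(beta), rtol = rtol, atol = atol,
                    jacfunc = jacf, jactype = "fullusr")))
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(tgrid) ||
      !all(is.finite(sol[, -1]))) {
    stop("sensitivity integration failed for beta = (",
         paste(signif(beta, 6), collapse = ", "), ")")
  }
  Tn <- length(tgrid)
  X <- unname(sol[, 1 + seq_len(K), drop = FALSE])
  S <- array(unname(sol[, -seq_len(K + 1), drop = FALSE]), c(Tn, K, P))
  Xdot <- t(vapply(seq_len(Tn),
                   function(j) rhs(model, X[j, ], beta, tgrid[j]),
                   numeric(K)))
  structure(list(X = X, Xdot = Xdot, S = S, tgrid = as.numeric(tgrid),
                 beta = as.numeric(beta)),
            class = "hidden_state_estimate")
}

#' First-order covariance of reconstructed hidden states
#'
#' Propagates the parameter covariance `C` through the sensitivities:
#' `Cov(x_hid(t_j)) = S_hid(t_j) C S_hid(t_j)'` per time point.
#'
#' @param est a [integrate_hidden] result.
#' @param C `P x P` parameter covariance.
#' @param hid_idx indices of the hidden states (default: all states).
#' @return array `T x K_hid x K_hid`.
#' @export
propagate_hidden_uncertainty <- function(est, C, hid_idx = NULL) {
  hid_idx <- hid_idx %||% seq_len(dim(est$S)[2])
  Tn <- dim(est$S)[1]
  out <- array(0, c(Tn, length(hid_idx), length(hid_idx)))
  for (j in seq_len(Tn)) {
    Sj <- matrix(est$S[j, hid_idx, ], length(hid_idx), dim(est$S)[3])
    out[j, , ] <- Sj %*% C %*% t(Sj)
  }
  out
}

#' Assemble the partially observed gradient-matching system
#'
#' Rows come from the observed states only; the ODE rows of the hidden states
#' are identically satisfied by the reconstruction and carry no information.
#' The reconstructed hidden states are deterministic functions of the
#' parameters, so their dependence is linearized into the design through the
#' forward sensitivities: for an observed state k,
#' `xdot_k(beta) ~ [g beta + h]_k (x(beta_cur)) + J_hid S_hid (beta -
#' beta_cur)`, giving the effective design `A = g_obs + J_obs,hid S_hid` and
#' the shifted response `xdot_hat_obs - h_obs - g_obs beta_cur -
#' J_obs,hid S_hid beta_cur + A beta_cur` (the last two terms cancel for the
#' `g_obs` part only). The residual covariance carries the smoothing
#' uncertainty of the observed states, per time block, as in the fully
#' observed case.
#' @keywords internal
#' @noRd
assemble_partial <- function(model, fits_observed, obs_idx, est, beta_cur,
                             ridge_scale = 1e-8) {
  K <- model$K; P <- model$P
  K_obs <- length(obs_idx)
  Tn <- length(fits_observed[[1]]$fitted)
  tgrid <- fits_observed[[1]]$basis$tgrid
  hid_idx <- setdiff(seq_len(K), obs_idx)
  Xhat <- est$X
  Xhat[, obs_idx] <- vapply(fits_observed, `[[`, numeric(Tn), "fitted")
  Xdot_obs <- vapply(fits_observed, `[[`, numeric(Tn), "fitted_deriv")

  Gmat <- matrix(0, Tn * K_obs, P)
  dvec <- numeric(Tn * K_obs)
  blocks <- vector("list", Tn)
  tr_total <- 0
  for (j in seq_len(Tn)) {
    xj <- Xhat[j, ]
    gj <- model$g(xj, tgrid[j])
    hj <- model$h(xj, tgrid[j])
    J <- rhs_jacobian_x(model, xj, beta_cur, tgrid[j])
    Shid <- matrix(est$S[j, hid_idx, ], length(hid_idx), P)
    JS <- matrix(J[obs_idx, hid_idx], K_obs) %*% Shid    # K_obs x P
    A <- gj[obs_idx, , drop = FALSE] + JS
    rows <- (j - 1) * K_obs + seq_len(K_obs)
    Gmat[rows, ] <- A
    dvec[rows] <- Xdot_obs[j, ] - hj[obs_idx] + JS %*% beta_cur
    # smoothing-uncertainty block of the observed rows
    Vj <- matrix(0, K_obs, K_obs)
    for (u in seq_len(K_obs)) {
      kp <- obs_idx[u]
      fit <- fits_observed[[u]]
      Sc <- fit$coef_cov
      if (is.null(Sc)) next
      bj <- fit$basis$B[j, ]
      bdj <- fit$basis$Bdot[j, ]
      q1 <- Sc %*% bj
      a <- sum(bj * q1)
      bq <- sum(bdj * q1)
      c2 <- sum(bdj * (Sc %*% bdj))
      Jc <- J[obs_idx, kp]
      Vj <- Vj + outer(Jc, Jc) * a
      Vj[, u] <- Vj[, u] - Jc * bq
      Vj[u, ] <- Vj[u, ] - Jc * bq
      Vj[u, u] <- Vj[u, u] + c2
    }
    blocks[[j]] <- (Vj + t(Vj)) / 2
    tr_total <- tr_total + sum(diag(Vj))
  }
  ridge <- ridge_scale * max(tr_total, 1e-300) / (Tn * K_obs)
  blocks <- lapply(blocks, function(Vj) Vj + diag(ridge, K_obs))
  structure(list(Gmat = Gmat, dvec = dvec, V = blocks, Xhat = Xhat,
                 tgrid = tgrid, T = Tn, K = K_obs, P = P),
            class = "gls_system")
}

#' Full delta-method residual covariance of the observed rows
#'
#' Cross-time analog of the per-time blocks built in [assemble_partial]: the
#' residual error of observed row (j, v) is, to first order,
#' `Bdot_v[j, ] delta_c_v - sum_u J[v, u](t_j) B_u[j, ] delta_c_u` over the
#' observed states u, so the complete covariance is `sum_u M_u Sigma_c_u M_u'`.
#' Used only for the final sandwich parameter covariance.
#' @keywords internal
#' @noRd
partial_full_V <- function(model, fits_observed, obs_idx, Xhat, tgrid, beta,
                           ridge_scale = 1e-8) {
  K_obs <- length(obs_idx)
  Tn <- length(tgrid)
  TK <- Tn * K_obs
  Jarr <- array(0, c(K_obs, K_obs, Tn))
  for (j in seq_len(Tn)) {
    J <- rhs_jacobian_x(model, Xhat[j, ], beta, tgrid[j])
    Jarr[, , j] <- J[obs_idx, obs_idx]
  }
  V <- matrix(0, TK, TK)
  for (u in seq_len(K_obs)) {
    Sc <- fits_observed[[u]]$coef_cov
    if (is.null(Sc)) next
    B <- fits_observed[[u]]$basis$B
    Bd <- fits_observed[[u]]$basis$Bdot
    M <- matrix(0, TK, ncol(B))
    for (v in seq_len(K_obs)) {
      rows <- (seq_len(Tn) - 1) * K_obs + v
      M[rows, ] <- -Jarr[v, u, ] * B
      if (v == u) M[rows, ] <- M[rows, ] + Bd
    }
    V <- V + M %*% Sc %*% t(M)
  }
  V <- (V + t(V)) / 2
  V + diag(ridge_scale * max(sum(diag(V)), 1e-300) / TK, TK)
}

#' Stage I estimate of one partially observed cell
#'
#' Fixed-point iteration: (i) reconstruct the hidden states and their
#' parameter sensitivities by integrating at the current estimate, (ii)
#' gradient matching by GLS on the observed-state rows, with the hidden-state
#' dependence on the parameters linearized into the design through the
#' sensitivities, (iii) update the residual covariance from the smoothing
#' covariance of the observed states. At the solution the reconstructed
#' hidden states are self-consistent with the estimated parameters; the
#' sensitivity term is what makes parameters that enter the data only through
#' the hidden states identifiable.
#'
#' @param model a linear-in-parameters [ode_model] with known initial
#'   conditions for the hidden states.
#' @param fits_observed spline fits of the observed states.
#' @param obs_idx indices of the observed states.
#' @param beta0 initial guess (default [default_initial_guess]).
#' @param tol relative l2 convergence tolerance on beta.
#' @param max_iter maximum fixed-point iterations.
#' @param rtol integration tolerance inside the loop.
#' @param cell_id identifier carried into the result.
#' @return An `individual_estimate`; `n_integrations` counts the sensitivity
#'   integrations performed.
#' @export
stage1_partial <- function(model, fits_observed, obs_idx, beta0 = NULL,
                           tol = 1e-2, max_iter = 10, rtol = 1e-6,
                           cell_id = NA) {
  if (length(obs_idx) == model$K) {
    return(fgls_fit(model, fits_observed[order(obs_idx)], cell_id = cell_id))
  }
  tgrid <- fits_observed[[1]]$basis$tgrid
  beta_cur <- beta0 %||% default_initial_guess(model, fits_observed, obs_idx)
  C_cur <- diag(pmax(beta_cur^2, 1e-12), model$P)
  history <- list(beta_cur)
  converged <- FALSE
  n_int <- 0L
  n_iter <- 0L
  try_integrate <- function(beta) {
    tryCatch(integrate_hidden(model, beta, tgrid, rtol = rtol),
             error = function(e) NULL)
  }
  est <- try_integrate(beta_cur)
  n_int <- n_int + 1L
  if (is.null(est)) {
    stop("integration failed at the initial guess beta0 = (",
         paste(signif(beta_cur, 6), collapse = ", "), ")")
  }
  for (it in seq_len(max_iter)) {
    sys <- assemble_partial(model, fits_observed, obs_idx, est, beta_cur)
    positive <- all(beta_cur > 0)
    if (positive) {
      # multiplicative (log-scale) update: rate constants stay positive and
      # early far-from-solution steps cannot overshoot into the degenerate
      # zero-trajectory regime; capped at one decade per iteration
      sys_log <- sys
      sys_log$Gmat <- sys$Gmat %*% diag(beta_cur, length(beta_cur))
      sys_log$dvec <- sys$dvec - as.numeric(sys$Gmat %*% beta_cur)
      sol <- gls_solve(sys_log)
      dtheta <- pmin(pmax(sol$beta, -log(10)), log(10))
      step_fun <- function(s) beta_cur * exp(s * dtheta)
      C_new <- diag(beta_cur) %*% sol$C %*% diag(beta_cur)
    } else {
      sol <- gls_solve(sys)
      step_fun <- function(s) beta_cur + s * (sol$beta - beta_cur)
      C_new <- sol$C
    }
    n_iter <- it
    # halve the step while the proposed parameters make the system
    # non-integrable
    s <- 1
    est_new <- NULL
    beta_new <- beta_cur
    for (h in 1:7) {
      beta_try <- step_fun(s)
      est_new <- try_integrate(beta_try)
      n_int <- n_int + 1L
      if (!is.null(est_new)) {
        beta_new <- beta_try
        break
      }
      s <- s / 2
    }
    if (is.null(est_new)) break  # stuck: report last integrable iterate
    rel <- sqrt(sum((beta_new - beta_cur)^2)) /
      max(sqrt(sum(beta_cur^2)), 1e-12)
    beta_cur <- beta_new
    C_cur <- C_new
    est <- est_new
    history[[it + 1]] <- beta_cur
    if (rel < tol && s == 1) {
      converged <- TRUE
      break
    }
  }
  # final parameter covariance: sandwich against the full (cross-time)
  # smoothing covariance of the observed rows, evaluated at the final estimate
  sys <- assemble_partial(model, fits_observed, obs_idx, est, beta_cur)
  Vfull <- partial_full_V(model, fits_observed, obs_idx, sys$Xhat,
                          sys$tgrid, beta_cur)
  C_cur <- tryCatch(sandwich_covariance(sys, Vfull), error = function(e) C_cur)
  individual_estimate(beta_hat = beta_cur, C = C_cur, n_iter = n_iter,
                      converged = converged, history = history,
                      cell_id = cell_id, n_integrations = n_int)
}
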