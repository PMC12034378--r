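# Stage II: population parameters (b, D) from individual estimates and their
# covariances by Expectation-Maximization under the measurement-error model
#   beta_hat_i | beta_i ~ N(beta_i, C_i),   beta_i ~ N(b, D).
# EM deconvolves the first-stage uncertainty: unlike the naive sample
# covariance of the beta_hat_i, the EM estimate of D is not inflated by C_i.

#' EM fit of the population mean and random-effects covariance
#'
#' E-step: posterior moments `mu_i = b + D (D + C_i)^-1 (beta_hat_i - b)`,
#' `Sigma_i = D - D (D + C_i)^-1 D`. M-step: `b = mean(mu_i)`,
#' `D = mean(Sigma_i + (mu_i - b)(mu_i - b)')`. Iterates until the relative
#' change in `(b, D)` falls below `tol`. After each M-step `D` is symmetrized
#' and its eigenvalues floored at `1e-10 trace(D)/P` for numerical safety.
#'
#' @param estimates list of `individual_estimate` objects (N >= 2).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @param family distribution label stored in the result (the EM itself is
#'   always Gaussian; see [lognormal_fit] for the log-normal route).
#' @param init optional list with starting values `b` and `D`; defaults to
#'   the componentwise median and the naive covariance of the estimates.
#' @return An object of class `population_estimate` with `b_hat`, `D_hat`,
#'   `loglik_trace` (marginal log-likelihood per iteration), `n_iter`,
#'   `converged`.
#' @export
em_fit <- function(estimates, tol = 1e-6, max_iter = 1000,
                   family = "normal", init = NULL) {
  N <- length(estimates)
  if (N < 2) stop("need at least two individual estimates")
  B <- do.call(rbind, lapply(estimates, `[[`, "beta_hat"))
  P <- ncol(B)
  Cs <- lapply(estimates, `[[`, "C")
  for (i in seq_len(N)) {
    ev <- eigen((Cs[[i]] + t(Cs[[i]])) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev < -1e-8 * max(abs(ev), 1e-300))) {
      stop("individual covariance of cell ",
           estimates[[i]]$cell_id %||% i, " is not positive semi-definite")
    }
  }
  if (!is.null(init)) {
    b <- as.numeric(init$b)
    D <- as.matrix(init$D)
  } else {
    b <- apply(B, 2, stats::median)
    Dn <- stats::cov(B) * (N - 1) / N
    D <- psd_floor(Dn, 1e-10 * max(sum(diag(Dn)), 1e-300) / P)
  }
  loglik_trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    mu <- matrix(0, N, P)
    Ssum <- matrix(0, P, P)
    for (i in seq_len(N)) {
      # Cholesky-based inverse: tolerates the extreme conditioning produced
      # by near-uninformative cells (very large C_i) without an rcond error
      M <- D + Cs[[i]]
      W <- D %*% chol2inv(chol((M + t(M)) / 2))
      mu[i, ] <- b + W %*% (B[i, ] - b)
      Ssum <- Ssum + (D - W %*% D)
    }
    b_new <- colMeans(mu)
    dev <- sweep(mu, 2, b_new)
    D_new <- (Ssum + t(dev) %*% dev) / N
    D_new <- psd_floor(D_new, 1e-10 * max(sum(diag(D_new)), 1e-300) / P)
    loglik_trace <- c(loglik_trace, marginal_loglik(estimates, b_new, D_new))
    rel <- (sqrt(sum((b_new - b)^2)) + sqrt(sum((D_new - D)^2))) /
      max(sqrt(sum(b^2)) + sqrt(sum(D^2)), 1e-12)
    b <- b_new; D <- D_new
    n_iter <- it
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(family = family, b_hat = b, D_hat = D,
                 loglik_trace = loglik_trace, n_iter = n_iter,
                 converged = converged),
            class = "population_estimate")
}

#' Marginal log-likelihood of the individual estimates
#'
#' Under the two-level model, marginally
#' `beta_hat_i ~ N(b, D + C_i)`; this returns the summed log-density, the
#' quantity EM ascends.
#'
#' @param estimates list of `individual_estimate`.
#' @param b,D candidate population parameters.
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(estimates, b, D) {
  P <- length(b)
  ll <- 0
  for (e in estimates) {
    M <- D + e$C
    R <- tryCatch(chol((M + t(M)) / 2),
                  error = function(err) stop("singular D + C_i"))
    z <- forwardsolve(t(R), e$beta_hat - b)
    ll <- ll - 0.5 * (P * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
  }
  ll
}

#' Approximate EM fit for log-normally distributed parameters
#'
#' Delta-method transform of the individual estimates to the log scale
#' (`m_i = log beta_hat_i`,
#' `C_i^log = diag(1/beta_hat_i) C_i diag(1/beta_hat_i)`), followed by the
#' Gaussian EM of [em_fit]. The returned `b_hat`/`D_hat` are the log-mean and
#' log-covariance.
#'
#' @param estimates list of `individual_estimate`; all components must be
#'   positive (values in (0, `clip`] are clipped to `clip` with a warning).
#' @param clip lower clipping bound for nonpositive components.
#' @param ... passed to [em_fit].
#' @return a `population_estimate` with `family = "lognormal"`.
#' @export
lognormal_fit <- function(estimates, clip = 1e-12, ...) {
  bad <- character(0)
  transformed <- lapply(estimates, function(e) {
    bh <- e$beta_hat
    if (any(bh <= 0)) {
      bad <<- c(bad, as.character(e$cell_id))
      bh <- pmax(bh, clip)
    }
    Dinv <- diag(1 / bh, length(bh))
    individual_estimate(beta_hat = log(bh),
                        C = Dinv %*% e$C %*% Dinv,
                        n_iter = e$n_iter, converged = e$converged,
                        cell_id = e$cell_id)
  })
  if (length(bad) > 0) {
    warning("nonpositive parameter estimates clipped at ", clip,
            " for cells: ", paste(bad, collapse = ", "))
  }
  em_fit(transformed, family = "lognormal", ...)
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("<population_estimate> family =", x$family, "\n")
  cat("  b_hat:", paste(signif(x$b_hat, 4), collapse = ", "), "\n")
  cat("  sqrt(diag(D_hat)):",
      paste(signif(sqrt(diag(x$D_hat)), 4), collapse = ", "), "\n")
  cat("  EM iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}
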