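# Accuracy metrics: closed-form 2-Wasserstein distance between Gaussians and
# recovery reports comparing estimated and generating population
# distributions.

#' 2-Wasserstein distance between two multivariate Gaussians
#'
#' Closed form:
#' `W2^2 = ||b1 - b2||^2 + tr(D1 + D2 - 2 (D2^(1/2) D1 D2^(1/2))^(1/2))`.
#' Symmetric in its arguments and a metric on Gaussian distributions.
#'
#' @param b1,b2 mean vectors.
#' @param D1,D2 positive semi-definite covariance matrices.
#' @return nonnegative scalar.
#' @export
w2_gaussian <- function(b1, D1, b2, D2) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  for (M in list(D1, D2)) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8 * max(abs(ev), 1e-300))) {
      stop("covariance inputs must be positive semi-definite")
    }
  }
  s2 <- sqrtm_psd(D2)
  cross <- sqrtm_psd(s2 %*% D1 %*% s2)
  w2sq <- sum((b1 - b2)^2) + sum(diag(D1)) + sum(diag(D2)) -
    2 * sum(diag(cross))
  sqrt(max(w2sq, 0))
}

#' Normalized Wasserstein mismatch of a population estimate
#'
#' `w2_gaussian` between the estimated and generating distributions, divided
#' by the Euclidean norm of the generating mean, so that the value is
#' invariant to a consistent rescaling of all parameters. Log-normal
#' estimates are compared on the log scale (where both are Gaussian).
#'
#' @param est a `population_estimate`.
#' @param truth a [population_distribution] of the same family.
#' @return nonnegative scalar.
#' @export
w2_normalized <- function(est, truth) {
  if (!identical(est$family, truth$family)) {
    stop("family mismatch: estimate is '", est$family, "', truth is '",
         truth$family, "'")
  }
  w2_gaussian(est$b_hat, est$D_hat, truth$b, truth$D) /
    sqrt(sum(truth$b^2))
}

#' Recovery report comparing an estimate against the generating distribution
#'
#' @param est a `population_estimate`.
#' @param truth the generating [population_distribution].
#' @param runtime_seconds optional wall-clock time of the producing run.
#' @return An object of class `recovery_report` with the normalized
#'   Wasserstein distance, per-parameter relative errors of the means and of
#'   the random-effect SDs, correlation errors, and the runtime.
#' @export
recovery_report <- function(est, truth, runtime_seconds = NA_real_) {
  sd_hat <- sqrt(diag(est$D_hat))
  sd_true <- sqrt(diag(truth$D))
  corr_err <- stats::cov2cor(est$D_hat + diag(1e-300, nrow(est$D_hat))) -
    stats::cov2cor(truth$D + diag(1e-300, nrow(truth$D)))
  structure(list(
    w2_normalized = w2_normalized(est, truth),
    mean_rel_error = (est$b_hat - truth$b) / truth$b,
    sd_rel_error = (sd_hat - sd_true) / ifelse(sd_true > 0, sd_true, 1),
    correlation_error = corr_err,
    runtime_seconds = runtime_seconds
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat("  normalized W2:        ", signif(x$w2_normalized, 4), "\n")
  cat("  mean rel. errors:     ",
      paste(signif(x$mean_rel_error, 3), collapse = ", "), "\n")
  cat("  SD rel. errors:       ",
      paste(signif(x$sd_rel_error, 3), collapse = ", "), "\n")
  if (!is.na(x$runtime_seconds)) {
    cat("  runtime (s):          ", signif(x$runtime_seconds, 4), "\n")
  }
  invisible(x)
}
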