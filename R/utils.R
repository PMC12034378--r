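# Internal numerical helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations do not disturb
#' the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

#' Draw N rows from a multivariate normal N(b, D)
#'
#' Uses the symmetric eigendecomposition of D so that positive semi-definite
#' (including singular) covariances are handled.
#' @keywords internal
#' @noRd
rmvnorm_psd <- function(n, b, D) {
  p <- length(b)
  D <- as.matrix(D)
  ed <- eigen((D + t(D)) / 2, symmetric = TRUE)
  ev <- ed$values
  tol <- -1e-8 * max(abs(ev), 1e-300)
  if (any(ev < tol)) {
    stop("covariance matrix 'D' is not positive semi-definite")
  }
  ev[ev < 0] <- 0
  A <- ed$vectors %*% (sqrt(ev) * t(ed$vectors))
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% A, 2, b, `+`)
}

#' Symmetric positive semi-definite matrix square root
#' @keywords internal
#' @noRd
sqrtm_psd <- function(M) {
  M <- as.matrix(M)
  ed <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(ed$values, 0)
  ed$vectors %*% (sqrt(ev) * t(ed$vectors))
}

#' Force symmetry and floor eigenvalues of a covariance matrix
#' @keywords internal
#' @noRd
psd_floor <- function(M, floor = 0) {
  M <- (M + t(M)) / 2
  ed <- eigen(M, symmetric = TRUE)
  ev <- pmax(ed$values, floor)
  M <- ed$vectors %*% (ev * t(ed$vectors))
  (M + t(M)) / 2
}

#' Central finite-difference Jacobian of f: R^n -> R^m
#' @keywords internal
#' @noRd
fd_jacobian <- function(f, x, eps = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  f0 <- as.numeric(f(x))
  J <- matrix(0, length(f0), n)
  if (is.null(eps)) eps <- pmax(abs(x), 1) * (.Machine$double.eps)^(1 / 3)
  for (j in seq_len(n)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + eps[j]
    xm[j] <- x[j] - eps[j]
    J[, j] <- (as.numeric(f(xp)) - as.numeric(f(xm))) / (2 * eps[j])
  }
  J
}

#' Solve a symmetric positive definite system via Cholesky
#' @keywords internal
#' @noRd
chol_solve <- function(A, b) {
  R <- chol((A + t(A)) / 2)
  backsolve(R, forwardsolve(t(R), b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
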