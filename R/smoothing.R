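# Penalized cubic B-spline smoothing of single-cell time series: state and
# gradient estimates, coefficient covariances, and measurement-noise
# parameter estimates. Smoothing precedes gradient matching, so the quality of
# these estimates drives the accuracy of the whole first stage.

#' Build a clamped cubic B-spline basis on a time grid
#'
#' @param knots nondecreasing knot vector including both endpoints (interior
#'   knots strictly inside `range(tgrid)`); endpoints are clamped (full
#'   multiplicity).
#' @param tgrid evaluation grid (the data time points).
#' @return An object of class `spline_basis` with fields `knots`, `degree`,
#'   `B` (T x n_basis evaluation matrix), `Bdot` (derivative matrix), and
#'   `penalty` (n_basis x n_basis integrated squared second derivative).
#' @export
build_basis <- function(knots, tgrid) {
  tgrid <- as.numeric(tgrid)
  knots <- sort(unique(as.numeric(knots)))
  if (min(knots) > min(tgrid) || max(knots) < max(tgrid)) {
    stop("'knots' must span the time grid")
  }
  n_int <- length(knots) - 2
  n_basis <- n_int + 4
  if (n_basis > length(tgrid)) {
    stop("too many knots for the grid: ", n_basis, " basis functions but ",
         "only ", length(tgrid), " time points")
  }
  aug <- c(rep(knots[1], 4), knots[-c(1, length(knots))],
           rep(knots[length(knots)], 4))
  B <- splines::splineDesign(aug, tgrid, ord = 4, outer.ok = FALSE)
  Bdot <- splines::splineDesign(aug, tgrid, ord = 4, derivs = 1)

  # Roughness penalty: integral of (second derivative)^2. Second derivatives
  # of cubic splines are piecewise linear, so 2-point Gauss-Legendre per
  # inter-knot interval integrates their products exactly.
  P <- matrix(0, n_basis, n_basis)
  gl <- c(-1, 1) / sqrt(3)
  for (l in seq_len(length(knots) - 1)) {
    a <- knots[l]; bnd <- knots[l + 1]
    half <- (bnd - a) / 2
    pts <- (a + bnd) / 2 + half * gl
    B2 <- splines::splineDesign(aug, pts, ord = 4, derivs = 2)
    P <- P + half * (t(B2) %*% B2)
  }
  structure(list(knots = knots, degree = 3L, tgrid = tgrid, aug_knots = aug,
                 B = B, Bdot = Bdot, penalty = (P + t(P)) / 2,
                 n_basis = n_basis),
            class = "spline_basis")
}

#' Evaluate a spline basis (and derivatives) at new time points
#' @param basis a [build_basis] object.
#' @param t evaluation times within the knot span.
#' @param deriv derivative order (0, 1, or 2).
#' @return matrix `length(t) x n_basis`.
#' @export
eval_basis <- function(basis, t, deriv = 0) {
  splines::splineDesign(basis$aug_knots, as.numeric(t), ord = 4,
                        derivs = deriv)
}

#' Penalized weighted least-squares spline fit for one state
#'
#' Minimizes `||W^(1/2) (y - B c)||^2 + lambda * c' P c`, solving the normal
#' equations `(B'WB + lambda P) c = B'W y`.
#'
#' @param y observations (length T).
#' @param basis a [build_basis] object evaluated on the data grid.
#' @param weights positive observation weights (length T or 1).
#' @param lambda nonnegative roughness penalty weight.
#' @param noise_var optional length-T vector of observation variances
#'   `sigma^2 + tau^2 xhat^2`; when supplied, the sandwich covariance of the
#'   spline coefficients is computed.
#' @return An object of class `spline_fit` with `coef`, `fitted`,
#'   `fitted_deriv`, `edf` (effective degrees of freedom), `lambda`, and
#'   `coef_cov` (NULL unless `noise_var` is given).
#' @export
fit_penalized <- function(y, basis, weights = 1, lambda = 0,
                          noise_var = NULL) {
  y <- as.numeric(y)
  Tn <- length(y)
  w <- rep_len(as.numeric(weights), Tn)
  if (any(w <= 0)) stop("'weights' must be positive")
  B <- basis$B
  BtW <- t(B * w)
  A <- BtW %*% B + lambda * basis$penalty
  R <- tryCatch(chol(A), error = function(e) {
    stop("singular penalized normal matrix; use fewer knots or a larger ",
         "'lambda'")
  })
  cf <- backsolve(R, forwardsolve(t(R), BtW %*% y))
  fitted <- as.numeric(B %*% cf)
  Ainv_Bt <- backsolve(R, forwardsolve(t(R), t(B)))   # A^{-1} B'
  edf <- sum((t(Ainv_Bt) * w) * B)                    # tr(B A^{-1} B' W)
  coef_cov <- NULL
  if (!is.null(noise_var)) {
    nv <- rep_len(as.numeric(noise_var), Tn)
    AinvBtW <- Ainv_Bt * rep(w, each = nrow(Ainv_Bt)) # A^{-1} B' W
    coef_cov <- AinvBtW %*% (t(AinvBtW) * nv)
    coef_cov <- (coef_cov + t(coef_cov)) / 2
  }
  structure(list(coef = as.numeric(cf), basis = basis, lambda = lambda,
                 weights = w, fitted = fitted,
                 fitted_deriv = as.numeric(basis$Bdot %*% cf),
                 edf = edf, coef_cov = coef_cov, y = y),
            class = "spline_fit")
}

#' Select the roughness penalty by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = T * RSS_w / (T - edf)^2` over a log-spaced grid;
#' fully deterministic.
#'
#' @param y,basis,weights as in [fit_penalized].
#' @param grid candidate penalty values (default `10^seq(-6, 3)` with 40
#'   points).
#' @return the selected `lambda` (scalar).
#' @export
select_lambda <- function(y, basis, weights = 1,
                          grid = 10^seq(-6, 3, length.out = 40)) {
  y <- as.numeric(y)
  Tn <- length(y)
  w <- rep_len(as.numeric(weights), Tn)
  B <- basis$B
  BtWB <- crossprod(B, B * w)
  BtWy <- crossprod(B, w * y)
  scores <- vapply(grid, function(lam) {
    A <- BtWB + lam * basis$penalty
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    Ainv <- chol2inv(R)
    cf <- Ainv %*% BtWy
    edf <- sum(Ainv * BtWB)
    rss <- sum(w * (y - as.numeric(B %*% cf))^2)
    denom <- max(Tn - edf, 1e-8)
    Tn * rss / denom^2
  }, numeric(1))
  grid[which.min(scores)]
}

#' Estimate measurement-noise parameters from smoothing residuals
#'
#' Method-of-moments: squared residuals, inflated by `T / (T - edf)` to
#' compensate the degrees of freedom absorbed by the smoother, are regressed
#' on `(1, xhat^2)` with nonnegativity constraints, giving
#' `sigma_hat = sqrt(intercept)` and `tau_hat = sqrt(slope)`.
#'
#' @param y observations for one state.
#' @param fit the corresponding [fit_penalized] result.
#' @return An object of class `noise_estimate` with `sigma_hat`, `tau_hat`.
#' @export
estimate_noise <- function(y, fit) {
  y <- as.numeric(y)
  Tn <- length(y)
  if (Tn < 5) stop("need at least 5 time points to estimate noise")
  r2 <- (y - fit$fitted)^2 * Tn / max(Tn - fit$edf, 1)
  x2 <- fit$fitted^2
  X <- cbind(1, x2)
  cf <- tryCatch(as.numeric(qr.solve(X, r2)), error = function(e) c(0, 0))
  if (any(cf < 0)) {
    # fall back to the best single-component fit
    s_only <- c(mean(r2), 0)
    t_only <- c(0, if (sum(x2^2) > 0) max(sum(r2 * x2) / sum(x2^2), 0) else 0)
    sse <- function(cc) sum((r2 - X %*% cc)^2)
    cf <- if (sse(s_only) <= sse(t_only)) s_only else t_only
  }
  structure(list(sigma_hat = sqrt(max(cf[1], 0)),
                 tau_hat = sqrt(max(cf[2], 0))),
            class = "noise_estimate")
}

#' Place interior knots at salient features of a time series
#'
#' Deterministic heuristic: pre-smooth with a centered moving average (window
#' `ceiling(T/10)`), locate local extrema and inflection candidates of the
#' pre-smoothed curve, place interior knots at those times, merge knots closer
#' than two median time steps, and cap at `floor(T/2)` interior knots.
#' Endpoints are always included.
#'
#' @param y observations.
#' @param t observation times.
#' @return knot vector (endpoints plus interior knots).
#' @export
auto_knots <- function(y, t) {
  y <- as.numeric(y); t <- as.numeric(t)
  Tn <- length(y)
  if (Tn < 5) stop("need at least 5 time points")
  w <- ceiling(Tn / 10)
  if (w > 1) {
    ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    na <- which(is.na(ys))
    ys[na] <- y[na]  # window does not fit near the endpoints
  } else {
    ys <- y
  }
  d1 <- diff(ys)
  d2 <- diff(d1)
  extrema <- which(d1[-length(d1)] * d1[-1] < 0) + 1
  inflect <- which(d2[-length(d2)] * d2[-1] < 0) + 1
  cand <- sort(unique(t[c(extrema, inflect)]))
  cand <- cand[cand > t[1] & cand < t[Tn]]
  # merge candidates closer than 2 median steps
  min_gap <- 2 * stats::median(diff(t))
  keep <- numeric(0)
  for (ck in cand) {
    if (length(keep) == 0 || ck - keep[length(keep)] >= min_gap) {
      keep <- c(keep, ck)
    }
  }
  keep <- keep[keep - t[1] >= min_gap & t[Tn] - keep >= min_gap]
  cap <- floor(Tn / 2)
  if (length(keep) > cap) keep <- keep[round(seq(1, length(keep),
                                                 length.out = cap))]
  if (length(keep) == 0) {
    # featureless (monotone-like) series: a few equispaced interior knots
    keep <- stats::quantile(t, c(0.25, 0.5, 0.75), names = FALSE)
  }
  c(t[1], keep, t[Tn])
}

#' Smooth all observed states of one cell
#'
#' Iterates penalized fitting, noise estimation, and reweighting (weights
#' `1 / (sigma_hat^2 + tau_hat^2 xhat^2)`) until the noise parameters change
#' by less than 1% or 5 rounds are reached. The roughness penalty per state is
#' selected by GCV unless given.
#'
#' @param cell a [cell_measurements].
#' @param knots either a single knot vector shared by all states, a list of
#'   per-state knot vectors, or NULL to use [auto_knots] per state.
#' @param lambda optional penalty (scalar or per-state vector); NULL for GCV.
#' @param max_rounds maximum reweighting rounds.
#' @return list with `fits` (list of [fit_penalized] per observed state, with
#'   `coef_cov` filled in) and `noise` (list of [estimate_noise] per state).
#' @export
smooth_cell <- function(cell, knots = NULL, lambda = NULL, max_rounds = 5) {
  stopifnot(inherits(cell, "cell_measurements"))
  K_obs <- ncol(cell$y)
  fits <- vector("list", K_obs)
  noise <- vector("list", K_obs)
  for (k in seq_len(K_obs)) {
    yk <- cell$y[, k]
    kn <- if (is.null(knots)) auto_knots(yk, cell$t)
          else if (is.list(knots)) knots[[k]] else knots
    basis <- build_basis(kn, cell$t)
    lam <- if (is.null(lambda)) NULL
           else if (length(lambda) > 1) lambda[k] else lambda
    w <- rep(1, length(yk))
    sig <- tau <- Inf
    fit <- NULL
    lam_k <- lam
    for (round in seq_len(max_rounds)) {
      # the GCV grid search is only repeated while the weights still move
      # substantially (first two rounds); afterwards the penalty is kept
      if (is.null(lam) && round <= 2) lam_k <- select_lambda(yk, basis, w)
      fit <- fit_penalized(yk, basis, w, lam_k)
      ns <- estimate_noise(yk, fit)
      nv <- pmax(ns$sigma_hat^2 + ns$tau_hat^2 * fit$fitted^2,
                 1e-12 * max(mean(yk^2), 1e-12))
      w <- 1 / nv
      rel <- max(abs(ns$sigma_hat - sig), abs(ns$tau_hat - tau)) /
        max(ns$sigma_hat + ns$tau_hat, 1e-12)
      sig <- ns$sigma_hat; tau <- ns$tau_hat
      noise[[k]] <- ns
      if (rel < 0.01) break
    }
    nv <- pmax(sig^2 + tau^2 * fit$fitted^2,
               1e-12 * max(mean(yk^2), 1e-12))
    fits[[k]] <- fit_penalized(yk, basis, 1 / nv, fit$lambda, noise_var = nv)
  }
  list(fits = fits, noise = noise)
}

#' Smooth every cell in a dataset with knots shared across cells
#'
#' Knot locations are chosen once per observed state from the cell-averaged
#' series (so all cells share the same basis per state), then each cell is
#' smoothed with [smooth_cell]. If the selection matrix `Q` is a square
#' permutation, smoothing the observations is equivalent to smoothing the
#' states directly.
#'
#' @param dataset a [population_dataset].
#' @param knots,lambda optional overrides passed to [smooth_cell]; by default
#'   knots come from [auto_knots] on the cell-averaged trace per state.
#' @param shared_knots if FALSE, knots are chosen per cell instead.
#' @return list with one [smooth_cell] result per cell, plus the shared
#'   `knots` used (or NULL).
#' @export
smooth_dataset <- function(dataset, knots = NULL, lambda = NULL,
                           shared_knots = TRUE) {
  stopifnot(inherits(dataset, "population_dataset"))
  t <- dataset$cells[[1]]$t
  K_obs <- dataset$measurement$K_obs
  if (is.null(knots) && shared_knots) {
    ybar <- Reduce(`+`, lapply(dataset$cells, `[[`, "y")) /
      length(dataset$cells)
    knots <- lapply(seq_len(K_obs), function(k) auto_knots(ybar[, k], t))
  }
  res <- lapply(dataset$cells, smooth_cell, knots = knots, lambda = lambda)
  list(cells = res, knots = knots)
}
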