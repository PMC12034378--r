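# Top-level two-stage pipelines tying smoothing, Stage I, and Stage II
# together.

#' Gradient-matching two-stage fit of a population dataset
#'
#' Runs the full pipeline: (1) penalized B-spline smoothing of every cell
#' (knots shared across cells per state), (2) Stage I gradient matching —
#' FGLS when all states are observed, the hidden-state fixed-point iteration
#' otherwise (auto-detected from the selection matrix), (3) Stage II EM for
#' the population mean and random-effects covariance.
#'
#' @param dataset a [population_dataset].
#' @param family `"normal"` or `"lognormal"` population distribution.
#' @param knots,lambda optional smoothing overrides (see [smooth_dataset]).
#' @param stage1 list of Stage I settings: `tol`, `max_iter` (defaults 1e-3 /
#'   20 for full observation, 1e-2 / 10 for partial), `beta0` (initial guess
#'   override for the partial case), `rtol`.
#' @param smoothing optional precomputed [smooth_dataset] result.
#' @return list of class `gmgts_fit` with `population`
#'   (a `population_estimate`), `individual` (list of `individual_estimate`),
#'   `smoothing`, `partial` (logical), and `runtime_seconds`.
#' @export
gmgts <- function(dataset, family = c("normal", "lognormal"), knots = NULL,
                  lambda = NULL, stage1 = list(), smoothing = NULL) {
  family <- match.arg(family)
  t0 <- proc.time()[["elapsed"]]
  model <- dataset$model
  if (!model$linear) {
    stop("gradient matching requires a model that is linear in parameters ",
         "(g/h decomposition); use gts_pipeline() for '", model$name, "'")
  }
  obs_idx <- observed_indices(dataset$measurement)
  partial <- length(obs_idx) < model$K
  sm <- smoothing %||% smooth_dataset(dataset, knots = knots, lambda = lambda)
  ests <- vector("list", length(dataset$cells))
  for (i in seq_along(dataset$cells)) {
    fits <- sm$cells[[i]]$fits
    ests[[i]] <- if (partial) {
      stage1_partial(model, fits, obs_idx,
                     beta0 = stage1$beta0,
                     tol = stage1$tol %||% 1e-2,
                     max_iter = stage1$max_iter %||% 10,
                     rtol = stage1$rtol %||% 1e-6,
                     cell_id = dataset$cells[[i]]$cell_id)
    } else {
      fgls_fit(model, fits[order(obs_idx)],
               tol = stage1$tol %||% 1e-3,
               max_iter = stage1$max_iter %||% 20,
               cell_id = dataset$cells[[i]]$cell_id)
    }
  }
  pop <- if (family == "normal") em_fit(ests) else lognormal_fit(ests)
  structure(list(population = pop, individual = ests, smoothing = sm,
                 partial = partial,
                 runtime_seconds = proc.time()[["elapsed"]] - t0),
            class = "gmgts_fit")
}

#' @export
print.gmgts_fit <- function(x, ...) {
  cat("<gmgts_fit> ", length(x$individual), " cells, ",
      if (x$partial) "partial" else "full", " observation, ",
      signif(x$runtime_seconds, 3), " s\n", sep = "")
  conv <- mean(vapply(x$individual, `[[`, logical(1), "converged"))
  cat("  Stage I converged: ", round(100 * conv, 1), "% of cells\n", sep = "")
  print(x$population)
  invisible(x)
}
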