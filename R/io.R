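# File round-tripping and command entry points. Datasets are stored as
# long-format CSV (cell_id, time, state_name, value) with a JSON sidecar
# holding the model identity, measurement model, seed, and — for simulated
# data — the generating distribution and ground-truth parameters.

#' Rebuild a built-in model from its serialized name
#' @keywords internal
#' @noRd
model_from_name <- function(name, fixed_params = NULL) {
  fp <- as.list(fixed_params %||% list())
  if (grepl("^lotka_volterra_m\\d+$", name)) {
    return(make_lotka_volterra(m = as.integer(sub("^lotka_volterra_m", "",
                                                  name))))
  }
  if (name == "repressilator_expanded") {
    return(make_repressilator(expanded = TRUE, kappa = fp$kappa %||% 10))
  }
  if (name == "repressilator_hill") {
    return(make_repressilator(expanded = FALSE))
  }
  if (name %in% c("fp_one_step", "fp_two_step")) {
    return(make_fp_maturation(steps = if (name == "fp_one_step") 1 else 2,
                              k_r = fp$k_r %||% 0.1,
                              k_dr = fp$k_dr %||% 0.07,
                              k_dil = fp$k_dil %||% 0.004,
                              t_on = fp$t_on %||% 0))
  }
  stop("cannot rebuild model '", name, "' from its name; only built-in ",
       "models round-trip through files")
}

#' Write a dataset to CSV + JSON sidecar
#'
#' @param dataset a [population_dataset] whose model is one of the built-in
#'   systems.
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, prefix) {
  obs_idx <- observed_indices(dataset$measurement)
  state_names <- dataset$model$state_names[obs_idx]
  rows <- lapply(dataset$cells, function(cell) {
    data.frame(cell_id = cell$cell_id,
               time = rep(cell$t, times = length(state_names)),
               state_name = rep(state_names, each = length(cell$t)),
               value = as.numeric(cell$y))
  })
  df <- do.call(rbind, rows)
  csv_path <- paste0(prefix, ".csv")
  json_path <- paste0(prefix, ".json")
  utils::write.csv(df, csv_path, row.names = FALSE)
  gd <- dataset$generating_distribution
  sidecar <- list(
    model_name = dataset$model$name,
    fixed_params = as.list(dataset$model$fixed_params),
    Q = dataset$measurement$Q,
    sigma = dataset$measurement$sigma,
    tau = dataset$measurement$tau,
    seed = dataset$seed,
    scenario = dataset$scenario,
    generating_distribution = if (!is.null(gd)) {
      list(family = gd$family, b = gd$b, D = gd$D)
    },
    true_betas = {
      tb <- lapply(dataset$cells, `[[`, "true_beta")
      if (all(vapply(tb, is.null, logical(1)))) NULL else do.call(rbind, tb)
    },
    cell_ids = vapply(dataset$cells, `[[`, character(1), "cell_id")
  )
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a dataset written by [write_dataset]
#'
#' @param prefix path prefix used when writing.
#' @return a [population_dataset].
#' @export
read_dataset <- function(prefix) {
  # explicit column classes: state names like "F" must not parse as logicals
  df <- utils::read.csv(paste0(prefix, ".csv"),
                        colClasses = c(cell_id = "character",
                                       time = "numeric",
                                       state_name = "character",
                                       value = "numeric"))
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  model <- model_from_name(sc$model_name, sc$fixed_params)
  Q <- matrix(as.numeric(sc$Q), nrow = length(sc$sigma), byrow = FALSE)
  meas <- measurement_model(Q, sigma = sc$sigma, tau = sc$tau)
  obs_names <- model$state_names[observed_indices(meas)]
  tb <- sc$true_betas
  cells <- lapply(seq_along(sc$cell_ids), function(i) {
    id <- sc$cell_ids[i]
    sub <- df[df$cell_id == id, ]
    tgrid <- sort(unique(sub$time))
    y <- vapply(obs_names, function(sn) {
      s <- sub[sub$state_name == sn, ]
      s$value[order(s$time)]
    }, numeric(length(tgrid)))
    cell_measurements(id, tgrid, y,
                      true_beta = if (!is.null(tb)) tb[i, ])
  })
  gd <- if (!is.null(sc$generating_distribution)) {
    population_distribution(sc$generating_distribution$family,
                            sc$generating_distribution$b,
                            matrix(as.numeric(sc$generating_distribution$D),
                                   length(sc$generating_distribution$b)))
  }
  population_dataset(cells, model, meas, generating_distribution = gd,
                     seed = sc$seed %||% NA, scenario = sc$scenario)
}

#' Write Stage I individual estimates to JSON
#' @param estimates list of `individual_estimate`.
#' @param path output JSON file.
#' @export
write_individual_estimates <- function(estimates, path) {
  out <- lapply(estimates, function(e) {
    list(cell_id = e$cell_id, beta_hat = e$beta_hat,
         C = as.numeric(t(e$C)),  # row-major
         n_iter = e$n_iter, converged = e$converged,
         n_integrations = e$n_integrations)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a population estimate to JSON
#' @param pop a `population_estimate`.
#' @param path output JSON file.
#' @export
write_population_estimate <- function(pop, path) {
  jsonlite::write_json(
    list(family = pop$family, b_hat = pop$b_hat, D_hat = pop$D_hat,
         loglik_trace = pop$loglik_trace, n_iter = pop$n_iter,
         converged = pop$converged),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a population estimate written by [write_population_estimate]
#' @param path JSON file.
#' @export
read_population_estimate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(family = x$family, b_hat = as.numeric(x$b_hat),
                 D_hat = matrix(as.numeric(x$D_hat), length(x$b_hat),
                                byrow = TRUE),
                 loglik_trace = as.numeric(x$loglik_trace),
                 n_iter = x$n_iter, converged = x$converged),
            class = "population_estimate")
}

#' Simulate a scenario and write it to disk (command entry point)
#'
#' @param config list with `scenario` (id), `out` (path prefix), `seed`, and
#'   optional overrides `N`, `tau`, `sigma`, `tgrid`.
#' @return the written [population_dataset], invisibly.
#' @export
cli_simulate <- function(config) {
  stopifnot(is.list(config), !is.null(config$scenario), !is.null(config$out))
  overrides <- config[intersect(names(config),
                                c("N", "tau", "sigma", "tgrid"))]
  ds <- generate_scenario(config$scenario, seed = config$seed %||% 1,
                          overrides = overrides)
  write_dataset(ds, config$out)
  message("wrote ", length(ds$cells), " cells to ", config$out, ".csv/.json")
  invisible(ds)
}

#' Fit a stored dataset (command entry point)
#'
#' Runs smoothing, Stage I (full or partial observation auto-detected from
#' the selection matrix), and Stage II, and writes
#' `<out>_individual.json` and `<out>_population.json`.
#'
#' @param config list with `data` (dataset prefix), `out` (output prefix),
#'   `method` (`"gmgts"` or `"gts"`), `family`, `seed`.
#' @return list of fit results, invisibly.
#' @export
cli_fit <- function(config) {
  stopifnot(is.list(config), !is.null(config$data), !is.null(config$out))
  method <- match.arg(config$method %||% "gmgts", c("gmgts", "gts"))
  family <- match.arg(config$family %||% "normal", c("normal", "lognormal"))
  ds <- read_dataset(config$data)
  if (method == "gmgts") {
    fit <- gmgts(ds, family = family)
    ests <- fit$individual
    pop <- fit$population
  } else {
    fit <- gts_pipeline(ds, family = family, seed = config$seed %||% 1)
    ests <- lapply(fit$individual[!vapply(fit$individual, is.null,
                                          logical(1))],
                   function(f) individual_estimate(
                     f$beta_hat, f$C, NA, TRUE, cell_id = f$cell_id,
                     n_integrations = f$n_integrations))
    pop <- fit$population
  }
  write_individual_estimates(ests, paste0(config$out, "_individual.json"))
  write_population_estimate(pop, paste0(config$out, "_population.json"))
  message("wrote estimates to ", config$out, "_{individual,population}.json")
  invisible(fit)
}

#' Compare stored estimates against stored ground truth (command entry point)
#'
#' @param config list with `data` (dataset prefix; must carry a generating
#'   distribution), `estimate` (population-estimate JSON), `out` (report
#'   prefix; writes `<out>_report.json` and `<out>_report.txt`).
#' @return the [recovery_report], invisibly.
#' @export
cli_evaluate <- function(config) {
  stopifnot(is.list(config), !is.null(config$data),
            !is.null(config$estimate), !is.null(config$out))
  ds <- read_dataset(config$data)
  if (is.null(ds$generating_distribution)) {
    stop("dataset ", config$data, " carries no ground-truth distribution")
  }
  pop <- read_population_estimate(config$estimate)
  rep <- recovery_report(pop, ds$generating_distribution)
  jsonlite::write_json(
    list(w2_normalized = rep$w2_normalized,
         mean_rel_error = rep$mean_rel_error,
         sd_rel_error = rep$sd_rel_error,
         correlation_error = rep$correlation_error),
    paste0(config$out, "_report.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  txt <- utils::capture.output(print(rep))
  writeLines(txt, paste0(config$out, "_report.txt"))
  message("wrote report to ", config$out, "_report.{json,txt}")
  invisible(rep)
}
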