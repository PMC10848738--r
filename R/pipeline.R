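#' Configuration for a full pipeline run
#'
#' @param observations annual abundance tibble (`year`, `L`, `J`, `A`) or
#'   a CSV path.
#' @param env long environment table (`year`, `month`, `factor`, `value`)
#'   or a CSV path.
#' @param preset model preset, `"RK"` or `"BH"`.
#' @param cost a [cost_config()].
#' @param factors candidate driver factors for the attribution stage.
#' @param K CV folds.
#' @param lambda_grid,tau_grid fused-LASSO hyperparameter grids.
#' @param n_primary,n_final,evals_per_cycle anomaly-fit cycle budgets.
#' @param n_permutations permutation-experiment size.
#' @param bootstrap_B bootstrap resamples for the coefficient bands.
#' @param seed integer seed used (with fixed offsets) by every stochastic
#'   stage.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(observations, env, preset = c("RK", "BH"),
                            cost = cost_config(),
                            factors = c("Chl", "T", "Ice", "SAM"),
                            K = 9,
                            lambda_grid = 10^seq(-4, 1, length.out = 8),
                            tau_grid = 10^seq(-4, 1, length.out = 8),
                            n_primary = 10, n_final = 20,
                            evals_per_cycle = 3000,
                            n_permutations = 200, bootstrap_B = 500,
                            seed = 1, out_dir = tempfile("krillab_run_")) {
  preset <- match.arg(preset)
  if (is.character(observations)) {
    observations <- tibble::as_tibble(utils::read.csv(observations))
  }
  if (is.character(env)) env <- tibble::as_tibble(utils::read.csv(env))
  stopifnot(
    all(c("year", "L", "J", "A") %in% names(observations)),
    all(c("year", "month", "factor", "value") %in% names(env))
  )
  structure(
    list(
      observations = observations, env = env, preset = preset, cost = cost,
      factors = factors, K = K, lambda_grid = lambda_grid,
      tau_grid = tau_grid, n_primary = n_primary, n_final = n_final,
      evals_per_cycle = evals_per_cycle, n_permutations = n_permutations,
      bootstrap_B = bootstrap_B, seed = seed, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

.log_line <- function(log_path, ...) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
    file = log_path, append = TRUE)
}

#' Run the three-step analysis pipeline
#'
#' Executes, in order: (1) the time-constant model fit; (2) the annual
#' loss-anomaly fit with sign-consistency significance; (3) the
#' attribution stage — correlation screens, factor-subset fused-LASSO
#' selection with CV, bootstrap coefficient bands, anomaly prediction
#' R^2, and the permuted-anomaly stock-recruit experiment. Every stage
#' writes its CSV output to `config$out_dir`, a key-value `summary.csv`
#' collects headline numbers, and `run_log.txt` records seeds and stage
#' completion. Any stage failure aborts with the stage name; partial
#' outputs are preserved.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `timeconstant`,
#'   `anomaly_fit`, `screens`, `selections`, `bands`, `scores`,
#'   `permutation`, `summary`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat("", file = log_path)
  .log_line(log_path, "krillab", as.character(utils::packageVersion("krillab")),
    "| preset", config$preset, "| seed", config$seed)
  stage <- function(name, expr) {
    .log_line(log_path, "stage start:", name)
    res <- tryCatch(expr, error = function(e) {
      .log_line(log_path, "stage FAILED:", name, "|", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE)
    })
    .log_line(log_path, "stage done: ", name)
    res
  }
  out <- function(f) file.path(config$out_dir, f)
  summary_rows <- list()
  note <- function(key, value) {
    summary_rows[[length(summary_rows) + 1]] <<- tibble::tibble(
      key = key, value = as.character(value)
    )
  }
  note("seed", config$seed)
  note("preset", config$preset)

  tc <- stage("fit_timeconstant", {
    fit <- fit_timeconstant(config$observations, config$preset,
      config = config$cost, seed = config$seed)
    write_params(fit$params, out("params_fitted.csv"))
    fit
  })
  note("timeconstant_cost", tc$cost)

  af <- stage("fit_anomalies", {
    fit <- fit_anomalies(config$observations, tc$params,
      config = config$cost,
      n_primary = config$n_primary, n_final = config$n_final,
      evals_per_cycle = config$evals_per_cycle, seed = config$seed)
    write_anomalies(fit, out("anomalies.csv"), out("anomaly_cycles.csv"))
    fit
  })
  note("anomaly_cost", af$cost)
  note("n_retained_cycles", af$n_retained)

  cohorts <- c(L = "delta_L", J = "delta_J")
  screens <- stage("correlation_screen", {
    res <- lapply(names(cohorts), function(k) {
      scr <- correlation_screen(
        tibble::tibble(year = af$anomalies$year,
          delta = af$anomalies[[cohorts[[k]]]]),
        config$env
      )
      utils::write.csv(scr, out(sprintf("screen_%s.csv", k)),
        row.names = FALSE)
      scr
    })
    stats::setNames(res, names(cohorts))
  })

  selections <- stage("subset_model_selection", {
    res <- lapply(names(cohorts), function(k) {
      sel <- select_factor_subset(
        tibble::tibble(year = af$anomalies$year,
          delta = af$anomalies[[cohorts[[k]]]]),
        config$env, factors = config$factors, K = config$K,
        lambda_grid = config$lambda_grid, tau_grid = config$tau_grid,
        seed = config$seed
      )
      utils::write.csv(sel$table, out(sprintf("subset_models_%s.csv", k)),
        row.names = FALSE)
      sel
    })
    stats::setNames(res, names(cohorts))
  })
  for (k in names(selections)) {
    note(paste0("selected_subset_", k), selections[[k]]$selected_subset)
    note(paste0("cv_error_", k),
      min(selections[[k]]$table$cv_error))
  }

  bands <- stage("bootstrap_bands", {
    res <- lapply(names(cohorts), function(k) {
      sel <- selections[[k]]
      bb <- bootstrap_bands(sel$selected_design, sel$selected$lambda_l1,
        sel$selected$tau_fuse, B = config$bootstrap_B,
        seed = config$seed + 10L)
      utils::write.csv(bb, out(sprintf("coefficients_%s.csv", k)),
        row.names = FALSE)
      bb
    })
    stats::setNames(res, names(cohorts))
  })

  scores <- stage("predict_and_score", {
    res <- lapply(names(cohorts), function(k) {
      sel <- selections[[k]]
      sc <- predict_and_score(sel$selected, sel$selected_design)
      utils::write.csv(sc$predictions, out(sprintf("predicted_%s.csv", k)),
        row.names = FALSE)
      sc
    })
    stats::setNames(res, names(cohorts))
  })
  for (k in names(scores)) {
    note(paste0("r_squared_", k), scores[[k]]$r_squared)
  }

  perm <- stage("permuted_anomaly_experiment", {
    pe <- permuted_anomaly_experiment(af$anomalies, tc$params,
      n_permutations = config$n_permutations, seed = config$seed + 20L)
    utils::write.csv(pe, out("permutation_experiment.csv"),
      row.names = FALSE)
    pe
  })
  note("permuted_median_r", attr(perm, "median_r"))
  note("unpermuted_r", attr(perm, "unpermuted_r"))

  summary <- dplyr::bind_rows(summary_rows)
  utils::write.csv(summary, out("summary.csv"), row.names = FALSE)
  .log_line(log_path, "pipeline complete")
  structure(
    list(
      timeconstant = tc, anomaly_fit = af, screens = screens,
      selections = selections, bands = bands, scores = scores,
      permutation = perm, summary = summary, out_dir = config$out_dir
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> outputs in", x$out_dir, "\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Standalone simulation with CSV export
#'
#' Runs [simulate_krill()] and writes the trajectory and 1 January sample
#' CSVs.
#'
#' @param params a [krill_params()] object.
#' @param years simulated years.
#' @param out_dir output directory.
#' @param anomalies optional anomaly table.
#' @return the `krill_sim` object, invisibly.
#' @export
simulate_only <- function(params, years = 27, out_dir = tempfile("krillab_sim_"),
                          anomalies = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_krill(params, years = years, anomalies = anomalies)
  write_trajectory(sim, file.path(out_dir, "trajectory.csv"),
    file.path(out_dir, "jan1_samples.csv"))
  invisible(sim)
}
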