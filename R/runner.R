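#' @importFrom utils write.csv read.csv
NULL

.known_estimators <- c("PS-IPTW", "CF", "CF-clusterID", "CF-PS")

# run all requested estimators on one simulated cohort (paired design:
# every estimator sees the identical dataset).  The logistic PS model is
# fitted once and shared by PS-IPTW and CF-PS; the internal nuisance
# forests are fitted once and shared by the CF variants.
.run_cell <- function(cohort, estimators, ps_covariates, forest_covariates,
                      options, scale) {
  out <- list()
  ps <- NULL
  if (any(c("PS-IPTW", "CF-PS") %in% estimators)) {
    ps <- fit_propensity_logistic(cohort, ps_covariates)
  }
  if ("PS-IPTW" %in% estimators) {
    out$iptw <- tryCatch(
      estimate_iptw(cohort, ps_covariates, ps_model = ps),
      error = function(e) .failed_row("PS-IPTW")
    )
  }
  cf_wanted <- intersect(c("CF", "CF-clusterID", "CF-PS"), estimators)
  if (length(cf_wanted)) {
    nuis <- if (any(c("CF", "CF-PS") %in% cf_wanted)) {
      fit_nuisance_forests(cohort, forest_covariates, options)
    }
    run_variant <- function(label, nuisances, ...) {
      tryCatch({
        m <- fit_causal_forest(cohort, forest_covariates, options,
                               nuisances = nuisances, ...)
        res <- average_treatment_effect(m, scale = scale, label = label)
        res[c("estimator", "estimate", "se", "ci_low", "ci_high",
              "converged")]
      }, error = function(e) .failed_row(label))
    }
    if ("CF" %in% cf_wanted) out$cf <- run_variant("CF", nuis)
    if ("CF-clusterID" %in% cf_wanted) {
      # cluster subsampling applies to the nuisance forests as well
      out$cfc <- run_variant("CF-clusterID", NULL,
                             clusters = cohort$cluster_id)
    }
    if ("CF-PS" %in% cf_wanted) {
      out$cfps <- run_variant("CF-PS", nuis, external_ps = ps$fitted)
    }
  }
  dplyr::bind_rows(lapply(out, function(d) {
    d[intersect(c("estimator", "estimate", "se", "ci_low", "ci_high",
                  "converged"), names(d))]
  }))
}

.failed_row <- function(label) {
  tibble::tibble(estimator = label, estimate = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, converged = FALSE)
}

#' Run the parametric simulation grid
#'
#' For every scenario and replication: simulate one cohort, run all
#' requested estimators on that same cohort (paired design), and collect
#' the long results table; then compute per-scenario performance metrics.
#' Per-cell seeds are derived from `(root_seed, scenario index, rep)`, so
#' results are identical for serial and parallel execution and any cell
#' can be regenerated in isolation.  With an output directory the run is
#' resumable: completed `(scenario, rep)` cells found in `results.csv` are
#' not recomputed.
#'
#' @param scenarios list of [scenario_config()]s (default: canonical 20).
#' @param estimators subset of `PS-IPTW`, `CF`, `CF-clusterID`, `CF-PS`.
#' @param n_reps replications per scenario (default: each scenario's own).
#' @param root_seed root seed of the run.
#' @param scale reporting scale for the forest estimators.
#' @param options forest tuning options.
#' @param ps_covariates propensity-model covariates.
#' @param forest_covariates forest covariates.
#' @param truth truth table passed to [summarize_scenario()]; by default
#'   IPTW (a conditional estimator) is compared against each scenario's
#'   conditional treatment log odds ratio, and the forest estimators
#'   against the [true_effect()] value on their reporting `scale`.
#' @param workers number of parallel workers (forked; results identical to
#'   serial execution).
#' @param out_dir optional directory for `results.csv`, `metrics.csv` and
#'   `manifest.json`.
#' @return object of class `sim_run`: list with `results`, `metrics`,
#'   `manifest`.
#' @export
run_grid <- function(scenarios = make_scenario_grid(),
                     estimators = .known_estimators,
                     n_reps = NULL,
                     root_seed = 1L,
                     scale = "marginal_logor",
                     options = forest_options(),
                     ps_covariates = default_ps_covariates(),
                     forest_covariates = default_forest_covariates(),
                     truth = NULL,
                     workers = 1L,
                     out_dir = NULL) {
  estimators <- match.arg(estimators, .known_estimators, several.ok = TRUE)
  done <- .load_completed(out_dir)
  scenarios <- purrr::map(scenarios, calibrate_scenario)

  cells <- purrr::imap(scenarios, function(cfg, s_idx) {
    reps <- n_reps %||% cfg$n_reps
    purrr::map(seq_len(reps), function(r) {
      list(cfg = cfg, s_idx = s_idx, rep = r)
    })
  }) |> purrr::flatten()

  run_one <- function(cell) {
    key <- paste(cell$cfg$scenario_id, cell$rep)
    if (key %in% done$keys) {
      return(done$rows[done$rows$.key == key,
                       setdiff(names(done$rows), ".key")])
    }
    seed <- derive_seed(root_seed, cell$s_idx, cell$rep)
    opts <- options
    opts$seed <- derive_seed(seed, 7L)
    cohort <- simulate_cohort(cell$cfg, seed)
    res <- .run_cell(cohort, estimators, ps_covariates, forest_covariates,
                     opts, scale)
    dplyr::bind_cols(
      tibble::tibble(scenario_id = cell$cfg$scenario_id, rep = cell$rep,
                     seed = seed),
      res
    )
  }

  rows <- if (workers > 1) {
    parallel::mclapply(cells, run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(cells, run_one)
  }
  results <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$scenario_id, .data$rep, .data$estimator)

  truths <- truth %||% .grid_truths(scenarios, estimators, scale)
  metrics <- summarize_scenario(results, truths)

  manifest <- list(
    root_seed = root_seed,
    scenario_ids = purrr::map_chr(scenarios, "scenario_id"),
    estimators = estimators,
    n_reps = n_reps %||% purrr::map_int(scenarios, "n_reps"),
    scale = scale,
    package_version = as.character(utils::packageVersion("clustercf")),
    n_cells = length(cells),
    completed = nrow(results)
  )
  run <- structure(list(results = results, metrics = metrics,
                        manifest = manifest), class = "sim_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.load_completed <- function(out_dir) {
  empty <- list(keys = character(), rows = NULL)
  if (is.null(out_dir)) return(empty)
  path <- file.path(out_dir, "results.csv")
  man <- file.path(out_dir, "manifest.json")
  if (!file.exists(path)) return(empty)
  if (file.exists(man)) {
    ok <- tryCatch({jsonlite::read_json(man); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("corrupt manifest.json in ", out_dir,
                  "; refusing to resume")
  }
  rows <- tibble::as_tibble(utils::read.csv(path))
  rows$.key <- paste(rows$scenario_id, rows$rep)
  list(keys = unique(rows$.key), rows = rows)
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(run$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

# Per-(scenario, estimator) truth table.  Default comparison: every
# estimator against the design's conditional log odds ratio (IPTW
# estimates it directly; the forests report the marginal log odds ratio,
# whose noncollapsibility gap is then part of their measured bias).  In
# risk-difference mode the forests are instead compared against the Monte
# Carlo risk-difference truth, since a risk difference and a log odds
# ratio are not commensurable.
.grid_truths <- function(scenarios, estimators, scale) {
  purrr::map_dfr(scenarios, function(cfg) {
    forest_truth <- if (scale == "marginal_logor") {
      cfg$tau
    } else if (any(estimators != "PS-IPTW")) {
      true_effect(cfg, scale, seed = derive_seed(cfg$seed, 31L))
    } else {
      NA_real_
    }
    tibble::tibble(
      scenario_id = cfg$scenario_id,
      estimator = estimators,
      truth = ifelse(estimators == "PS-IPTW", cfg$tau, forest_truth)
    )
  })
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> %d result rows, %d metric rows, root seed %s\n",
              nrow(x$results), nrow(x$metrics), x$manifest$root_seed))
  invisible(x)
}

#' Run the plasmode simulation grid
#'
#' Mirrors [run_grid()] but cohorts come from [plasmode_simulate()] over a
#' grid of cluster-confounding strengths against a base cohort (the
#' seeded synthetic one, or any CSV with the base-cohort schema).
#'
#' @param base a base-cohort tibble, a CSV path, or `"synthetic"`.
#' @param gamma_z_grid treatment-model log-odds grid for the hospital
#'   covariates.
#' @param config a [plasmode_config()] template.
#' @param estimators,n_reps,root_seed,scale,options,workers,out_dir as in
#'   [run_grid()].
#' @return object of class `sim_run`.
#' @export
run_plasmode_grid <- function(base = "synthetic",
                              gamma_z_grid = .gamma_grid(),
                              config = plasmode_config(),
                              estimators = .known_estimators,
                              n_reps = NULL,
                              root_seed = 1L,
                              scale = "marginal_logor",
                              options = forest_options(),
                              workers = 1L,
                              out_dir = NULL) {
  estimators <- match.arg(estimators, .known_estimators, several.ok = TRUE)
  if (is.character(base)) {
    base <- if (identical(base, "synthetic")) {
      generate_synthetic_base_cohort(seed = derive_seed(root_seed, 77L))
    } else if (file.exists(base)) {
      read_base_cohort(base)
    } else {
      stop("base must be 'synthetic', an existing CSV path, or a tibble")
    }
  } else {
    base <- validate_base_cohort(base)
  }

  configs <- purrr::map(gamma_z_grid, function(g) {
    cfg <- config
    cfg$gamma_z <- g
    cfg$scenario_id <- sprintf("plasmode_or%.2f", exp(g))
    calibrate_plasmode(base, cfg)
  })

  cells <- purrr::imap(configs, function(cfg, s_idx) {
    reps <- n_reps %||% cfg$n_reps
    purrr::map(seq_len(reps), function(r) list(cfg = cfg, s_idx = s_idx,
                                               rep = r))
  }) |> purrr::flatten()

  covs <- plasmode_covariates()
  run_one <- function(cell) {
    seed <- derive_seed(root_seed, 1000L + cell$s_idx, cell$rep)
    opts <- options
    opts$seed <- derive_seed(seed, 7L)
    cohort <- plasmode_simulate(base, cell$cfg, seed)
    res <- .run_cell(cohort, estimators, covs, covs, opts, scale)
    dplyr::bind_cols(
      tibble::tibble(scenario_id = cell$cfg$scenario_id, rep = cell$rep,
                     seed = seed),
      res
    )
  }
  rows <- if (workers > 1) {
    parallel::mclapply(cells, run_one, mc.cores = workers)
  } else {
    lapply(cells, run_one)
  }
  results <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$scenario_id, .data$rep, .data$estimator)
  truths <- purrr::map_dfr(configs, function(cfg) {
    forest_truth <- if (scale == "marginal_logor") {
      cfg$tau
    } else if (any(estimators != "PS-IPTW")) {
      plasmode_true_effect(base, cfg, scale)
    } else {
      NA_real_
    }
    tibble::tibble(
      scenario_id = cfg$scenario_id,
      estimator = estimators,
      truth = ifelse(estimators == "PS-IPTW", cfg$tau, forest_truth)
    )
  })
  metrics <- summarize_scenario(results, truths)
  manifest <- list(
    root_seed = root_seed, arm = "plasmode",
    scenario_ids = truths$scenario_id, estimators = estimators,
    scale = scale, n_base = nrow(base),
    package_version = as.character(utils::packageVersion("clustercf")),
    completed = nrow(results)
  )
  run <- structure(list(results = results, metrics = metrics,
                        manifest = manifest), class = "sim_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}
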