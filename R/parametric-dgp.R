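#' Draw cluster sizes with a fixed total
#'
#' Sizes are drawn Poisson(`n_mean`) per cluster (zero draws bumped to 1),
#' then adjusted by single-patient additions/removals at uniformly random
#' clusters until the sum equals `total_target` exactly.  This honours both
#' a Poisson cluster-size distribution and a fixed total sample size.
#'
#' @param m number of clusters.
#' @param n_mean Poisson mean cluster size.
#' @param total_target exact total number of patients.
#' @param rng_seed optional seed; when `NULL` the current RNG stream is
#'   used (so callers can embed the draw in their own seeded stream).
#' @return integer vector of `m` positive sizes summing to `total_target`.
#' @export
#' @examples
#' sum(draw_cluster_sizes(10, 1000, 10000, rng_seed = 1))
draw_cluster_sizes <- function(m, n_mean, total_target, rng_seed = NULL) {
  stopifnot(m >= 1, n_mean >= 1)
  if (total_target < m) {
    stop("total_target < m: cannot give every cluster one patient")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sizes <- stats::rpois(m, n_mean)
  sizes[sizes == 0] <- 1L
  diff <- total_target - sum(sizes)
  while (diff > 0) {
    idx <- sample.int(m, min(diff, m), replace = FALSE)
    sizes[idx] <- sizes[idx] + 1L
    diff <- total_target - sum(sizes)
  }
  while (diff < 0) {
    cand <- which(sizes > 1)
    idx <- sample(cand, min(-diff, length(cand)), replace = FALSE)
    sizes[idx] <- sizes[idx] - 1L
    diff <- total_target - sum(sizes)
  }
  as.integer(sizes)
}

#' Calibrate a logistic intercept to a prevalence target
#'
#' Finds `alpha` such that `mean(plogis(alpha + LP))` hits
#' `prevalence_target`, by monotone root-finding over a Monte Carlo sample
#' of the intercept-free linear predictor.  Used because the generating
#' models fix every slope but leave the intercepts free; calibrating both
#' intercepts to 50% prevalence is the package's neutral default.
#'
#' @param linear_predictor_sampler function of one argument `n` returning
#'   `n` draws of the intercept-free linear predictor.
#' @param prevalence_target target prevalence in (0, 1).
#' @param tolerance absolute tolerance on the achieved prevalence.
#' @param n_mc Monte Carlo sample size.
#' @return the calibrated intercept (scalar).
#' @export
#' @examples
#' calibrate_intercept(function(n) rep(0, n), 0.731) # ~ logit(0.731)
calibrate_intercept <- function(linear_predictor_sampler, prevalence_target,
                                tolerance = 1e-4, n_mc = 200000L) {
  stopifnot(prevalence_target > 0, prevalence_target < 1)
  lp <- linear_predictor_sampler(n_mc)
  f <- function(a) mean(expit(a + lp)) - prevalence_target
  root <- stats::uniroot(f, interval = c(-30, 30), tol = tolerance / 10,
                         extendInt = "upX", maxiter = 200)
  if (abs(f(root$root)) > tolerance) {
    stop("intercept calibration did not reach the requested tolerance")
  }
  root$root
}

# covariate draws shared by cohort simulation and intercept calibration;
# marginal = TRUE ignores the cluster layout (z1/z2 drawn per patient),
# which leaves their patient-level marginals unchanged
.draw_covariates <- function(n, sizes = NULL) {
  if (is.null(sizes)) {
    z1 <- stats::rnorm(n)
    z2 <- stats::rbinom(n, 1, 0.5)
    cluster_id <- NULL
  } else {
    m <- length(sizes)
    z1 <- rep(stats::rnorm(m), times = sizes)
    z2 <- rep(stats::rbinom(m, 1, 0.5), times = sizes)
    cluster_id <- rep(seq_len(m), times = sizes)
  }
  tibble::tibble(
    cluster_id = cluster_id %||% NA_integer_,
    z1 = z1, z2 = z2,
    x1 = stats::rbinom(n, 1, 0.4),
    x2 = stats::rbinom(n, 1, 0.45),
    x3 = stats::rbinom(n, 1, 0.5),
    x4 = stats::rnorm(n),
    x5 = stats::rnorm(n),
    x6 = stats::rbinom(n, 1, 0.5),
    x7 = stats::rbinom(n, 1, 0.5)
  )
}

.lp_treat <- function(d, cfg) {
  as.numeric(
    as.matrix(d[paste0("x", 1:5)]) %*% cfg$beta_x_treat +
      cfg$beta_instrument * d$x7 +
      cfg$gamma_z * (d$z1 + d$z2) +
      cfg$delta_interaction * d$z1 * d$x1
  )
}

.lp_outcome <- function(d, cfg) {
  as.numeric(
    as.matrix(d[paste0("x", 1:5)]) %*% cfg$beta_x_out +
      cfg$beta_riskfactor * d$x6 +
      cfg$gamma_z_out * (d$z1 + d$z2)
  )
}

#' Calibrate a scenario's model intercepts
#'
#' Fills `alpha0` (treatment model) and `lambda0` (outcome model) so the
#' marginal treatment and outcome prevalences match their targets, using a
#' seeded Monte Carlo sample of the covariate distribution.  The outcome
#' intercept is calibrated with the treatment drawn from the already
#' calibrated treatment model, so `lambda0` accounts for the `tau * T`
#' term.  Idempotent: a config with intercepts present is returned as is.
#'
#' @param config a `scenario_config`.
#' @param n_mc Monte Carlo sample size for calibration.
#' @return the config with `alpha0` and `lambda0` set.
#' @export
calibrate_scenario <- function(config, n_mc = 200000L) {
  if (!is.null(config$alpha0) && !is.null(config$lambda0)) return(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 999983L))
  d <- .draw_covariates(n_mc)
  lp_t <- .lp_treat(d, config)
  config$alpha0 <- calibrate_intercept(function(n) lp_t,
                                       config$treat_prevalence_target)
  tr <- stats::rbinom(n_mc, 1, expit(config$alpha0 + lp_t))
  lp_y <- .lp_outcome(d, config) + config$tau * tr
  config$lambda0 <- calibrate_intercept(function(n) lp_y,
                                        config$outcome_prevalence_target)
  config
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one clustered cohort
#'
#' Draws cluster sizes, broadcasts cluster-level confounders to members,
#' draws patient-level covariates, then treatment and outcome from the
#' logistic models of the scenario.  Identical `(config, rep_seed)` pairs
#' give identical tables.  A degenerate draw (a single treatment arm or a
#' constant outcome) triggers one automatic reseeded redraw, then an error.
#'
#' @param config a `scenario_config`; intercepts are calibrated on the fly
#'   when absent.
#' @param rep_seed integer seed for this replication.
#' @return a tibble with `row_id`, `cluster_id` (factor), `z1`, `z2`,
#'   `x1..x7`, `treatment`, `outcome`.
#' @export
#' @examples
#' cohort <- simulate_cohort(
#'   scenario_config(10, 50, total_target = 500), rep_seed = 1)
#' nlevels(cohort$cluster_id)
simulate_cohort <- function(config, rep_seed) {
  config <- calibrate_scenario(config)
  for (attempt in 1:2) {
    seed <- if (attempt == 1) rep_seed else derive_seed(rep_seed, 424243L)
    set.seed(seed)
    sizes <- draw_cluster_sizes(config$n_clusters, config$mean_cluster_size,
                                config$total_target)
    n <- sum(sizes)
    d <- .draw_covariates(n, sizes = sizes)
    d$treatment <- stats::rbinom(n, 1, expit(config$alpha0 + .lp_treat(d, config)))
    p_y <- expit(config$lambda0 + config$tau * d$treatment + .lp_outcome(d, config))
    d$outcome <- stats::rbinom(n, 1, p_y)
    ok <- length(unique(d$treatment)) == 2 && length(unique(d$outcome)) == 2
    if (ok) {
      d$cluster_id <- factor(d$cluster_id)
      return(tibble::tibble(row_id = seq_len(n), d))
    }
  }
  stop("degenerate cohort (single treatment arm or constant outcome) after reseed")
}

#' True treatment effect of a scenario on a requested scale
#'
#' The conditional log odds ratio is the scenario's `tau` by construction.
#' Marginal scales are computed by simulating both potential outcomes for a
#' large Monte Carlo population under the scenario: the marginal log odds
#' ratio contrasts the potential-outcome prevalences on the logit scale and
#' the risk difference contrasts them directly.  Because the outcome model
#' has non-null covariate effects, the marginal log odds ratio is smaller
#' in magnitude than `tau` (noncollapsibility of the odds ratio).
#'
#' @param config a `scenario_config`.
#' @param scale one of `"conditional_logor"`, `"marginal_logor"`,
#'   `"risk_difference"`.
#' @param n_mc Monte Carlo population size for the marginal scales.
#' @param seed seed for the Monte Carlo population.
#' @return scalar effect on the requested scale.
#' @export
true_effect <- function(config,
                        scale = c("conditional_logor", "marginal_logor",
                                  "risk_difference"),
                        n_mc = 200000L, seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "conditional_logor") return(config$tau)
  stopifnot(n_mc >= 1e5)
  config <- calibrate_scenario(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d <- .draw_covariates(n_mc)
  lp_y <- config$lambda0 + .lp_outcome(d, config)
  p1 <- mean(expit(lp_y + config$tau))
  p0 <- mean(expit(lp_y))
  switch(scale,
    marginal_logor = stats::qlogis(p1) - stats::qlogis(p0),
    risk_difference = p1 - p0
  )
}

#' Write a cohort to CSV (or Parquet)
#'
#' @param cohort a cohort tibble from [simulate_cohort()] or
#'   [plasmode_simulate()].
#' @param path output file; `.parquet` extension switches to Parquet (needs
#'   the arrow package), anything else writes CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required for Parquet output")
    }
    arrow::write_parquet(cohort, path)
  } else {
    utils::write.csv(cohort, path, row.names = FALSE)
  }
  invisible(path)
}
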