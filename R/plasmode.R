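#' Generate a synthetic pancreatectomy-style base cohort
#'
#' A seeded stand-in for a hospital EHR surgery cohort: patient-level age,
#' sex and Charlson comorbidity index plus hospital-level teaching status,
#' size (>= 500 beds) and yearly procedure volume, with patients nested in
#' hospitals (defaults: 9981 patients across 341 hospitals, about 30 per
#' hospital).  The object is synthetic: it reproduces the shape and
#' plausible marginals of such a cohort, not any real data.  Hospital sizes
#' are multinomial with gamma-distributed propensities (so volumes are
#' right-skewed); age is truncated normal (65, 12) floored at 18; Charlson
#' is drawn through a Gaussian copula with rank correlation about 0.3 with
#' age; teaching and large-hospital status are more likely at high-volume
#' hospitals.
#'
#' @param n_patients total patients (default 9981).
#' @param n_hospitals number of hospitals (default 341).
#' @param seed integer seed.
#' @return a tibble with `patient_id`, `hospital_id` (factor), `age`,
#'   `sex`, `charlson`, `teaching`, `large_hospital`, `annual_volume`;
#'   hospital-level fields are constant within `hospital_id`.
#' @export
#' @examples
#' base <- generate_synthetic_base_cohort(1000, 40, seed = 1)
#' mean(table(base$hospital_id))
generate_synthetic_base_cohort <- function(n_patients = 9981L,
                                           n_hospitals = 341L,
                                           seed = 1L) {
  stopifnot(n_patients >= n_hospitals, n_hospitals >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  prop <- stats::rgamma(n_hospitals, shape = 2, rate = 1)
  sizes <- 1L + stats::rmultinom(1, n_patients - n_hospitals,
                                 prob = prop)[, 1]
  annual_volume <- pmax(1L, as.integer(round(sizes / 5)))  # 5 study years
  lv <- log(annual_volume)
  vol_s <- (lv - mean(lv)) / max(stats::sd(lv), 1e-8)
  teaching <- stats::rbinom(n_hospitals, 1, expit(-1 + 1.5 * vol_s))
  large_hospital <- stats::rbinom(n_hospitals, 1, expit(-0.8 + 1.2 * vol_s))

  n <- n_patients
  u <- stats::runif(n, stats::pnorm(18, 65, 12), 1)
  age <- stats::qnorm(u, 65, 12)
  age_lat <- stats::qnorm(u)                    # latent normal behind age
  rho <- 0.3
  ch_lat <- rho * age_lat + sqrt(1 - rho^2) * stats::rnorm(n)
  charlson <- stats::qnbinom(stats::pnorm(ch_lat), size = 1.5, mu = 2)

  hospital <- rep(seq_len(n_hospitals), times = sizes)
  tibble::tibble(
    patient_id = seq_len(n),
    hospital_id = factor(hospital),
    age = age,
    sex = stats::rbinom(n, 1, 0.5),
    charlson = as.integer(charlson),
    teaching = teaching[hospital],
    large_hospital = large_hospital[hospital],
    annual_volume = annual_volume[hospital]
  )
}

#' Read / write a base cohort CSV
#'
#' Any CSV with the base-cohort schema (`patient_id`, `hospital_id`,
#' `age`, `sex`, `charlson`, `teaching`, `large_hospital`,
#' `annual_volume`) is accepted interchangeably with the synthetic one, so
#' a real cohort can be substituted without code changes.
#'
#' @param path CSV file path.
#' @return a validated base-cohort tibble.
#' @export
read_base_cohort <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  validate_base_cohort(d)
}

#' @rdname read_base_cohort
#' @param base base-cohort tibble to write.
#' @export
write_base_cohort <- function(base, path) {
  utils::write.csv(base, path, row.names = FALSE)
  invisible(path)
}

validate_base_cohort <- function(base) {
  need <- c("patient_id", "hospital_id", "age", "sex", "charlson",
            "teaching", "large_hospital", "annual_volume")
  missing <- setdiff(need, names(base))
  if (length(missing)) {
    stop("base cohort is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(base$age < 18)) stop("base cohort contains patients under 18")
  const <- base |>
    dplyr::group_by(.data$hospital_id) |>
    dplyr::summarise(dplyr::across(
      c("teaching", "large_hospital", "annual_volume"),
      ~ dplyr::n_distinct(.x)
    ), .groups = "drop")
  if (any(as.matrix(const[-1]) != 1)) {
    stop("hospital-level fields vary within a hospital_id")
  }
  base$hospital_id <- factor(base$hospital_id)
  base
}

#' Bootstrap-resample a base cohort
#'
#' Rows (whole covariate vectors, hospital id included) are sampled
#' uniformly with replacement, which preserves the joint covariate
#' distribution; patient ids are rewritten.
#'
#' @param base base-cohort tibble.
#' @param n_sim number of rows to draw (default: base size).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return resampled base-cohort tibble with fresh `patient_id`.
#' @export
plasmode_resample <- function(base, n_sim = nrow(base), seed = NULL) {
  stopifnot(nrow(base) >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(base), n_sim, replace = TRUE)
  out <- base[idx, , drop = FALSE]
  out$patient_id <- seq_len(n_sim)
  attr(out, "source_rows") <- idx
  out
}

#' Configure a plasmode simulation
#'
#' Exposure and outcome are generated from logistic models over the
#' standardized base covariates.  The hospital-level covariates (teaching,
#' large hospital, standardized log annual volume) receive `gamma_z` on
#' the treatment model — the same confounding grid as the parametric arm —
#' and `gamma_z_out` each on the outcome model; patient-level covariates
#' (standardized age, sex, standardized Charlson) receive
#' `exposure_coefs` / `outcome_coefs`.  Coefficient defaults mirror the
#' parametric arm's first three confounder effects; they are declared
#' package defaults, not estimates from any real cohort.
#'
#' @param n_sim simulated cohort size; `NULL` means the base size.
#' @param gamma_z hospital-covariate log-odds effect on treatment.
#' @param gamma_z_out hospital-covariate log-odds effect on outcome.
#' @param tau true conditional treatment log odds ratio.
#' @param exposure_coefs,outcome_coefs length-3 coefficients for
#'   (age, sex, charlson), applied after standardization.
#' @param treat_prevalence_target,outcome_prevalence_target intercept
#'   calibration targets.
#' @param n_reps replication count.
#' @param seed base seed.
#' @return list of class `plasmode_config`.
#' @export
plasmode_config <- function(n_sim = NULL,
                            gamma_z = 0.4055,
                            gamma_z_out = 0.4055,
                            tau = 0.4055,
                            exposure_coefs = c(0.35, 0.4, 0.45),
                            outcome_coefs = c(0.35, 0.4, 0.45),
                            treat_prevalence_target = 0.5,
                            outcome_prevalence_target = 0.5,
                            n_reps = 100L,
                            seed = 20232L) {
  stopifnot(
    length(exposure_coefs) == 3, length(outcome_coefs) == 3,
    treat_prevalence_target > 0, treat_prevalence_target < 1,
    outcome_prevalence_target > 0, outcome_prevalence_target < 1
  )
  structure(list(
    n_sim = n_sim, gamma_z = gamma_z, gamma_z_out = gamma_z_out, tau = tau,
    exposure_coefs = exposure_coefs, outcome_coefs = outcome_coefs,
    treat_prevalence_target = treat_prevalence_target,
    outcome_prevalence_target = outcome_prevalence_target,
    n_reps = as.integer(n_reps), seed = as.integer(seed),
    alpha0 = NULL, lambda0 = NULL
  ), class = "plasmode_config")
}

# standardized design columns used by both models; scaling constants come
# from the base cohort so coefficients keep their meaning across resamples
.plasmode_design <- function(d, center) {
  tibble::tibble(
    age_s = (d$age - center$age_mean) / center$age_sd,
    sex = d$sex,
    charlson_s = (d$charlson - center$ch_mean) / center$ch_sd,
    teaching = d$teaching,
    large_hospital = d$large_hospital,
    volume_s = (log(d$annual_volume) - center$vol_mean) / center$vol_sd
  )
}

.plasmode_center <- function(base) {
  list(
    age_mean = mean(base$age), age_sd = stats::sd(base$age),
    ch_mean = mean(base$charlson), ch_sd = max(stats::sd(base$charlson), 1e-8),
    vol_mean = mean(log(base$annual_volume)),
    vol_sd = max(stats::sd(log(base$annual_volume)), 1e-8)
  )
}

.plasmode_lp_treat <- function(des, cfg) {
  as.numeric(as.matrix(des[c("age_s", "sex", "charlson_s")]) %*%
               cfg$exposure_coefs) +
    cfg$gamma_z * (des$teaching + des$large_hospital + des$volume_s)
}

.plasmode_lp_outcome <- function(des, cfg) {
  as.numeric(as.matrix(des[c("age_s", "sex", "charlson_s")]) %*%
               cfg$outcome_coefs) +
    cfg$gamma_z_out * (des$teaching + des$large_hospital + des$volume_s)
}

#' Calibrate plasmode model intercepts against a base cohort
#'
#' @param base base-cohort tibble.
#' @param config a `plasmode_config`.
#' @return the config with `alpha0`, `lambda0` and the standardization
#'   constants filled in.
#' @export
calibrate_plasmode <- function(base, config) {
  if (!is.null(config$alpha0) && !is.null(config$lambda0)) return(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 999979L))
  config$center <- .plasmode_center(base)
  des <- .plasmode_design(base, config$center)
  lp_t <- .plasmode_lp_treat(des, config)
  config$alpha0 <- calibrate_intercept(function(n) lp_t,
                                       config$treat_prevalence_target)
  tr <- stats::rbinom(nrow(des), 1, expit(config$alpha0 + lp_t))
  lp_y <- .plasmode_lp_outcome(des, config) + config$tau * tr
  config$lambda0 <- calibrate_intercept(function(n) lp_y,
                                        config$outcome_prevalence_target)
  config
}

#' Simulate one plasmode cohort
#'
#' Bootstrap-resamples the base covariates, then generates treatment and
#' outcome from the configured logistic models with calibrated intercepts.
#' The output uses the estimator-facing cohort schema: `cluster_id` is the
#' hospital id and the standardized design columns are the covariates.
#'
#' @param base base-cohort tibble.
#' @param config a `plasmode_config`.
#' @param rep_seed seed for this replication.
#' @return a cohort tibble with `row_id`, `cluster_id`, the design columns
#'   (`age_s`, `sex`, `charlson_s`, `teaching`, `large_hospital`,
#'   `volume_s`), `treatment` and `outcome`.
#' @export
plasmode_simulate <- function(base, config, rep_seed) {
  config <- calibrate_plasmode(base, config)
  n_sim <- config$n_sim %||% nrow(base)
  for (attempt in 1:2) {
    seed <- if (attempt == 1) rep_seed else derive_seed(rep_seed, 424243L)
    set.seed(seed)
    res <- plasmode_resample(base, n_sim)
    des <- .plasmode_design(res, config$center)
    treatment <- stats::rbinom(n_sim, 1, expit(config$alpha0 +
                                                 .plasmode_lp_treat(des, config)))
    p_y <- expit(config$lambda0 + config$tau * treatment +
                   .plasmode_lp_outcome(des, config))
    outcome <- stats::rbinom(n_sim, 1, p_y)
    if (length(unique(treatment)) == 2 && length(unique(outcome)) == 2) {
      return(tibble::tibble(
        row_id = seq_len(n_sim),
        cluster_id = factor(res$hospital_id),
        des,
        treatment = treatment,
        outcome = outcome
      ))
    }
  }
  stop("degenerate plasmode cohort after reseed")
}

#' True plasmode treatment effect on a requested scale
#'
#' The conditional log odds ratio is `tau` by construction.  Marginal
#' scales average both potential-outcome probabilities over the base
#' cohort's covariate rows (the population the resampling draws from).
#'
#' @param base base-cohort tibble.
#' @param config a [plasmode_config()].
#' @param scale effect scale.
#' @return scalar effect.
#' @export
plasmode_true_effect <- function(base, config,
                                 scale = c("conditional_logor",
                                           "marginal_logor",
                                           "risk_difference")) {
  scale <- match.arg(scale)
  if (scale == "conditional_logor") return(config$tau)
  config <- calibrate_plasmode(base, config)
  des <- .plasmode_design(base, config$center)
  lp_y0 <- config$lambda0 + .plasmode_lp_outcome(des, config)
  p1 <- mean(expit(lp_y0 + config$tau))
  p0 <- mean(expit(lp_y0))
  switch(scale,
    marginal_logor = stats::qlogis(p1) - stats::qlogis(p0),
    risk_difference = p1 - p0
  )
}

#' Covariate names of a plasmode cohort
#' @return character vector of the design-column names.
#' @export
plasmode_covariates <- function() {
  c("age_s", "sex", "charlson_s", "teaching", "large_hospital", "volume_s")
}
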