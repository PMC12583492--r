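test_that("synthetic base cohort has the canonical shape", {
  base <- generate_synthetic_base_cohort(seed = 4)
  expect_equal(nrow(base), 9981)
  expect_equal(nlevels(base$hospital_id), 341)
  expect_equal(mean(table(base$hospital_id)), 9981 / 341, tolerance = 1e-8)
  expect_true(all(base$age >= 18))
  expect_true(all(base$charlson >= 0))
  # hospital-level fields constant within hospital
  hos <- base |>
    dplyr::group_by(hospital_id) |>
    dplyr::summarise(dplyr::across(c(teaching, large_hospital, annual_volume),
                                   dplyr::n_distinct))
  expect_true(all(as.matrix(hos[-1]) == 1))
  # age-comorbidity association roughly as designed
  rho <- cor(base$age, base$charlson, method = "spearman")
  expect_gt(rho, 0.2)
  expect_lt(rho, 0.4)
  # volume positively associated with teaching status
  expect_gt(
    mean(base$annual_volume[base$teaching == 1]),
    mean(base$annual_volume[base$teaching == 0])
  )
  # forced one-patient-per-hospital allocation
  tiny <- generate_synthetic_base_cohort(341, 341, seed = 1)
  expect_true(all(table(tiny$hospital_id) == 1))
})

test_that("base cohorts round-trip through CSV with validation", {
  base <- generate_synthetic_base_cohort(400, 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_base_cohort(base, path)
  back <- read_base_cohort(path)
  expect_equal(nrow(back), 400)
  expect_equal(back$age, base$age, tolerance = 1e-8)
  bad <- base
  bad$teaching[1] <- 1 - bad$teaching[1]
  write_base_cohort(bad, path)
  expect_error(read_base_cohort(path), "hospital-level")
})

test_that("bootstrap resampling keeps rows jointly and covers ~63% of sources", {
  base <- generate_synthetic_base_cohort(500, 25, seed = 3)
  res <- plasmode_resample(base, seed = 1)
  expect_equal(nrow(res), 500)
  hos <- res |>
    dplyr::group_by(hospital_id) |>
    dplyr::summarise(dplyr::across(c(teaching, large_hospital, annual_volume),
                                   dplyr::n_distinct))
  expect_true(all(as.matrix(hos[-1]) == 1))
  # classical bootstrap coverage of distinct source rows
  frac <- vapply(1:60, function(i) {
    length(unique(attr(plasmode_resample(base, seed = i), "source_rows"))) / 500
  }, numeric(1))
  expect_equal(mean(frac), 1 - exp(-1), tolerance = 0.01)
  # single-row base: all copies identical
  one <- plasmode_resample(base[1, ], n_sim = 5, seed = 1)
  expect_equal(nrow(one), 5)
  expect_length(unique(one$age), 1)
})

test_that("plasmode simulation emits estimator-ready cohorts deterministically", {
  base <- generate_synthetic_base_cohort(1500, 50, seed = 5)
  cfg <- plasmode_config(gamma_z = 0.9163, n_reps = 2)
  sim <- plasmode_simulate(base, cfg, rep_seed = 11)
  expect_setequal(
    names(sim),
    c("row_id", "cluster_id", plasmode_covariates(), "treatment", "outcome")
  )
  expect_lte(nlevels(droplevels(sim$cluster_id)), 50)
  expect_setequal(unique(sim$treatment), c(0, 1))
  expect_setequal(unique(sim$outcome), c(0, 1))
  expect_identical(sim, plasmode_simulate(base, cfg, rep_seed = 11))
  # resampled covariate means stay near the base means (bootstrap SEs)
  for (v in c("teaching", "sex")) {
    p <- mean(base[[v]])
    expect_lt(abs(mean(sim[[v]]) - p), 3 * sqrt(p * (1 - p) / 1500) + 0.02)
  }
})

test_that("null plasmode models hit 50% event rates in both arms", {
  base <- generate_synthetic_base_cohort(2000, 60, seed = 6)
  cfg <- plasmode_config(
    gamma_z = 0, gamma_z_out = 0, tau = 0,
    exposure_coefs = rep(0, 3), outcome_coefs = rep(0, 3)
  )
  sim <- plasmode_simulate(base, cfg, rep_seed = 7)
  for (arm in 0:1) {
    rate <- mean(sim$outcome[sim$treatment == arm])
    n_arm <- sum(sim$treatment == arm)
    expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / n_arm))
  }
})

test_that("the estimator stack runs unchanged on plasmode cohorts", {
  base <- generate_synthetic_base_cohort(1200, 40, seed = 8)
  cfg <- plasmode_config(gamma_z = 0.4055)
  sim <- plasmode_simulate(base, cfg, rep_seed = 3)
  covs <- plasmode_covariates()
  ipw <- estimate_iptw(sim, covariates = covs)
  expect_true(ipw$converged)
  cf <- fit_causal_forest(sim, covariates = covs,
                          options = fast_forest(n_trees = 50))
  ate <- average_treatment_effect(cf)
  expect_true(is.finite(ate$estimate))
  expect_gt(ate$se, 0)
})
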