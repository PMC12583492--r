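#' Causal-forest tuning options
#'
#' Defaults follow the study configuration: 200 trees, half of each tree's
#' subsample used for determining splits (honesty fraction 0.5), subsample
#' fraction 0.5, minimum leaf size 5, unlimited depth.  `n_tree_groups`
#' records the grouped-variance tree-group size; it has no effect on point
#' estimates.
#'
#' @param n_trees number of trees.
#' @param subsample_fraction fraction of rows (or clusters) per tree.
#' @param honesty_fraction fraction of each subsample used for split
#'   determination; the rest populates leaf effects.
#' @param min_leaf_size minimum rows per child during splitting.
#' @param max_depth maximum tree depth, `Inf` for unlimited.
#' @param n_tree_groups tree-group size for grouped variance bookkeeping.
#' @param seed integer seed used for all forest randomness.
#' @return list of class `forest_options`.
#' @export
forest_options <- function(n_trees = 200L, subsample_fraction = 0.5,
                           honesty_fraction = 0.5, min_leaf_size = 5L,
                           max_depth = Inf, n_tree_groups = 50L,
                           seed = 1L) {
  stopifnot(
    n_trees >= 1, subsample_fraction > 0, subsample_fraction <= 1,
    honesty_fraction > 0, honesty_fraction < 1, min_leaf_size >= 1
  )
  structure(list(
    n_trees = as.integer(n_trees),
    subsample_fraction = subsample_fraction,
    honesty_fraction = honesty_fraction,
    min_leaf_size = as.integer(min_leaf_size),
    max_depth = if (is.finite(max_depth)) as.integer(max_depth) else -1L,
    n_tree_groups = as.integer(n_tree_groups),
    seed = as.integer(seed)
  ), class = "forest_options")
}

#' Default causal-forest covariate set
#'
#' All simulated covariates (patient- and cluster-level, including the
#' instrument and the risk factor): the forest is handed everything the
#' investigator would supply and left to sort out relevance.
#'
#' @return character vector of covariate names.
#' @export
default_forest_covariates <- function() c(paste0("x", 1:7), "z1", "z2")

#' Fit out-of-bag nuisance regression forests
#'
#' Two honest subsampled regression forests (same tree machinery and
#' tuning as the causal forest, with variance-reduction splitting on the
#' split half and estimate-half leaf means) predict treatment propensity
#' `e(x)` and the marginal outcome `y(x)` from the covariates.
#' Predictions are out-of-bag, so each row is predicted only by trees not
#' trained on it (the cross-fitting the doubly robust construction
#' requires).  Propensities are clipped to `[0.02, 0.98]`; the clip count
#' is reported.
#'
#' @param cohort cohort tibble.
#' @param covariates covariate names.
#' @param options a [forest_options()].
#' @param clusters optional cluster memberships; when given, nuisance
#'   trees subsample whole clusters (so out-of-bag predictions for a row
#'   come only from trees that excluded its entire cluster).
#' @return list with `e_hat`, `y_hat`, `n_clipped`.
#' @export
fit_nuisance_forests <- function(cohort,
                                 covariates = default_forest_covariates(),
                                 options = forest_options(),
                                 clusters = NULL) {
  X <- as.matrix(cohort[covariates])
  storage.mode(X) <- "double"
  n <- nrow(X)
  ones <- rep(1, n)
  treat <- as.integer(cohort$treatment)
  cl_idx <- if (!is.null(clusters)) as.integer(factor(clusters)) else integer(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  rf_oob <- function(y, seed_offset) {
    set.seed(derive_seed(options$seed, seed_offset))
    trees <- cpp_cf_fit(X, y, ones, treat, cl_idx, options$n_trees,
                        options$subsample_fraction, options$honesty_fraction,
                        options$min_leaf_size, options$max_depth,
                        regression = TRUE)
    cpp_cf_predict_oob(trees, X)
  }
  e_raw <- rf_oob(as.numeric(cohort$treatment), 1L)
  y_hat <- rf_oob(as.numeric(cohort$outcome), 2L)
  e_hat <- clip_probs(e_raw, 0.02, 0.98)
  list(e_hat = as.numeric(e_hat), y_hat = y_hat,
       n_clipped = attr(e_hat, "n_clipped"))
}

#' Fit an honest double-sample causal forest
#'
#' Outcome and treatment are orthogonalized against the covariates
#' (residuals `Y - y(x)`, `T - e(x)` from [fit_nuisance_forests()], or a
#' supplied external propensity in place of `e(x)`); each tree then draws
#' a subsample — whole clusters when `clusters` is given — splits it into
#' a split half and an estimate half, chooses axis-aligned splits on the
#' split half to maximize between-child heterogeneity of the
#' residual-on-residual effect, and fills leaf effects from the estimate
#' half only.  Ties between equal-gain splits break to the lowest
#' covariate index, then the lowest threshold; the fit is deterministic
#' under `options$seed`.
#'
#' Variant map: default arguments give the plain forest; `clusters =
#' cohort$cluster_id` gives the cluster-subsampled variant with
#' cluster-robust variance; `external_ps` (e.g. logistic-regression
#' propensities) gives the external-propensity variant.
#'
#' @param cohort cohort tibble with `treatment` and `outcome`.
#' @param covariates covariate names.
#' @param options a [forest_options()].
#' @param clusters optional factor of cluster memberships for
#'   cluster-level subsampling and cluster-robust variance.
#' @param external_ps optional external propensity vector in (0, 1) used
#'   in place of the internal forest propensity.
#' @param nuisances optionally a precomputed [fit_nuisance_forests()]
#'   result for this cohort (shared across variants on the same data).
#' @return object of class `causal_forest`.
#' @export
#' @examples
#' cohort <- simulate_cohort(scenario_config(10, 60, total_target = 600), 1)
#' cf <- fit_causal_forest(cohort, options = forest_options(n_trees = 50))
#' average_treatment_effect(cf)
fit_causal_forest <- function(cohort,
                              covariates = default_forest_covariates(),
                              options = forest_options(),
                              clusters = NULL,
                              external_ps = NULL,
                              nuisances = NULL) {
  stopifnot(all(covariates %in% names(cohort)),
            length(unique(cohort$treatment)) == 2)
  X <- as.matrix(cohort[covariates])
  storage.mode(X) <- "double"
  nuis <- nuisances %||%
    fit_nuisance_forests(cohort, covariates, options, clusters = clusters)
  if (!is.null(external_ps)) {
    stopifnot(length(external_ps) == nrow(cohort))
    e_hat <- as.numeric(clip_probs(external_ps, 0.02, 0.98))
    ps_source <- "external"
  } else {
    e_hat <- nuis$e_hat
    ps_source <- "internal"
  }
  y_hat <- nuis$y_hat
  yres <- as.numeric(cohort$outcome) - y_hat
  tres <- as.numeric(cohort$treatment) - e_hat
  cl_idx <- if (!is.null(clusters)) {
    as.integer(factor(clusters))
  } else {
    integer(0)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(options$seed)
  trees <- cpp_cf_fit(X, yres, tres, as.integer(cohort$treatment), cl_idx,
                      options$n_trees, options$subsample_fraction,
                      options$honesty_fraction, options$min_leaf_size,
                      options$max_depth, regression = FALSE)
  structure(list(
    trees = trees,
    X = X,
    covariates = covariates,
    y = as.numeric(cohort$outcome),
    t = as.numeric(cohort$treatment),
    e_hat = e_hat,
    y_hat = y_hat,
    ps_source = ps_source,
    clusters = if (length(cl_idx)) cl_idx else NULL,
    n_clipped_e = nuis$n_clipped,
    options = options
  ), class = "causal_forest")
}

#' @export
print.causal_forest <- function(x, ...) {
  cat(sprintf(
    "<causal_forest> %d trees, n=%d, p=%d, propensity=%s%s\n",
    length(x$trees), nrow(x$X), ncol(x$X), x$ps_source,
    if (!is.null(x$clusters)) ", cluster-subsampled" else ""
  ))
  invisible(x)
}

#' Predict conditional average treatment effects
#'
#' Forest-averaged leaf effects on the risk-difference scale.  For the
#' training rows (`newdata = NULL`) predictions are out-of-bag.
#'
#' @param model a [fit_causal_forest()] object.
#' @param newdata optional data frame with the training covariates.
#' @return numeric vector of CATE predictions.
#' @export
predict_cate <- function(model, newdata = NULL) {
  if (is.null(newdata)) {
    cpp_cf_predict_oob(model$trees, model$X)
  } else {
    Xn <- as.matrix(as.data.frame(newdata)[model$covariates])
    storage.mode(Xn) <- "double"
    cpp_cf_predict(model$trees, Xn)
  }
}

#' @export
predict.causal_forest <- function(object, newdata = NULL, ...) {
  predict_cate(object, newdata)
}

# influence-function variance; clusters=NULL gives the i.i.d. variance,
# otherwise scores are summed within clusters first
.score_se <- function(phi, clusters = NULL) {
  n <- length(phi)
  if (is.null(clusters)) {
    stats::sd(phi) / sqrt(n)
  } else {
    centered <- phi - mean(phi)
    cl_sum <- tapply(centered, clusters, sum)
    sqrt(sum(cl_sum^2)) / n
  }
}

#' Doubly robust (AIPW) average treatment effect
#'
#' Augmented inverse-probability weighting over supplied nuisances: with
#' `m1 = y_hat + (1 - e_hat) * tau_hat` and `m0 = y_hat - e_hat * tau_hat`,
#' the potential-outcome mean estimates are
#' `mu1 = mean(m1 + T (Y - m1) / e_hat)` and
#' `mu0 = mean(m0 + (1 - T)(Y - m0) / (1 - e_hat))`; the risk difference
#' is `mu1 - mu0` and the marginal log odds ratio is
#' `logit(mu1) - logit(mu0)` with a delta-method standard error.  Standard
#' errors come from the influence scores, summed within clusters when
#' `clusters` is supplied.
#'
#' @param y,t outcome and treatment vectors (0/1).
#' @param tau_hat per-row CATE estimates (risk-difference scale).
#' @param e_hat,y_hat propensity and marginal-outcome predictions.
#' @param clusters optional cluster memberships for cluster-robust SEs.
#' @param scale `"risk_difference"` (native) or `"marginal_logor"`.
#' @return one-row tibble: `estimate`, `se`, `ci_low`, `ci_high`, `mu1`,
#'   `mu0`, `converged`.
#' @export
aipw_ate <- function(y, t, tau_hat, e_hat, y_hat, clusters = NULL,
                     scale = c("risk_difference", "marginal_logor")) {
  scale <- match.arg(scale)
  m1 <- y_hat + (1 - e_hat) * tau_hat
  m0 <- y_hat - e_hat * tau_hat
  psi1 <- m1 + t * (y - m1) / e_hat
  psi0 <- m0 + (1 - t) * (y - m0) / (1 - e_hat)
  mu1 <- mean(psi1)
  mu0 <- mean(psi0)
  if (scale == "risk_difference") {
    phi <- psi1 - psi0
    est <- mu1 - mu0
    se <- .score_se(phi, clusters)
  } else {
    if (mu1 <= 0 || mu1 >= 1 || mu0 <= 0 || mu0 >= 1) {
      stop(sprintf(
        "AIPW potential-outcome means outside (0,1): mu1=%.4f mu0=%.4f",
        mu1, mu0
      ))
    }
    est <- stats::qlogis(mu1) - stats::qlogis(mu0)
    phi <- psi1 / (mu1 * (1 - mu1)) - psi0 / (mu0 * (1 - mu0))
    se <- .score_se(phi, clusters)
  }
  tibble::tibble(
    estimate = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    mu1 = mu1, mu0 = mu0, converged = TRUE
  )
}

#' Average treatment effect of a fitted causal forest
#'
#' Combines the forest's out-of-bag CATE predictions with its nuisance
#' predictions in the doubly robust AIPW estimator (see [aipw_ate()]).
#' The default reporting scale is the forest-native risk difference,
#' compared against the Monte Carlo risk-difference truth from
#' [true_effect()]; `"marginal_logor"` transforms the AIPW
#' potential-outcome means onto the log odds ratio scale instead.
#'
#' @param model a [fit_causal_forest()] object.
#' @param scale `"risk_difference"` or `"marginal_logor"`.
#' @param label estimator label recorded in the result.
#' @return one-row tibble: `estimator`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `converged` (plus `mu1`, `mu0`).
#' @export
average_treatment_effect <- function(model,
                                     scale = c("risk_difference",
                                               "marginal_logor"),
                                     label = "CF") {
  scale <- match.arg(scale)
  tau_hat <- predict_cate(model)
  out <- aipw_ate(model$y, model$t, tau_hat, model$e_hat, model$y_hat,
                  clusters = model$clusters, scale = scale)
  dplyr::bind_cols(tibble::tibble(estimator = label), out)
}

#' @method tidy causal_forest
#' @export
tidy.causal_forest <- function(x, scale = "risk_difference", ...) {
  res <- average_treatment_effect(x, scale = scale)
  tibble::tibble(
    term = paste0("ate_", scale), estimate = res$estimate,
    std.error = res$se, conf.low = res$ci_low, conf.high = res$ci_high
  )
}

#' @method glance causal_forest
#' @export
glance.causal_forest <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$X), n_trees = length(x$trees),
    subsample_fraction = x$options$subsample_fraction,
    honesty_fraction = x$options$honesty_fraction,
    min_leaf_size = x$options$min_leaf_size,
    ps_source = x$ps_source,
    clustered = !is.null(x$clusters),
    n_clipped_e = x$n_clipped_e
  )
}
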