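#' Default propensity-score covariate set
#'
#' The confounders only: the five patient-level confounders and the two
#' cluster-level confounders.  The instrument (`x7`) and the outcome-only
#' risk factor (`x6`) are deliberately excluded, and the cross-level
#' interaction `z1:x1` is not included by default (main-effects
#' specification), which is the model misspecification at work when the
#' cluster confounding is strong.
#'
#' @return character vector of covariate names.
#' @export
default_ps_covariates <- function() c(paste0("x", 1:5), "z1", "z2")

#' Fit a logistic propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment on the requested
#' covariates (main effects; optionally the `z1:x1` cross-level
#' interaction).  Fitted probabilities are clipped to `[0.001, 0.999]`
#' before any weighting to avoid infinite weights; the clip count is kept
#' on the object.
#'
#' @param cohort cohort tibble with a 0/1 `treatment` column.
#' @param covariates covariate names present in `cohort`.
#' @param include_interaction add the `z1:x1` interaction term (only
#'   meaningful for parametric-arm cohorts).
#' @return object of class `ps_model` with elements `fit`, `coefficients`,
#'   `covariates`, `fitted` (clipped probabilities), `converged`,
#'   `n_clipped`.
#' @export
#' @examples
#' cohort <- simulate_cohort(scenario_config(10, 50, total_target = 500), 1)
#' ps <- fit_propensity_logistic(cohort)
#' range(ps$fitted)
fit_propensity_logistic <- function(cohort,
                                    covariates = default_ps_covariates(),
                                    include_interaction = FALSE) {
  stopifnot(all(covariates %in% names(cohort)))
  rhs <- paste(covariates, collapse = " + ")
  if (include_interaction) rhs <- paste(rhs, "+ z1:x1")
  fml <- stats::as.formula(paste("treatment ~", rhs))
  fit <- stats::glm(fml, data = cohort, family = stats::binomial())
  p <- clip_probs(as.numeric(stats::fitted(fit)), 0.001, 0.999)
  structure(list(
    fit = fit,
    coefficients = stats::coef(fit),
    covariates = covariates,
    fitted = as.numeric(p),
    converged = isTRUE(fit$converged),
    n_clipped = attr(p, "n_clipped")
  ), class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat(sprintf("<ps_model> %d covariates, %d rows, converged=%s, clipped=%d\n",
              length(x$covariates), length(x$fitted), x$converged,
              x$n_clipped))
  invisible(x)
}

#' @method tidy ps_model
#' @export
tidy.ps_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @method glance ps_model
#' @export
glance.ps_model <- function(x, ...) {
  tibble::tibble(
    n = length(x$fitted), converged = x$converged, n_clipped = x$n_clipped,
    aic = stats::AIC(x$fit)
  )
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' `w_i = pbar / ps_i` for treated and `(1 - pbar) / (1 - ps_i)` for
#' untreated patients, where `pbar` is the marginal treated fraction.  The
#' sample mean of stabilized weights is 1 in expectation.
#'
#' @param ps propensity scores strictly inside (0, 1).
#' @param treatment 0/1 vector of the same length.
#' @return positive weight vector.
#' @export
#' @examples
#' stabilized_weights(c(0.25, 0.5), c(1, 0))
stabilized_weights <- function(ps, treatment) {
  stopifnot(length(ps) == length(treatment))
  if (any(ps <= 0 | ps >= 1)) stop("propensity scores must lie strictly in (0, 1)")
  pbar <- mean(treatment)
  ifelse(treatment == 1, pbar / ps, (1 - pbar) / (1 - ps))
}

# weighted random-intercept logit of outcome on treatment; the binomial
# family warns about non-integer successes because the stabilized weights
# enter as likelihood weights -- that is the intended weighting convention
.fit_weighted_glmm <- function(cohort, w) {
  d <- cohort
  d$.w <- w
  fit_with <- function(optimizer) {
    withCallingHandlers(
      lme4::glmer(outcome ~ treatment + (1 | cluster_id), data = d,
                  family = stats::binomial(), weights = .w,
                  control = lme4::glmerControl(optimizer = optimizer,
                                               calc.derivs = FALSE)),
      warning = function(w2) {
        if (grepl("non-integer", conditionMessage(w2))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  fit <- tryCatch(fit_with("bobyqa"), error = function(e) NULL,
                  warning = function(w2) NULL)
  optimizer <- "bobyqa"
  if (is.null(fit)) {
    fit <- tryCatch(fit_with("Nelder_Mead"), error = function(e) NULL,
                    warning = function(w2) NULL)
    optimizer <- "Nelder_Mead"
  }
  list(fit = fit, optimizer = optimizer)
}

#' Estimate the treatment effect by stabilized IPTW
#'
#' Fits the logistic propensity model, computes stabilized weights, and
#' regresses the outcome on treatment in a weighted logistic model with a
#' Gaussian random intercept per cluster (Laplace approximation; weights
#' enter as per-observation likelihood weights).  The point estimate is
#' the treatment coefficient on the log odds ratio scale with its model
#' (Wald) standard error and a 95% CI at `estimate +/- 1.96 se`.
#'
#' @param cohort cohort tibble with `cluster_id`, `treatment`, `outcome`.
#' @param covariates propensity-model covariates.
#' @param include_interaction include `z1:x1` in the propensity model.
#' @param ps_model optionally, a pre-fitted [fit_propensity_logistic()]
#'   object for this cohort (used to share one fit across estimators).
#' @return one-row tibble: `estimator`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `converged`, plus the optimizer used.
#' @export
estimate_iptw <- function(cohort, covariates = default_ps_covariates(),
                          include_interaction = FALSE, ps_model = NULL) {
  stopifnot(dplyr::n_distinct(cohort$cluster_id) >= 2)
  ps <- ps_model %||%
    fit_propensity_logistic(cohort, covariates, include_interaction)
  w <- stabilized_weights(ps$fitted, cohort$treatment)
  res <- .fit_weighted_glmm(cohort, w)
  if (is.null(res$fit) || !ps$converged) {
    return(tibble::tibble(
      estimator = "PS-IPTW", estimate = NA_real_, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, converged = FALSE,
      optimizer = res$optimizer
    ))
  }
  co <- summary(res$fit)$coefficients
  est <- co["treatment", "Estimate"]
  se <- co["treatment", "Std. Error"]
  tibble::tibble(
    estimator = "PS-IPTW", estimate = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    converged = TRUE, optimizer = res$optimizer
  )
}

#' Weighted standardized mean differences
#'
#' Balance diagnostic: absolute standardized mean difference of each
#' covariate between arms after weighting, with the pooled unweighted
#' standard deviation in the denominator.
#'
#' @param cohort cohort tibble.
#' @param covariates covariate names.
#' @param weights per-patient weights (default 1: unweighted SMD).
#' @return tibble with `covariate` and `smd`.
#' @export
weighted_smd <- function(cohort, covariates = default_ps_covariates(),
                         weights = rep(1, nrow(cohort))) {
  t1 <- cohort$treatment == 1
  purrr::map_dfr(covariates, function(v) {
    x <- cohort[[v]]
    m1 <- stats::weighted.mean(x[t1], weights[t1])
    m0 <- stats::weighted.mean(x[!t1], weights[!t1])
    s <- sqrt((stats::var(x[t1]) + stats::var(x[!t1])) / 2)
    tibble::tibble(covariate = v, smd = abs(m1 - m0) / s)
  })
}
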