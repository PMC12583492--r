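#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib clustercf, .registration = TRUE
NULL

#' Derive a per-cell random seed
#'
#' Deterministic counter scheme mapping (root seed, scenario index,
#' replication index) to a 32-bit seed, so any simulation cell can be
#' regenerated in isolation.  Stable across package versions.
#'
#' @param root_seed integer root seed for a whole run.
#' @param scenario integer scenario index (>= 0).
#' @param rep integer replication index (>= 0).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 3, 12)
derive_seed <- function(root_seed, scenario = 0L, rep = 0L) {
  root <- as.numeric(root_seed) %% 2147483647
  s <- (root * 48271 + as.numeric(scenario) * 65537 +
    as.numeric(rep) * 8191 + 1) %% 2147483629
  as.integer(s + 1)
}

expit <- stats::plogis

clip_probs <- function(p, lo, hi) {
  clipped <- sum(p < lo | p > hi)
  structure(pmin(pmax(p, lo), hi), n_clipped = clipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
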