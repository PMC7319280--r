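#' Model pool: shared kinetics plus subpopulation fold changes
#'
#' A pool is a set of network models that share the 22 kinetic parameters
#' and differ only in log10 fold-change modifiers on the six
#' noise-susceptible production parameters. Cluster weights record the
#' fraction of cells assigned to each subpopulation; an affine
#' observation model maps simulated total p53 to reporter intensity.
#'
#' @param shared A `p53_params` object (or named vector of the 22
#'   parameters).
#' @param delta Numeric matrix, one row per subpopulation, columns named
#'   (or ordered) as [p53_noise_susceptible()]; log10 fold changes.
#' @param weights Non-negative weights, one per subpopulation; normalized
#'   to sum to 1.
#' @param scale,offset Observation model (intensity = scale * p53_total +
#'   offset).
#' @return Object of class `p53_pool`.
#' @export
model_pool <- function(shared, delta, weights = NULL, scale = 1,
                       offset = 0) {
  shared <- as_p53_params(shared)
  ns <- p53_noise_susceptible()
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1)
  delta <- as.matrix(delta)
  if (ncol(delta) != 6L)
    stop("`delta` must have 6 columns (one per noise-susceptible parameter)")
  if (is.null(colnames(delta))) colnames(delta) <- ns
  if (!setequal(colnames(delta), ns))
    stop("`delta` columns must be the noise-susceptible parameters")
  delta <- delta[, ns, drop = FALSE]
  K <- nrow(delta)
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K || any(weights < 0) || sum(weights) <= 0)
    stop("`weights` must be K non-negative values with positive sum")
  weights <- weights / sum(weights)
  stopifnot(scale > 0, offset >= 0)
  structure(list(shared = shared, delta = delta, weights = weights,
                 scale = scale, offset = offset),
            class = "p53_pool")
}

as_model_pool <- function(x) {
  if (inherits(x, "p53_pool_fit")) return(x$pool)
  if (inherits(x, "p53_pool")) return(x)
  stop("expected a `p53_pool` or `p53_pool_fit` object")
}

#' Number of subpopulation-specific parameters in a pool
#'
#' Counts fold-change modifiers whose magnitude is at or above the zero
#' tolerance; the remaining candidates are regarded as unspecific. Before
#' regularization a pool with K subpopulations carries exactly K x 6
#' candidates.
#'
#' @param pool A `p53_pool` or `p53_pool_fit`.
#' @param zero_tol Magnitude below which a modifier counts as zero
#'   (log10), default 1e-3.
#' @return Integer count.
#' @export
count_specific <- function(pool, zero_tol = 1e-3) {
  pool <- as_model_pool(pool)
  sum(abs(pool$delta) >= zero_tol)
}

#' Parameters of one pool member
#'
#' @param pool A `p53_pool` or `p53_pool_fit`.
#' @param k Subpopulation index.
#' @return A `p53_params` object with the member's effective parameters.
#' @export
pool_member <- function(pool, k) {
  pool <- as_model_pool(pool)
  stopifnot(k >= 1, k <= nrow(pool$delta))
  apply_modifiers(pool$shared, pool$delta[k, ])
}

#' @export
print.p53_pool <- function(x, ...) {
  cat("p53 model pool:", nrow(x$delta), "subpopulation(s),",
      count_specific(x), "non-zero fold-change modifier(s) of",
      length(x$delta), "candidates\n")
  invisible(x)
}
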