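#' Canonical parameter names of the p53 network model
#'
#' The model exposes exactly 22 fitted, strictly positive rate constants.
#' Six of them scale production of mRNAs and proteins and are flagged
#' noise-susceptible: these are the candidates for subpopulation-specific
#' fold-change modifiers.
#'
#' @return Character vector of length 22 (canonical order).
#' @export
p53_param_names <- function() {
  c("beta_s", "alpha_s", "alpha_ws",
    "beta_p", "alpha_pi", "alpha_mpi", "beta_sp", "T_s",
    "alpha_wpa", "alpha_mpa",
    "beta_mt", "beta_pamt", "T_pa", "alpha_mt", "beta_mtm",
    "alpha_m", "alpha_sm",
    "beta_wt", "beta_pawt", "alpha_wt", "beta_wtw", "alpha_w")
}

#' Noise-susceptible production parameters
#'
#' Production of mRNAs and proteins is susceptible to intrinsic noise, so
#' the corresponding six rate constants (basal Mdm2/Wip1 transcription,
#' Mdm2/Wip1 translation, p53 synthesis, ATM activation) may differ
#' between subpopulations; all other, biochemical parameters are shared.
#'
#' @return Character vector of length 6.
#' @export
p53_noise_susceptible <- function() {
  c("beta_mt", "beta_mtm", "beta_p", "beta_s", "beta_wt", "beta_wtw")
}

#' Construct a validated model parameter set
#'
#' @param values Named numeric vector covering all 22 canonical names
#'   (see [p53_param_names()]); all values strictly positive.
#' @param hill Fixed (non-fitted) Hill exponent for p53-dependent
#'   transcription of Mdm2 and Wip1. Default 4.
#'
#' @return Named numeric vector of class `p53_params` with attribute
#'   `hill`.
#' @export
p53_params <- function(values, hill = 4) {
  nm <- p53_param_names()
  if (is.null(names(values)) || !all(nm %in% names(values)))
    stop("`values` must be named and cover all 22 canonical parameters; ",
         "missing: ", paste(setdiff(nm, names(values)), collapse = ", "))
  extra <- setdiff(names(values), nm)
  if (length(extra))
    stop("unknown parameter name(s): ", paste(extra, collapse = ", "))
  v <- as.numeric(values[nm])
  names(v) <- nm
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all 22 parameters must be finite and strictly positive")
  if (!is.numeric(hill) || length(hill) != 1L || hill <= 0)
    stop("`hill` must be a single positive number")
  structure(v, hill = hill, class = "p53_params")
}

#' Bundled reference parameter set
#'
#' A synthetic reference parameterization of the network, tuned so that a
#' persistent damage step elicits pulsatile p53 dynamics with
#' near-uniform pulse amplitude and an inter-peak interval of roughly
#' 5.5 h, matching the qualitative behaviour the framework assumes. It is
#' a fixture of this package, not an experimentally estimated set.
#'
#' @return A `p53_params` object.
#' @export
p53_reference_params <- function() {
  p53_params(.p53_reference_values)
}

#' Apply subpopulation fold-change modifiers to a parameter set
#'
#' Effective parameters are \eqn{\theta \cdot 10^{\Delta}} for the six
#' noise-susceptible parameters and unchanged otherwise.
#'
#' @param shared A `p53_params` object (shared kinetic parameters).
#' @param modifiers Named numeric vector of log10 fold changes; names
#'   must be a subset of [p53_noise_susceptible()].
#'
#' @return A `p53_params` object with modified values.
#' @export
apply_modifiers <- function(shared, modifiers) {
  shared <- as_p53_params(shared)
  if (length(modifiers) == 0L) return(shared)
  ns <- p53_noise_susceptible()
  if (is.null(names(modifiers)) || !all(names(modifiers) %in% ns))
    stop("modifiers allowed only on the noise-susceptible parameters: ",
         paste(ns, collapse = ", "))
  if (any(!is.finite(modifiers)))
    stop("modifiers must be finite log10 fold changes")
  v <- unclass(shared)
  v[names(modifiers)] <- v[names(modifiers)] * 10^as.numeric(modifiers)
  p53_params(v, hill = attr(shared, "hill"))
}

as_p53_params <- function(x) {
  if (inherits(x, "p53_params")) x else p53_params(x)
}

#' @export
print.p53_params <- function(x, ...) {
  cat("p53 network parameters (22 rate constants, Hill n =",
      attr(x, "hill"), ")\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))), ...)
  invisible(x)
}
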