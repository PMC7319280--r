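# Bundled synthetic reference values. Tuned (not experimentally estimated)
# so that a persistent damage step yields relaxation-type p53 pulses:
# 4 prominent maxima in 24 h (first at ~2.75 h, inter-peak interval
# ~5.75 h with CV ~4%), deep inter-pulse troughs, moderate amplitude
# dampening, and pulsatility that survives +/-30% single-parameter
# perturbations and subpopulation fold changes across the working range.
.p53_reference_values <- c(
  beta_s = 2.52788,
  alpha_s = 0.291595,
  alpha_ws = 10.3248,
  beta_p = 0.795025,
  alpha_pi = 0.0744709,
  alpha_mpi = 9.63396,
  beta_sp = 0.979162,
  T_s = 1.54087,
  alpha_wpa = 0.381528,
  alpha_mpa = 0.761461,
  beta_mt = 0.0142118,
  beta_pamt = 1.04199,
  T_pa = 1.1389,
  alpha_mt = 0.914542,
  beta_mtm = 4.04404,
  alpha_m = 0.428197,
  alpha_sm = 2.82672,
  beta_wt = 0.0180759,
  beta_pawt = 3.46811,
  alpha_wt = 3.51753,
  beta_wtw = 1.36519,
  alpha_w = 0.906087)

# Ten-subpopulation log10 fold-change fixture on the six noise-susceptible
# parameters (columns in the order of p53_noise_susceptible()). Values span
# the working fold-change band (-0.46 .. +0.65 log10); the beta_wt column is
# identically zero (unspecific); row 1 is the reference member. Rows were
# chosen by a maximin criterion on the dissimilarity between the members'
# normalized trajectories so the planted subpopulations are well separated.
.p53_delta_fixture <- matrix(c(
   0.000,  0.000,  0.000,  0.000, 0,  0.000,
   0.369, -0.254,  0.138, -0.460, 0,  0.000,
  -0.460,  0.307,  0.650,  0.449, 0,  0.650,
  -0.120,  0.494,  0.428,  0.180, 0,  0.643,
   0.650,  0.145,  0.650,  0.650, 0, -0.357,
  -0.320,  0.111,  0.448, -0.151, 0,  0.370,
   0.158, -0.378, -0.307,  0.258, 0,  0.510,
  -0.130,  0.459,  0.585,  0.247, 0,  0.650,
   0.313,  0.260,  0.067,  0.485, 0,  0.646,
  -0.080,  0.306,  0.521, -0.383, 0,  0.398),
  nrow = 10, byrow = TRUE)

#' Demonstration model pool with ten planted subpopulations
#'
#' A synthetic ten-member pool built from the bundled reference parameters
#' ([p53_reference_params()]) and a fixed matrix of subpopulation log10
#' fold changes on the six noise-susceptible parameters. The fold changes
#' span the working band of roughly -0.46 to +0.65 log10, the basal Wip1
#' transcription column is identically zero (an unspecific parameter), and
#' the rows are well separated in trajectory shape. Used throughout as the
#' planted ground truth for recovery experiments.
#'
#' @param k Number of subpopulations to keep (first `k` rows) or, when a
#'   vector, the member indices to keep (each in 1..10).
#' @param scale,offset Observation model mapping total p53 to reporter
#'   intensity (a.u.).
#' @return A [model_pool()] with equal weights.
#' @export
p53_demo_pool <- function(k = 10, scale = 100, offset = 0) {
  idx <- if (length(k) == 1L) seq_len(k) else as.integer(k)
  stopifnot(all(idx >= 1), all(idx <= 10), !anyDuplicated(idx))
  k <- length(idx)
  delta <- .p53_delta_fixture[idx, , drop = FALSE]
  colnames(delta) <- p53_noise_susceptible()
  model_pool(p53_reference_params(), delta, weights = rep(1 / k, k),
             scale = scale, offset = offset)
}

#' Three-subpopulation pool for parameter-recovery experiments
#'
#' A compact planted pool used to probe calibration and L1 support
#' recovery: the reference member plus two members that each carry two
#' strong fold changes (magnitudes 0.35-0.4 log10) on disjoint
#' parameters, so exactly 4 of the 18 candidate modifiers are truly
#' non-zero and the planted pattern is not compressible into the shared
#' parameters (the all-zero first row pins any column-wise shift).
#'
#' @param scale,offset Observation model.
#' @return A [model_pool()] with equal weights.
#' @export
p53_recovery_pool <- function(scale = 100, offset = 0) {
  delta <- matrix(c(
    0.00, 0.00, 0.0,  0.00, 0,  0.00,
    0.00, 0.00, 0.4, -0.35, 0,  0.00,
    0.00, 0.40, 0.0,  0.00, 0, -0.35),
    nrow = 3, byrow = TRUE)
  colnames(delta) <- p53_noise_susceptible()
  model_pool(p53_reference_params(), delta, weights = rep(1 / 3, 3),
             scale = scale, offset = offset)
}
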