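#' Synthetic single-cell dataset configuration
#'
#' Bundles everything the generator needs: the generating pool, cell
#' numbers, sampling scheme, cell-level parameter jitter, measurement
#' noise and an optional planted perturbation. The defaults emulate the
#' live-cell imaging design the pipeline assumes: imaging every 15 min
#' for 24 h starting 30 min after irradiation, lognormal cell-to-cell
#' variability on the six noise-susceptible production parameters, and
#' multiplicative gaussian measurement noise.
#'
#' @param pool Generating [model_pool()] (default [p53_demo_pool()]).
#' @param n_cells Number of cells.
#' @param t_start First observation time (h post irradiation).
#' @param interval Sampling interval (h), default 0.25 (15 min).
#' @param duration Observation span (h), default 24.
#' @param jitter_sd Cell-level lognormal jitter SD (log10) on the six
#'   noise-susceptible parameters, default 0.1.
#' @param noise_cv Multiplicative gaussian measurement noise CV,
#'   default 0.05.
#' @param perturbation Planted [perturbation_spec()] or `NULL`.
#' @param balanced Draw subpopulations in (nearly) equal numbers rather
#'   than multinomially by weight.
#' @param seed RNG seed; recorded in every output.
#' @return Object of class `p53_gen_config`.
#' @export
generator_config <- function(pool = p53_demo_pool(), n_cells = 200,
                             t_start = 0.5, interval = 0.25,
                             duration = 24, jitter_sd = 0.1,
                             noise_cv = 0.05, perturbation = NULL,
                             balanced = TRUE, seed = 1) {
  stopifnot(interval > 0, jitter_sd >= 0, noise_cv >= 0, n_cells >= 1)
  structure(list(pool = as_model_pool(pool), n_cells = n_cells,
                 t_start = t_start, interval = interval,
                 duration = duration, jitter_sd = jitter_sd,
                 noise_cv = noise_cv, perturbation = perturbation,
                 balanced = balanced, seed = seed),
            class = "p53_gen_config")
}

#' Generate synthetic calibration-condition cells
#'
#' Per cell: draw a subpopulation (by weight), jitter the six
#' noise-susceptible parameters lognormally around the subpopulation
#' values, simulate, sample the reporter observable on the observation
#' grid and apply multiplicative gaussian noise. Cells whose jittered
#' parameters fail to produce finite dynamics are resampled (up to 10
#' attempts each, counted in the ground truth). Fully reproducible from
#' the seed.
#'
#' @param config A [generator_config()]; its `perturbation` must be
#'   `NULL` for the calibration condition.
#' @return List with `trajectories` (long data frame) and
#'   `ground_truth` (list: per-cell subpopulation and realized
#'   parameters, the seed, resample count, planted perturbation).
#' @export
generate_calibration_cells <- function(config) {
  stopifnot(inherits(config, "p53_gen_config"))
  if (!is.null(config$perturbation) && nrow(config$perturbation))
    stop("calibration condition must not carry a planted perturbation")
  generate_cells(config)
}

#' Generate synthetic perturbation-condition cells
#'
#' As [generate_calibration_cells()], with the planted perturbation
#' fold-changes applied from their onset times (presets used in the
#' validation design: onset -1 h for pre-treatment and 1.5, 2.5, 3 or
#' 5 h post irradiation).
#'
#' @param config A [generator_config()] with a non-empty
#'   `perturbation`.
#' @return As [generate_calibration_cells()].
#' @export
generate_perturbed_cells <- function(config) {
  stopifnot(inherits(config, "p53_gen_config"))
  if (is.null(config$perturbation) || !nrow(config$perturbation))
    stop("perturbation condition requires a planted perturbation")
  generate_cells(config)
}

generate_cells <- function(config) {
  pool <- config$pool
  K <- nrow(pool$delta)
  n <- config$n_cells
  set.seed(config$seed)
  sub <- if (config$balanced)
    sample(rep(seq_len(K), length.out = n))
  else sample.int(K, n, replace = TRUE, prob = pool$weights)
  times <- seq(config$t_start, config$duration, by = config$interval)
  ns <- p53_noise_susceptible()
  rows <- vector("list", n)
  params_realized <- vector("list", n)
  resampled <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in 1:10) {
      jit <- stats::rnorm(6, 0, config$jitter_sd)
      names(jit) <- ns
      pars <- tryCatch(
        apply_modifiers(pool_member(pool, sub[i]), jit),
        error = function(e) NULL)
      sim <- if (is.null(pars)) NULL else tryCatch(
        p53_simulate(pars, perturbation = config$perturbation,
                     times = times),
        error = function(e) NULL)
      if (!is.null(sim)) {
        y <- pool$scale * sim$observables$p53_total + pool$offset
        y <- y * (1 + stats::rnorm(length(y), 0, config$noise_cv))
        rows[[i]] <- data.frame(
          cell_id = sprintf("cell_%03d", i), time_h = times,
          intensity = y)
        params_realized[[i]] <- pars
        ok <- TRUE
        break
      }
      resampled <- resampled + 1L
    }
    if (!ok) stop("cell ", i, ": no finite dynamics after 10 attempts")
  }
  list(trajectories = do.call(rbind, rows),
       ground_truth = list(
         subpopulation = stats::setNames(sub, sprintf("cell_%03d",
                                                      seq_len(n))),
         parameters = params_realized,
         perturbation = config$perturbation,
         seed = config$seed, resampled = resampled))
}

#' Normalized population-level readout table
#'
#' Weighted-mean observables of the pool at the requested time points,
#' normalized to the value at the first time point (the sample
#' harvested at irradiation), with optional gaussian replicate noise --
#' the layout of population-level immunoblot / qRT-PCR time courses.
#'
#' @param pool A [model_pool()].
#' @param time_points Sampling times (h); the first is the
#'   normalization reference.
#' @param perturbation Optional [perturbation_spec()].
#' @param replicate_cv Gaussian replicate noise CV (0 = none).
#' @param seed Seed used when `replicate_cv > 0`.
#' @param normalize Observable columns to normalize to the reference
#'   time point. The ATM-P proxy is excluded by default: the pre-damage
#'   model state has exactly zero active ATM, so its reference value
#'   cannot serve as a denominator and the column is reported raw.
#' @return Data frame: `time_h` plus one column per observable
#'   (normalized where requested).
#' @export
generate_population_readout_data <- function(pool, time_points =
                                             c(0, 1, 2.5, 5, 7.5, 10),
                                             perturbation = NULL,
                                             replicate_cv = 0,
                                             seed = 1,
                                             normalize = c("p53_total",
                                               "mdm2_mrna", "mdm2",
                                               "wip1_mrna", "wip1")) {
  grid <- sort(unique(c(time_points, seq(0, max(time_points),
                                         by = 0.25))))
  ro <- population_readouts(as_model_pool(pool), perturbation,
                            times = grid)
  idx <- match(time_points, ro$time_h)
  out <- ro[idx, , drop = FALSE]
  if (replicate_cv > 0) set.seed(seed)
  for (cn in setdiff(names(out), "time_h")) {
    if (cn %in% normalize) {
      ref <- out[[cn]][1]
      if (ref == 0) stop("zero value at the normalization time point for ",
                         cn)
      out[[cn]] <- out[[cn]] / ref
    }
    if (replicate_cv > 0)
      out[[cn]] <- out[[cn]] *
        (1 + stats::rnorm(nrow(out), 0, replicate_cv))
  }
  rownames(out) <- NULL
  out
}
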