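#' Read a long-format trajectory table
#'
#' @param path CSV file with header `cell_id,time_h,intensity`.
#' @return Validated trajectory data frame, sorted by cell and time.
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_h", "intensity")
  if (!all(need %in% names(d)))
    stop("expected columns cell_id, time_h, intensity in ", path)
  d <- d[order(d$cell_id, d$time_h), need]
  rownames(d) <- NULL
  validate_trajectories(d)
}

#' Write a trajectory table
#'
#' @param data Long trajectory data frame.
#' @param path Output CSV path.
#' @export
write_trajectories <- function(data, path) {
  utils::write.csv(validate_trajectories(data), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a model pool to JSON
#'
#' @param pool A `p53_pool` or `p53_pool_fit`.
#' @param path Output path.
#' @export
write_pool <- function(pool, path) {
  pool <- as_model_pool(pool)
  obj <- list(shared = as.list(stats::setNames(as.numeric(pool$shared),
                                names(unclass(pool$shared)))),
              hill = attr(pool$shared, "hill"),
              delta = unname(apply(pool$delta, 1, as.list)),
              delta_parameters = colnames(pool$delta),
              weights = pool$weights,
              scale = pool$scale, offset = pool$offset)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model pool from JSON
#'
#' @param path JSON file written by [write_pool()].
#' @return A `p53_pool`.
#' @export
read_pool <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  delta <- as.matrix(obj$delta)
  colnames(delta) <- obj$delta_parameters
  model_pool(p53_params(unlist(obj$shared), hill = obj$hill), delta,
             weights = obj$weights, scale = obj$scale,
             offset = obj$offset)
}

#' Run the subpopulation-modeling pipeline
#'
#' Convenience driver tying the stages together on a synthetic dataset:
#' generate calibration cells, extract features, select the number of
#' subpopulations, compute peak-based means, calibrate the pool, and
#' optionally screen a set of parameter combinations against a
#' perturbation dataset. Intended for demonstration and smoke testing;
#' each stage is also exported on its own.
#'
#' @param config A [generator_config()] for the calibration condition.
#' @param k_range Cluster-count search range.
#' @param calibrate Whether to run the (slower) pool calibration.
#' @param n_starts,maxit Calibration effort.
#' @param out_dir Optional directory: writes trajectories, features,
#'   cluster assignments and the fitted pool there.
#' @return List with the stage results (`data`, `features`,
#'   `selection`, `peak_means`, and optionally `fit`).
#' @export
run_pipeline <- function(config = generator_config(n_cells = 60,
                                                   pool = p53_demo_pool(3)),
                         k_range = 2:6, calibrate = FALSE,
                         n_starts = 1, maxit = 30, out_dir = NULL) {
  data <- generate_calibration_cells(config)
  feats <- trajectory_features(data$trajectories)
  sel <- select_cluster_count(data$trajectories, k_range)
  pms <- cluster_peak_means(data$trajectories, sel$clusters)
  out <- list(data = data, features = feats, selection = sel,
              peak_means = pms, seed = config$seed)
  if (calibrate)
    out$fit <- fit_pool(pms, scale = config$pool$scale,
                        offset = config$pool$offset,
                        n_starts = n_starts, maxit = maxit,
                        seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectories(data$trajectories,
                       file.path(out_dir, "trajectories.csv"))
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(cell_id = names(sel$clusters$labels),
                 cluster = sel$clusters$labels),
      file.path(out_dir, "clusters.csv"), row.names = FALSE)
    if (!is.null(out$fit))
      write_pool(out$fit, file.path(out_dir, "pool.json"))
    jsonlite::write_json(list(seed = config$seed,
                              n_cells = config$n_cells,
                              jitter_sd = config$jitter_sd,
                              noise_cv = config$noise_cv,
                              k_selected = sel$k),
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Export screening report tables
#'
#' @param condensed Condensed sensitivity table
#'   ([condense_sensitivity()]).
#' @param ranking Ranked combination table ([rank_combinations()]).
#' @param out_dir Output directory.
#' @return Paths of the written files.
#' @export
export_report <- function(condensed = NULL, ranking = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(condensed)) {
    p <- file.path(out_dir, "sensitivity_condensed.csv")
    utils::write.csv(condensed, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(ranking)) {
    p <- file.path(out_dir, "combination_ranking.csv")
    utils::write.csv(ranking, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}
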