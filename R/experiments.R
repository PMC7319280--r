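#' Match pool members to calibration clusters
#'
#' Clustering labels subpopulations in an arbitrary order; this utility
#' finds the bijective matching between the members of a pool and a set
#' of peak-based means by greedily pairing the (member, cluster)
#' combinations with the smallest calibration residual.
#'
#' @param pool A `p53_pool`.
#' @param peak_means List of `p53_peak_mean` (one per cluster).
#' @param ... Residual settings passed to [pool_residuals()].
#' @return Integer vector `perm` with `perm[m]` = cluster index matched
#'   to member m.
#' @export
match_pool_to_clusters <- function(pool, peak_means, ...) {
  pool <- as_model_pool(pool)
  K <- nrow(pool$delta)
  stopifnot(length(peak_means) == K)
  cost <- matrix(NA_real_, K, K)
  for (m in seq_len(K)) {
    sub <- model_pool(pool$shared, pool$delta[m, , drop = FALSE], 1,
                      scale = pool$scale, offset = pool$offset)
    for (k in seq_len(K))
      cost[m, k] <- sum(pool_residuals(sub, peak_means[k], ...)^2)
  }
  perm <- integer(K)
  cc <- cost
  for (i in seq_len(K)) {
    ix <- which(cc == min(cc), arr.ind = TRUE)[1, ]
    perm[ix[1]] <- ix[2]
    cc[ix[1], ] <- Inf
    cc[, ix[2]] <- Inf
  }
  perm
}

#' Cluster-number recovery experiment
#'
#' Generates a low-noise synthetic calibration dataset from a planted
#' pool and reports the Calinski-Harabasz-selected number of
#' subpopulations together with the label agreement at the planted K.
#'
#' @param seed RNG seed.
#' @param pool Generating pool (default the ten-member demo pool).
#' @param n_cells Number of cells (default 200, i.e. 20 per planted
#'   subpopulation).
#' @param jitter_sd,noise_cv Generator noise (low-noise preset by
#'   default: cell-level jitter 0.01 log10, measurement noise CV 5%).
#' @param k_range Search range for the cluster count.
#' @return List with `k_selected`, `accuracy` (majority-label agreement
#'   at the planted K) and the CH score table.
#' @export
experiment_cluster_recovery <- function(seed, pool = p53_demo_pool(),
                                        n_cells = 200,
                                        jitter_sd = 0.01,
                                        noise_cv = 0.05,
                                        k_range = 2:15) {
  gen <- generate_calibration_cells(generator_config(
    pool = pool, n_cells = n_cells, jitter_sd = jitter_sd,
    noise_cv = noise_cv, seed = seed))
  sel <- select_cluster_count(gen$trajectories, k_range)
  ktrue <- nrow(as_model_pool(pool)$delta)
  lab <- stats::cutree(sel$clusters$tree, ktrue)
  truth <- gen$ground_truth$subpopulation[names(lab)]
  acc <- sum(apply(table(lab, truth), 1, max)) / length(lab)
  list(k_selected = sel$k, accuracy = acc, ch = sel$ch)
}

#' Pool-calibration recovery experiment
#'
#' Builds noiseless peak-based-mean targets by simulating every member
#' of a planted pool, then refits the pool from the bundled reference
#' start and reports how many shared parameters are recovered within a
#' log10 tolerance, together with the recovered modifier support from
#' the L1 path.
#'
#' @param seed RNG seed (start design).
#' @param pool Planted pool (default [p53_recovery_pool()]).
#' @param tol Log10 recovery tolerance per shared parameter (0.15).
#' @param lambda_grid Penalty grid for the support analysis.
#' @param n_starts,maxit Calibration effort.
#' @param zero_tol Support threshold (log10).
#' @return List with `n_theta_recovered`, `theta_error` (named log10
#'   errors, unpenalized fit), `support_true`, `support_recovered`,
#'   `support_extra`, and the two fits.
#' @export
experiment_pool_recovery <- function(seed, pool = p53_recovery_pool(),
                                     tol = 0.15,
                                     lambda_grid = c(0, 0.1, 0.3),
                                     n_starts = 2, maxit = 80,
                                     zero_tol = 1e-3) {
  pool <- as_model_pool(pool)
  K <- nrow(pool$delta)
  grid <- seq(0.5, 24, by = 0.25)
  targets <- lapply(seq_len(K), function(k) {
    tr <- observe_p53(p53_simulate(pool_member(pool, k), times = grid),
                      scale = pool$scale, offset = pool$offset,
                      cell_id = paste0("member_", k))
    peak_based_mean(tr)
  })
  sel <- l1_path_select(targets, lambda_grid = lambda_grid,
                        n_starts = n_starts, maxit = maxit, seed = seed,
                        scale = pool$scale, offset = pool$offset)
  fit0 <- sel$fits[[1]]
  err <- log10(as.numeric(fit0$pool$shared)) -
    log10(as.numeric(pool$shared))
  names(err) <- p53_param_names()
  supp_true <- abs(pool$delta) >= zero_tol
  supp_fit <- abs(sel$fit$pool$delta) >= zero_tol
  list(n_theta_recovered = sum(abs(err) <= tol),
       theta_error = err,
       support_true = sum(supp_true),
       support_recovered = sum(supp_fit & supp_true),
       support_extra = sum(supp_fit & !supp_true),
       fit_unpenalized = fit0, selection = sel)
}

#' Closed-loop crosstalk inference experiment
#'
#' The full inference loop on synthetic ground truth: generate
#' calibration cells from a planted pool, cluster them and compute
#' peak-based means; generate perturbation cells with a planted
#' fold-change combination, assign them to the calibration clusters and
#' compute perturbation peak-based means; then fit the planted
#' combination and a set of decoy combinations and rank them by
#' weighted chi-square. Clusters that receive no perturbation cells
#' keep their calibration mean with zero weight.
#'
#' @param seed RNG seed (generation, decoy draw, fits).
#' @param pool Planted pool (default the three-member demo pool).
#' @param true_set Planted parameter combination.
#' @param true_pi Planted log10 fold changes.
#' @param n_cells Cells per condition arm.
#' @param n_decoy_pairs,n_decoy_triplets Size of the decoy panel. The
#'   panel is a fixed, deterministic stratified draw (independent of
#'   `seed`): the screened subset is part of the experimental design,
#'   while the seed varies the synthetic data.
#' @param jitter_sd,noise_cv Generator noise.
#' @param t_inh Perturbation onset (h).
#' @param n_starts,maxit Combination-fit effort.
#' @return List with `rank_true` (rank of the planted combination),
#'   `pi_fitted`, `pi_error`, `chi2_true`, `chi2_best_decoy`, `ranking`
#'   (full table) and the target peak means.
#' @export
crosstalk_closed_loop <- function(seed,
                                  pool = p53_demo_pool(c(5, 7, 10)),
                                  true_set = c("alpha_mpi", "alpha_m",
                                               "beta_sp"),
                                  true_pi = c(0.3, 0.3, -0.3),
                                  n_cells = 150, n_decoy_pairs = 24,
                                  n_decoy_triplets = 5,
                                  jitter_sd = 0.01, noise_cv = 0.02,
                                  t_inh = -1, n_starts = 2,
                                  maxit = 35) {
  pool <- as_model_pool(pool)
  K <- nrow(pool$delta)
  pert <- perturbation_spec(true_set, true_pi, t_inh)

  gc <- generate_calibration_cells(generator_config(
    pool = pool, n_cells = n_cells, jitter_sd = jitter_sd,
    noise_cv = noise_cv, seed = seed))
  cl <- hierarchical_cluster(pairwise_dissimilarity(gc$trajectories), K)
  cal_pm <- cluster_peak_means(gc$trajectories, cl)
  perm <- match_pool_to_clusters(pool, cal_pm)
  cal_pm <- cal_pm[perm]

  gp <- generate_perturbed_cells(generator_config(
    pool = pool, n_cells = n_cells, jitter_sd = jitter_sd,
    noise_cv = noise_cv, seed = seed + 1000L, perturbation = pert))
  asg <- assign_to_clusters(gp$trajectories, cal_pm)
  weights <- numeric(K)
  pm <- vector("list", K)
  for (k in seq_len(K)) {
    ids <- names(asg$labels)[!is.na(asg$labels) & asg$labels == k]
    if (length(ids)) {
      pm[[k]] <- peak_based_mean(
        gp$trajectories[gp$trajectories$cell_id %in% ids, , drop = FALSE])
      weights[k] <- length(ids)
    } else {
      pm[[k]] <- cal_pm[[k]]
      weights[k] <- 0
    }
  }

  set.seed(20201L)   # fixed decoy panel: design, not data
  prs <- enumerate_combinations(size = 2)
  dp <- prs[sample(nrow(prs), n_decoy_pairs), , drop = FALSE]
  dt <- replicate(n_decoy_triplets, sample(p53_param_names(), 3),
                  simplify = FALSE)
  set.seed(seed)
  cands <- c(list(true_set),
             lapply(seq_len(nrow(dp)), function(i) c(dp$p1[i], dp$p2[i])),
             dt)
  fits <- lapply(cands, function(ps)
    fit_combination(pool, ps, pm, t_inh = t_inh, weights = weights,
                    n_starts = n_starts, maxit = maxit, seed = seed))
  chi2 <- vapply(fits, function(f) f$chi2, numeric(1))
  list(rank_true = rank(chi2, ties.method = "min")[1],
       pi_fitted = fits[[1]]$pi,
       pi_error = max(abs(fits[[1]]$pi - true_pi)),
       chi2_true = chi2[1],
       chi2_best_decoy = min(chi2[-1]),
       ranking = rank_combinations(fits, top = length(fits)),
       fits = fits, targets = pm, weights = weights,
       calibration = cal_pm)
}

#' Perturbation-phenotype experiment
#'
#' Generates matched calibration and perturbation arms and tests the
#' qualitative feature signature of the planted perturbation (later
#' maxima and minima, longer inter-peak intervals, larger dampening
#' factors) with Wilcoxon rank-sum tests and Holm correction.
#'
#' @param seed RNG seed (the perturbation arm uses `seed + 1`).
#' @param pool Generating pool.
#' @param true_set,true_pi,t_inh Planted perturbation.
#' @param n_cells Cells per arm.
#' @param jitter_sd,noise_cv Generator noise.
#' @return The [compare_features()] table (group A = calibration,
#'   group B = perturbation).
#' @export
experiment_phenotype <- function(seed, pool = p53_demo_pool(),
                                 true_set = c("alpha_mpi", "alpha_m",
                                              "beta_sp"),
                                 true_pi = c(0.3, 0.3, -0.3),
                                 t_inh = -1, n_cells = 200,
                                 jitter_sd = 0.01, noise_cv = 0.05) {
  ga <- generate_calibration_cells(generator_config(
    pool = pool, n_cells = n_cells, jitter_sd = jitter_sd,
    noise_cv = noise_cv, seed = seed))
  gb <- generate_perturbed_cells(generator_config(
    pool = pool, n_cells = n_cells, jitter_sd = jitter_sd,
    noise_cv = noise_cv, seed = seed + 1L,
    perturbation = perturbation_spec(true_set, true_pi, t_inh)))
  compare_features(trajectory_features(ga$trajectories),
                   trajectory_features(gb$trajectories))
}
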