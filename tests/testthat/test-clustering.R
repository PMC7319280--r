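test_that("trajectory dissimilarity is a normalized Euclidean metric", {
  t <- 0:2
  d <- rbind(make_traj(c(0, 1, 0), t, "a"), make_traj(c(1, 0, 1), t, "b"))
  D <- suppressWarnings(pairwise_dissimilarity(d, sigma = 0.5))
  expect_equal(D["a", "b"], sqrt(3))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), c(0, 0))
  # identical trajectories are at distance zero
  d2 <- rbind(make_traj(c(0, 2, 1), t, "a"), make_traj(c(0, 2, 1), t, "b"))
  D2 <- suppressWarnings(pairwise_dissimilarity(d2, sigma = 0.5))
  expect_equal(D2["a", "b"], 0)
})

test_that("hierarchical clustering recovers planted 1-D groups", {
  x <- c(a = 0, b = 0.1, c = 10, d = 10.1)
  D <- as.matrix(dist(x))
  cl <- hierarchical_cluster(D, 2)
  expect_identical(unname(cl$labels[c("a", "b")]),
                   rep(cl$labels[["a"]], 2))
  expect_identical(unname(cl$labels[c("c", "d")]),
                   rep(cl$labels[["c"]], 2))
  expect_equal(cl$weights, c(0.5, 0.5))
  # K = N - 1 merges exactly the minimum-distance pair
  cl3 <- hierarchical_cluster(as.matrix(dist(c(a = 0, b = 1, c = 1.2,
                                               d = 5))), 3)
  expect_identical(cl3$labels[["b"]], cl3$labels[["c"]])
  expect_identical(length(unique(cl3$labels)), 3L)
  # duplicated cell always co-clusters with its twin
  cl4 <- hierarchical_cluster(as.matrix(dist(c(a = 0, a2 = 0, b = 3,
                                               c = 9))), 3)
  expect_identical(cl4$labels[["a"]], cl4$labels[["a2"]])
  expect_error(hierarchical_cluster(D, 4), "k")
})

test_that("Calinski-Harabasz index matches hand computation", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(calinski_harabasz(x, lab), 200)  # B=100, W=1
  expect_equal(calinski_harabasz(x, lab),
               oracle_ch_1d(as.numeric(x), lab))
  # coincident centroids give index zero
  x2 <- matrix(c(-1, 1, -1, 1), ncol = 1)
  expect_equal(calinski_harabasz(x2, c(1, 1, 2, 2)), 0)
  expect_error(calinski_harabasz(matrix(c(1, 1, 2, 2), ncol = 1),
                                 c(1, 1, 2, 2)), "degenerate")
  # planted labels beat random labels on separated data
  set.seed(2)
  x3 <- matrix(c(rnorm(20, 0, .2), rnorm(20, 8, .2)), ncol = 1)
  planted <- rep(1:2, each = 20)
  expect_gt(calinski_harabasz(x3, planted),
            calinski_harabasz(x3, sample(planted)))
})

test_that("cluster-count selection finds planted waveform groups", {
  t <- seq(0, 24, by = 0.25)
  set.seed(42)
  rows <- list()
  shapes <- list(function(t) sin(2 * pi * t / 5.5),
                 function(t) sin(2 * pi * t / 9) + 0.3 * t / 24,
                 function(t) exp(-((t - 12) / 4)^2))
  for (g in 1:3) for (i in 1:8) {
    y <- shapes[[g]](t) + rnorm(length(t), 0, 0.03) + 2
    rows[[length(rows) + 1]] <- make_traj(y, t, sprintf("g%d_%d", g, i))
  }
  data <- do.call(rbind, rows)
  sel <- select_cluster_count(data, 2:8)
  expect_identical(sel$k, 3L)
  truth <- rep(1:3, each = 8)
  tab <- table(sel$clusters$labels, truth)
  expect_equal(sum(apply(tab, 1, max)) / 24, 1)
  # a single candidate K is returned as-is
  expect_identical(select_cluster_count(data, 2)$k, 2L)
  expect_error(select_cluster_count(data, integer(0)), "k_range")
})

test_that("peak-based mean averages extrema peak-wise", {
  sim <- p53_simulate(p53_reference_params())
  tr <- observe_p53(sim, scale = 100, cell_id = "c1")
  pm1 <- peak_based_mean(tr)
  ext <- detect_extrema(smooth_trajectories(tr$intensity, 0.5, tr$time_h),
                        tr$time_h)
  mx <- ext[ext$kind == "max", ]
  expect_equal(pm1$peaks$t_max, mx$time[seq_len(nrow(pm1$peaks))])
  expect_equal(pm1$peaks$f_max, mx$value[seq_len(nrow(pm1$peaks))])
  # two shifted copies average to the midpoint peak by peak
  tr2 <- tr; tr2$cell_id <- "c2"; tr2$time_h <- tr2$time_h + 0.5
  tr2 <- tr2[tr2$time_h <= 24, ]
  both <- rbind(tr[tr$time_h >= 1, ], tr2[tr2$time_h >= 1, ])
  pm2 <- peak_based_mean(both)
  expect_equal(pm2$n_cells, 2L)
  expect_equal(pm2$peaks$t_max[1], pm1$peaks$t_max[1] + 0.25,
               tolerance = 0.05)
  expect_error(peak_based_mean(make_traj(rep(1, 97), seq(0, 24, 0.25))),
               "no member")
})

test_that("peak-index coverage rule drops sparse indices", {
  sim <- p53_simulate(p53_reference_params())
  tr <- observe_p53(sim, scale = 100, cell_id = "c1")
  short <- tr[tr$time_h <= 10, ]          # fewer peaks
  short$cell_id <- "c2"
  pm_all <- peak_based_mean(tr)
  pm_mix <- peak_based_mean(rbind(tr, short))
  n_short <- nrow(peak_based_mean(short["c2" == short$cell_id, ])$peaks)
  # with one of two members covering an index, 50% coverage keeps it
  expect_gte(nrow(pm_mix$peaks), n_short)
  pm_strict <- peak_based_mean(rbind(tr, short), coverage = 0.9)
  expect_identical(nrow(pm_strict$peaks), n_short)
})

test_that("perturbed trajectories are assigned to their source cluster", {
  pool <- p53_demo_pool(c(5, 7, 10))
  grid <- seq(0.5, 24, by = 0.25)
  cal <- lapply(1:3, function(k)
    peak_based_mean(observe_p53(p53_simulate(pool_member(pool, k),
                                             times = grid),
                                scale = 100, cell_id = paste0("m", k))))
  # a delayed copy of a member still lands in that member's cluster
  pert <- perturbation_spec(c("alpha_mpi", "alpha_m", "beta_sp"),
                            c(0.3, 0.3, -0.3), -1)
  for (k in 1:3) {
    trp <- observe_p53(p53_simulate(pool_member(pool, k),
                                    perturbation = pert, times = grid),
                       scale = 100, cell_id = "x")
    asg <- assign_to_clusters(trp, cal)
    expect_identical(unname(asg$labels[["x"]]), k)
  }
  # an exact copy of a calibration member maps to its own cluster
  tr <- observe_p53(p53_simulate(pool_member(pool, 2), times = grid),
                    scale = 100, cell_id = "y")
  asg2 <- assign_to_clusters(tr, cal)
  expect_identical(unname(asg2$labels[["y"]]), 2L)
  # a flat trajectory is unassignable
  flat <- make_traj(rep(100, length(grid)), grid, "flat")
  asg3 <- assign_to_clusters(flat, cal)
  expect_true("flat" %in% asg3$unassignable)
  expect_equal(sum(asg3$weights), 0)
})

test_that("self-assignment without criteria reproduces cluster labels", {
  pool <- p53_demo_pool(c(5, 7, 10))
  gen <- generate_calibration_cells(generator_config(
    pool = pool, n_cells = 45, jitter_sd = 0.01, noise_cv = 0.05,
    seed = 7))
  cl <- hierarchical_cluster(pairwise_dissimilarity(gen$trajectories), 3)
  pm <- cluster_peak_means(gen$trajectories, cl)
  asg <- assign_to_clusters(gen$trajectories, pm,
                            criteria = default_assignment_criteria()[0, ])
  agree <- mean(asg$labels[names(cl$labels)] == cl$labels, na.rm = TRUE)
  expect_gte(agree, 0.95)
  expect_equal(sum(asg$weights), 1)
})
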