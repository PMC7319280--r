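#' Pairwise dissimilarity between single-cell trajectories
#'
#' The default measure is the Euclidean distance between smoothed,
#' per-cell range-normalized trajectories (each cell scaled to [0, 1] by
#' its own range) on the common sampling grid. The alternative operates
#' on z-scored feature vectors.
#'
#' @param data Long trajectory data frame on a common grid.
#' @param method `"trajectory"` (default) or `"features"`.
#' @param sigma Smoothing kernel SD (h).
#' @param max_peaks Peaks used by the feature method.
#' @return Symmetric dissimilarity matrix with cell ids as dimnames.
#' @export
pairwise_dissimilarity <- function(data, method = c("trajectory", "features"),
                                   sigma = 0.5, max_peaks = 4) {
  method <- match.arg(method)
  M <- trajectory_representation(data, method, sigma, max_peaks)
  D <- as.matrix(stats::dist(M))
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

# cells-by-variables representation used for clustering and for the
# Calinski-Harabasz index
trajectory_representation <- function(data, method = "trajectory",
                                      sigma = 0.5, max_peaks = 4) {
  data <- validate_trajectories(data)
  ids <- unique(data$cell_id)
  if (method == "trajectory") {
    grids <- split(data$time_h, data$cell_id)
    g0 <- grids[[1]]
    same <- all(vapply(grids, function(g)
      length(g) == length(g0) && all(g == g0), logical(1)))
    if (!same) stop("trajectories must share a common time grid")
    sm <- smooth_trajectories(data, sigma)
    M <- do.call(rbind, lapply(ids, function(id) {
      y <- sm$intensity[sm$cell_id == id]
      r <- max(y) - min(y)
      if (r <= 0) stop("flat trajectory for cell ", id,
                       ": range normalization undefined")
      (y - min(y)) / r
    }))
  } else {
    ft <- trajectory_features(data, sigma = sigma, max_peaks = max_peaks)
    ft <- ft[ft$feature %in% c("t_max", "t_min", "ipi", "df", "f_max"), ]
    ft$key <- paste(ft$feature, ft$peak_index, sep = "_")
    keys <- sort(unique(ft$key))
    M <- matrix(NA_real_, length(ids), length(keys),
                dimnames = list(ids, keys))
    for (r in seq_len(nrow(ft)))
      M[ft$cell_id[r], ft$key[r]] <- ft$value[r]
    keep <- colSums(is.na(M)) == 0
    M <- M[, keep, drop = FALSE]
    if (!ncol(M)) stop("no feature shared by all cells")
    M <- scale(M)
  }
  rownames(M) <- ids
  M
}

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Ward-linkage hierarchical clustering cut at K clusters. Labels are
#' relabelled contiguously in order of first appearance, so the result
#' is deterministic given the matrix.
#'
#' @param D Symmetric dissimilarity matrix (or `dist`).
#' @param k Number of clusters (2 <= k < N).
#' @param linkage Linkage method for [stats::hclust()], default
#'   `"ward.D2"`.
#' @return Object of class `p53_clusters`: list with `labels` (named
#'   integer vector), `sizes`, `weights` and the `hclust` tree.
#' @export
hierarchical_cluster <- function(D, k, linkage = "ward.D2") {
  d <- if (inherits(D, "dist")) D else stats::as.dist(D)
  n <- attr(d, "Size")
  if (k < 2 || k >= n) stop("`k` must satisfy 2 <= k < number of cells")
  hc <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(hc, k)
  labels <- as.integer(factor(raw, levels = unique(raw)))
  names(labels) <- names(raw)
  sizes <- tabulate(labels, k)
  structure(list(labels = labels, k = k, sizes = sizes,
                 weights = sizes / sum(sizes), tree = hc),
            class = "p53_clusters")
}

#' @export
print.p53_clusters <- function(x, ...) {
  cat("p53 trajectory clustering: k =", x$k, "\n sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Calinski-Harabasz index
#'
#' CH = (B / (K - 1)) / (W / (N - K)), where B and W are the between- and
#' within-cluster sums of squared deviations in the representation space.
#'
#' @param x Cells-by-variables numeric matrix.
#' @param labels Cluster labels, one per row of `x`.
#' @return The index (0 when all centroids coincide).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  K <- length(unique(labels))
  N <- nrow(x)
  if (K < 2) stop("need at least 2 clusters")
  mu <- colMeans(x)
  B <- 0; W <- 0
  for (k in unique(labels)) {
    xk <- x[labels == k, , drop = FALSE]
    ck <- colMeans(xk)
    B <- B + nrow(xk) * sum((ck - mu)^2)
    W <- W + sum(sweep(xk, 2, ck)^2)
  }
  if (W <= 0) stop("degenerate clustering: zero within-cluster scatter")
  (B / (K - 1)) / (W / (N - K))
}

#' Select the number of subpopulations
#'
#' Clusters the trajectories hierarchically and scans a range of cluster
#' numbers, scoring each cut with the Calinski-Harabasz index computed on
#' the same representation used for the dissimilarities; ties break
#' toward the smaller K.
#'
#' @param data Long trajectory data frame.
#' @param k_range Candidate cluster counts (default 2:15).
#' @param method,sigma Passed to [pairwise_dissimilarity()].
#' @param linkage Linkage method.
#' @return List with `k` (selected count), `clusters` (a `p53_clusters`
#'   at the selected K), and `ch` (data frame of the scanned index).
#' @export
select_cluster_count <- function(data, k_range = 2:15,
                                 method = "trajectory", sigma = 0.5,
                                 linkage = "ward.D2") {
  if (!length(k_range)) stop("empty `k_range`")
  M <- trajectory_representation(data, method, sigma)
  n <- nrow(M)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) >= n)
    stop("`k_range` must lie within [2, N - 1]")
  d <- stats::dist(M)
  hc <- stats::hclust(d, method = linkage)
  ch <- vapply(k_range, function(K)
    calinski_harabasz(M, stats::cutree(hc, K)), numeric(1))
  kstar <- k_range[which.max(ch)]   # which.max takes the first maximum
  list(k = kstar,
       clusters = hierarchical_cluster(d, kstar, linkage),
       ch = data.frame(k = k_range, ch = ch))
}

#' Peak-based mean of a set of trajectories
#'
#' Averages extrema in a peak-wise manner: for each peak index present
#' in at least `coverage` of the member cells, the mean timing and mean
#' absolute value of the maxima (and of the following minima) are
#' computed; pointwise averaging would blur the pulsatile shape. The
#' initial value is the mean first observed sample.
#'
#' @param data Long trajectory data frame (one cluster's members).
#' @param sigma,min_prominence,min_separation Extrema-detection settings.
#' @param coverage Minimum fraction of members that must possess a peak
#'   index for it to be reported (default 0.5).
#' @param max_peaks Cap on reported peak indices.
#' @return Object of class `p53_peak_mean`: list with `init`, `n_cells`
#'   and `peaks` (data frame `peak`, `t_max`, `f_max`, `t_min`, `f_min`;
#'   trailing `t_min`/`f_min` may be NA).
#' @export
peak_based_mean <- function(data, sigma = 0.5, min_prominence = 0.05,
                            min_separation = 2, coverage = 0.5,
                            max_peaks = 8) {
  data <- smooth_trajectories(validate_trajectories(data), sigma)
  cells <- split(data, data$cell_id)
  exts <- lapply(cells, function(d)
    detect_extrema(d$intensity, d$time_h, min_prominence, min_separation))
  n <- length(exts)
  npk <- vapply(exts, function(e) sum(e$kind == "max"), integer(1))
  if (all(npk == 0)) stop("no member has any detected peak")
  init <- mean(vapply(cells, function(d) d$intensity[1], numeric(1)))
  pmax_idx <- min(max_peaks, max(npk))
  rows <- list()
  for (p in seq_len(pmax_idx)) {
    have <- which(npk >= p)
    if (length(have) < coverage * n) break
    tm <- vm <- tn <- vn <- numeric(0)
    for (i in have) {
      mx <- exts[[i]][exts[[i]]$kind == "max", ]
      mn <- exts[[i]][exts[[i]]$kind == "min", ]
      tm <- c(tm, mx$time[p]); vm <- c(vm, mx$value[p])
      if (nrow(mn) >= p) { tn <- c(tn, mn$time[p]); vn <- c(vn, mn$value[p]) }
    }
    rows[[p]] <- data.frame(
      peak = p, t_max = mean(tm), f_max = mean(vm),
      t_min = if (length(tn) >= coverage * length(have)) mean(tn) else NA_real_,
      f_min = if (length(vn) >= coverage * length(have)) mean(vn) else NA_real_)
  }
  peaks <- do.call(rbind, rows)
  if (is.null(peaks)) stop("no peak index reaches the coverage threshold")
  ord_t <- stats::na.omit(as.numeric(t(peaks[, c("t_max", "t_min")])))
  if (is.unsorted(ord_t, strictly = TRUE))
    warning("peak-based mean extrema times are not strictly alternating")
  structure(list(init = init, n_cells = n, peaks = peaks),
            class = "p53_peak_mean")
}

#' @export
print.p53_peak_mean <- function(x, ...) {
  cat("peak-based mean of", x$n_cells, "cells; init =",
      format(x$init, digits = 4), "\n")
  print(x$peaks, digits = 4)
  invisible(x)
}

#' Peak-based means for every cluster
#'
#' @param data Long trajectory data frame.
#' @param clusters A `p53_clusters` object (labels named by cell id).
#' @param ... Passed to [peak_based_mean()].
#' @return List of `p53_peak_mean`, one per cluster label.
#' @export
cluster_peak_means <- function(data, clusters, ...) {
  lab <- clusters$labels
  lapply(seq_len(clusters$k), function(k) {
    ids <- names(lab)[lab == k]
    peak_based_mean(data[data$cell_id %in% ids, , drop = FALSE], ...)
  })
}

#' Default assignment criteria for perturbation trajectories
#'
#' Nine signed rules encoding the perturbation phenotype (delayed maxima
#' and minima, longer inter-peak intervals, stronger dampening, roughly
#' preserved first-peak amplitude): a perturbed cell should exceed its
#' candidate cluster's calibration value for the timing features, and
#' stay within a tolerance band for the first-peak amplitude.
#'
#' @return Data frame with columns `feature`, `peak_index`, `direction`
#'   (`"greater"`, `"less"` or `"within"`) and `tolerance` (relative,
#'   used by `"within"`).
#' @export
default_assignment_criteria <- function() {
  data.frame(
    feature = c("t_max", "t_max", "t_min", "t_min", "ipi", "ipi",
                "df", "df", "f_max"),
    peak_index = c(1, 2, 1, 2, 1, 2, 2, 3, 1),
    direction = c(rep("greater", 6), "greater", "greater", "within"),
    tolerance = c(rep(0, 8), 0.3))
}

#' Assign perturbation trajectories to calibration clusters
#'
#' Each trajectory is assigned to the calibration cluster that satisfies
#' the most direction criteria (its features compared against the
#' cluster's calibration feature values); ties are broken by the minimal
#' z-scored feature distance to the cluster's calibration values.
#' Trajectories without detected peaks land in the `unassignable`
#' bucket.
#'
#' @param data Long trajectory data frame (perturbation condition).
#' @param calibration List of per-cluster `p53_peak_mean` objects (the
#'   calibration targets).
#' @param criteria Rule table, default [default_assignment_criteria()].
#' @param distance_features Feature keys used for the z-scored
#'   tie-break distance. The default uses time-shift-invariant features
#'   (first-peak amplitude, dampening factors, inter-peak intervals):
#'   a perturbation that delays all pulses moves every absolute timing
#'   feature away from the source cluster, so absolute timings would
#'   systematically misdirect the tie-break. With an empty criteria
#'   table the assignment degenerates to the minimal z-scored distance
#'   over all shared features (including absolute timings), the
#'   appropriate mode for unperturbed data.
#' @param sigma,min_prominence,min_separation Feature settings.
#' @return List with `labels` (named integer; NA = unassignable),
#'   `weights`, `sizes`, `unassignable` (cell ids) and `percent`
#'   (per-cluster percentages).
#' @export
assign_to_clusters <- function(data, calibration,
                               criteria = default_assignment_criteria(),
                               distance_features = c("f_max_1", "df_2",
                                 "df_3", "ipi_1", "ipi_2"),
                               sigma = 0.5, min_prominence = 0.05,
                               min_separation = 2) {
  K <- length(calibration)
  calib_feats <- lapply(calibration, peak_mean_features)
  # z-scoring scales from the spread of calibration values across clusters
  all_keys <- unique(unlist(lapply(calib_feats, names)))
  sds <- vapply(all_keys, function(k) {
    v <- vapply(calib_feats, function(f) f[k][[1]] %||% NA_real_, numeric(1))
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))
  names(sds) <- all_keys

  feats <- trajectory_features(data, sigma = sigma,
                               min_prominence = min_prominence,
                               min_separation = min_separation)
  ids <- unique(data$cell_id)
  labels <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (id in ids) {
    f <- feats[feats$cell_id == id, , drop = FALSE]
    if (!nrow(f)) next
    fv <- stats::setNames(f$value, paste(f$feature, f$peak_index, sep = "_"))
    score <- dist_k <- numeric(K)
    for (k in seq_len(K)) {
      ck <- calib_feats[[k]]
      nsat <- 0
      for (r in seq_len(nrow(criteria))) {
        key <- paste(criteria$feature[r], criteria$peak_index[r], sep = "_")
        if (is.na(fv[key]) || is.null(ck[[key]])) next
        nsat <- nsat + switch(criteria$direction[r],
          greater = fv[[key]] >= ck[[key]],
          less    = fv[[key]] <= ck[[key]],
          within  = abs(fv[[key]] - ck[[key]]) <=
                    criteria$tolerance[r] * abs(ck[[key]]))
      }
      score[k] <- nsat
      shared <- intersect(names(fv), names(ck))
      if (nrow(criteria))
        shared <- intersect(shared, distance_features) %||na%
          intersect(names(fv), names(ck))
      dist_k[k] <- if (length(shared))
        sqrt(mean(((fv[shared] - unlist(ck[shared])) / sds[shared])^2))
      else Inf
    }
    top <- which(score == max(score))
    labels[id] <- top[which.min(dist_k[top])]
  }
  assigned <- labels[!is.na(labels)]
  sizes <- tabulate(assigned, K)
  list(labels = labels,
       sizes = sizes,
       weights = if (sum(sizes)) sizes / sum(sizes) else rep(0, K),
       unassignable = names(labels)[is.na(labels)],
       percent = 100 * sizes / max(1, sum(sizes)))
}

# flatten a peak-based mean into named feature values comparable with
# trajectory_features() keys
peak_mean_features <- function(pm) {
  pk <- pm$peaks
  out <- list()
  for (i in seq_len(nrow(pk))) {
    p <- pk$peak[i]
    out[[paste0("t_max_", p)]] <- pk$t_max[i]
    out[[paste0("f_max_", p)]] <- pk$f_max[i]
    out[[paste0("df_", p)]] <- pk$f_max[1] / pk$f_max[i]
    if (!is.na(pk$t_min[i])) out[[paste0("t_min_", p)]] <- pk$t_min[i]
    if (!is.na(pk$f_min[i])) out[[paste0("f_min_", p)]] <- pk$f_min[i]
    if (i < nrow(pk))
      out[[paste0("ipi_", p)]] <- pk$t_max[i + 1] - pk$t_max[i]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%||na%` <- function(a, b) if (length(a)) a else b
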