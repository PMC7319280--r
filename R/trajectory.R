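#' Gaussian-weighted moving-average smoothing
#'
#' Each output sample is a gaussian-weighted average of the input samples
#' within a window truncated at three standard deviations; near the
#' endpoints the weights are renormalized over the available samples, so
#' the output grid equals the input grid.
#'
#' @param x Long-format trajectory data frame (`cell_id`, `time_h`,
#'   `intensity`) or a numeric vector (then `times` must be given).
#' @param sigma Kernel standard deviation in hours (default 0.5 h, two
#'   sampling intervals at 15-min imaging).
#' @param times Sampling times when `x` is a bare vector.
#' @return Same shape as the input, smoothed.
#' @export
smooth_trajectories <- function(x, sigma = 0.5, times = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    stopifnot(!is.null(times), length(times) == length(x))
    return(gauss_smooth_vec(x, times, sigma))
  }
  x <- validate_trajectories(x)
  dt <- min(diff(sort(unique(x$time_h))))
  if (sigma <= 0) stop("`sigma` must be positive")
  if (sigma < dt) {
    warning("kernel width below the sampling interval; returning input unchanged")
    return(x)
  }
  out <- x
  for (id in unique(x$cell_id)) {
    i <- which(x$cell_id == id)
    out$intensity[i] <- gauss_smooth_vec(x$intensity[i], x$time_h[i], sigma)
  }
  out
}

gauss_smooth_vec <- function(y, t, sigma) {
  n <- length(y)
  out <- numeric(n)
  halfw <- 3 * sigma
  for (i in seq_len(n)) {
    j <- which(abs(t - t[i]) <= halfw)
    w <- exp(-0.5 * ((t[j] - t[i]) / sigma)^2)
    out[i] <- sum(w * y[j]) / sum(w)
  }
  out
}

#' Detect alternating extrema of a pulsatile trajectory
#'
#' Local maxima are screened by topographic prominence (relative to the
#' trajectory's global range) and by a minimum separation from the
#' previously kept maximum; between consecutive kept maxima exactly one
#' minimum -- the global minimum of the segment -- is emitted. The
#' sequence starts with the first kept maximum and strictly alternates.
#'
#' @param values Numeric trajectory (smooth it first).
#' @param times Sampling times (h), strictly increasing.
#' @param min_prominence Minimum prominence as a fraction of the global
#'   range (default 0.05).
#' @param min_separation Minimum time between kept maxima (h, default 2).
#' @param refine Parabolic sub-grid refinement of extrema timing and
#'   value (default TRUE): a quadratic through the extremum sample and
#'   its neighbours replaces the grid-quantized location, which keeps
#'   extrema-based objectives smooth in the model parameters.
#' @return Data frame (`kind`, `time`, `value`) of class `p53_extrema`;
#'   zero rows when no maximum qualifies.
#' @export
detect_extrema <- function(values, times, min_prominence = 0.05,
                           min_separation = 2, refine = TRUE) {
  stopifnot(length(values) == length(times))
  if (length(values) < 3L) stop("need at least 3 samples to detect extrema")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  n <- length(values)
  rng <- max(values) - min(values)
  empty <- data.frame(kind = character(), time = numeric(),
                      value = numeric())
  class(empty) <- c("p53_extrema", "data.frame")
  if (rng <= 1e-9 * max(abs(values), 1)) return(empty)  # flat trace

  # local maxima; >= on the left tolerates flat tops on a sampled grid
  cand <- which(values[2:(n - 1)] >= values[1:(n - 2)] &
                values[2:(n - 1)] > values[3:n]) + 1L
  if (!length(cand)) return(empty)

  prom <- vapply(cand, function(i) peak_prominence(values, i), numeric(1))
  cand <- cand[prom >= min_prominence * rng]
  if (!length(cand)) return(empty)

  kept <- cand[1]
  for (i in cand[-1])
    if (times[i] - times[kept[length(kept)]] >= min_separation)
      kept <- c(kept, i)

  kind <- rep("max", length(kept))
  ext_i <- kept
  if (length(kept) > 1) {
    mins <- integer(length(kept) - 1)
    for (s in seq_len(length(kept) - 1)) {
      seg <- kept[s]:kept[s + 1]
      mins[s] <- seg[which.min(values[seg])]
    }
    ord <- order(c(times[kept], times[mins]))
    ext_i <- c(kept, mins)[ord]
    kind <- c(rep("max", length(kept)), rep("min", length(mins)))[ord]
  }
  tt <- times[ext_i]
  vv <- values[ext_i]
  if (refine) {
    for (j in seq_along(ext_i)) {
      i <- ext_i[j]
      if (i <= 1L || i >= n) next
      ref <- parabolic_vertex(times[(i - 1):(i + 1)],
                              values[(i - 1):(i + 1)])
      if (!is.null(ref)) { tt[j] <- ref[1]; vv[j] <- ref[2] }
    }
  }
  out <- data.frame(kind = kind, time = tt, value = vv)
  class(out) <- c("p53_extrema", "data.frame")
  out
}

# vertex of the parabola through three points; NULL when degenerate or
# when the vertex falls outside the bracketing interval
parabolic_vertex <- function(t3, y3) {
  d21 <- (y3[2] - y3[1]) / (t3[2] - t3[1])
  d32 <- (y3[3] - y3[2]) / (t3[3] - t3[2])
  a <- (d32 - d21) / (t3[3] - t3[1])
  if (!is.finite(a) || a == 0) return(NULL)
  tv <- (t3[1] + t3[2]) / 2 - d21 / (2 * a)
  if (tv < t3[1] || tv > t3[3]) return(NULL)
  yv <- y3[1] + d21 * (tv - t3[1]) + a * (tv - t3[1]) * (tv - t3[2])
  c(tv, yv)
}

# topographic prominence of a local maximum: height above the higher of
# the lowest points separating it from greater values on either side
peak_prominence <- function(values, i) {
  n <- length(values)
  left <- values[seq_len(i - 1)]
  hi_l <- which(left > values[i])
  base_l <- if (length(hi_l)) min(values[(max(hi_l)):(i - 1)]) else min(left)
  right <- values[(i + 1):n]
  hi_r <- which(right > values[i])
  base_r <- if (length(hi_r)) min(values[(i + 1):(i + min(hi_r))])
            else min(right)
  values[i] - max(base_l, base_r)
}

#' Dynamic features of a pulsatile trajectory
#'
#' Computes, per peak index n up to `max_peaks`: timing and absolute
#' value of maxima (`t_max`, `f_max`) and of the following minima
#' (`t_min`, `f_min`), inter-peak interval `ipi_n = t_max[n+1] -
#' t_max[n]`, dampening factor `df_n = f_max[1] / f_max[n]`, amplitude
#' (`f_max[n] - f_min[n]`), width (trough-to-trough interval), and the
#' rising/falling slopes between adjacent extrema. Absent peaks yield
#' absent rows, never zeros.
#'
#' @param extrema A `p53_extrema` data frame (see [detect_extrema()]).
#' @param max_peaks Number of pulses considered (default 4).
#' @param cell_id Identifier attached to the rows.
#' @return Long data frame (`cell_id`, `feature`, `peak_index`, `value`).
#' @export
extract_features <- function(extrema, max_peaks = 4, cell_id = "cell_1") {
  empty <- data.frame(cell_id = character(), feature = character(),
                      peak_index = integer(), value = numeric())
  if (nrow(extrema) == 0L) return(empty)
  mx <- extrema[extrema$kind == "max", , drop = FALSE]
  mn <- extrema[extrema$kind == "min", , drop = FALSE]
  np <- min(nrow(mx), max_peaks)
  rows <- list()
  add <- function(feature, peak, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_id = cell_id, feature = feature, peak_index = peak,
      value = value)
  for (p in seq_len(np)) {
    add("t_max", p, mx$time[p])
    add("f_max", p, mx$value[p])
    add("df", p, mx$value[1] / mx$value[p])
    if (p <= nrow(mn)) {
      add("t_min", p, mn$time[p])
      add("f_min", p, mn$value[p])
      add("amplitude", p, mx$value[p] - mn$value[p])
      add("neg_slope", p, (mn$value[p] - mx$value[p]) /
                          (mn$time[p] - mx$time[p]))
      if (p >= 2) add("width", p, mn$time[p] - mn$time[p - 1])
    }
    if (p >= 2)
      add("pos_slope", p, (mx$value[p] - mn$value[p - 1]) /
                          (mx$time[p] - mn$time[p - 1]))
    if (p < np) add("ipi", p, mx$time[p + 1] - mx$time[p])
  }
  do.call(rbind, rows)
}

#' Features for every cell of a trajectory table
#'
#' Smooths each trajectory, detects extrema and extracts features.
#'
#' @param data Long trajectory data frame (`cell_id`, `time_h`,
#'   `intensity`).
#' @param sigma Smoothing kernel SD (h).
#' @param min_prominence,min_separation Passed to [detect_extrema()].
#' @param max_peaks Passed to [extract_features()].
#' @return Long feature data frame.
#' @export
trajectory_features <- function(data, sigma = 0.5, min_prominence = 0.05,
                                min_separation = 2, max_peaks = 4) {
  data <- smooth_trajectories(data, sigma)
  out <- lapply(split(data, data$cell_id), function(d) {
    ext <- detect_extrema(d$intensity, d$time_h, min_prominence,
                          min_separation)
    extract_features(ext, max_peaks, cell_id = d$cell_id[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Holm step-down adjustment of p values
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Adjusted p values, in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Compare feature distributions between two groups of cells
#'
#' Two-sided Wilcoxon rank-sum test per (feature, peak index), with Holm
#' correction applied across the whole tested family. Small samples
#' without ties are tested exactly; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param features_a,features_b Long feature data frames
#'   (see [trajectory_features()]).
#' @param features Which features to test (default the four used for
#'   perturbation phenotyping).
#' @return Data frame with per-test sample sizes, group medians, raw and
#'   Holm-adjusted p values and significance stars.
#' @export
compare_features <- function(features_a, features_b,
                             features = c("t_max", "t_min", "ipi", "df")) {
  rows <- list()
  for (f in features) {
    a <- features_a[features_a$feature == f, , drop = FALSE]
    b <- features_b[features_b$feature == f, , drop = FALSE]
    if (!nrow(a) || !nrow(b))
      stop("empty group for feature ", f)
    for (pk in sort(unique(c(a$peak_index, b$peak_index)))) {
      if (f == "df" && pk == 1) next   # df_1 is 1 by construction
      va <- a$value[a$peak_index == pk]
      vb <- b$value[b$peak_index == pk]
      if (length(va) < 2 || length(vb) < 2) next
      wt <- suppressWarnings(
        stats::wilcox.test(va, vb, alternative = "two.sided",
                           exact = (length(va) <= 10 && length(vb) <= 10 &&
                                    !anyDuplicated(c(va, vb))),
                           correct = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, peak_index = pk,
        n_a = length(va), n_b = length(vb),
        median_a = stats::median(va), median_b = stats::median(vb),
        statistic = unname(wt$statistic), p_value = wt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p_value)
  out$stars <- ifelse(out$p_adjusted < 0.001, "***",
               ifelse(out$p_adjusted < 0.01, "**",
               ifelse(out$p_adjusted < 0.05, "*", "")))
  out
}

validate_trajectories <- function(data) {
  need <- c("cell_id", "time_h", "intensity")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("trajectory data must have columns cell_id, time_h, intensity")
  if (any(!is.finite(data$time_h)) || any(!is.finite(data$intensity)))
    stop("non-finite values in trajectory data")
  for (id in unique(data$cell_id)) {
    tt <- data$time_h[data$cell_id == id]
    if (anyDuplicated(tt))
      stop("duplicated time point for cell ", id)
    if (is.unsorted(tt, strictly = TRUE))
      stop("times not strictly increasing for cell ", id)
  }
  data
}
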