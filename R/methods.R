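#' @export
print.p53_pool_fit <- function(x, ...) {
  cat("Calibrated p53 model pool\n")
  cat("  subpopulations:", nrow(x$pool$delta), "\n")
  cat("  weighted SSR:", format(x$ssr, digits = 5),
      " lambda:", x$lambda, "\n")
  cat("  subpopulation-specific parameters:", x$n_specific, "of",
      length(x$pool$delta), "candidates\n")
  invisible(x)
}

#' @export
summary.p53_pool_fit <- function(object, ...) {
  x <- object
  cat("Calibrated p53 model pool (", nrow(x$pool$delta),
      " subpopulations)\n", sep = "")
  cat("weighted SSR: ", format(x$ssr, digits = 6),
      ";  objective: ", format(x$objective, digits = 6),
      ";  lambda: ", x$lambda, "\n", sep = "")
  cat("\nShared kinetic parameters:\n")
  print(stats::setNames(as.numeric(x$pool$shared),
                        names(unclass(x$pool$shared))), digits = 4)
  cat("\nSubpopulation log10 fold changes (rows = subpopulations):\n")
  print(round(x$pool$delta, 3))
  cat("\nCluster weights:", paste(round(x$pool$weights, 3),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.p53_pool_fit <- function(object, ...) {
  th <- stats::setNames(as.numeric(object$pool$shared),
                        names(unclass(object$pool$shared)))
  d <- object$pool$delta
  dn <- as.vector(outer(seq_len(nrow(d)), colnames(d),
                        function(k, p) paste0("delta_", p, "[", k, "]")))
  c(th, stats::setNames(as.vector(d), dn))
}

#' @export
residuals.p53_pool_fit <- function(object, ...) object$residuals

#' Simulate a fitted pool
#'
#' Simulates every subpopulation member of the calibrated pool (with an
#' optional perturbation) and returns the reporter-scale trajectories.
#'
#' @param object A `p53_pool_fit`.
#' @param nsim Unused (one deterministic simulation per member).
#' @param seed Unused.
#' @param perturbation Optional [perturbation_spec()].
#' @param times Output grid.
#' @param ... Ignored.
#' @return Data frame: `subpopulation`, `time_h`, `intensity`.
#' @export
simulate.p53_pool_fit <- function(object, nsim = 1, seed = NULL,
                                  perturbation = NULL,
                                  times = NULL, ...) {
  pool <- object$pool
  times <- times %||% object$times
  out <- lapply(seq_len(nrow(pool$delta)), function(k) {
    sim <- p53_simulate(pool_member(pool, k), perturbation = perturbation,
                        times = times)
    data.frame(subpopulation = k, time_h = times,
               intensity = pool$scale * sim$observables$p53_total +
                 pool$offset)
  })
  do.call(rbind, out)
}

#' Plot a fitted pool against its peak-based means
#'
#' One panel per subpopulation: simulated reporter trajectory (line)
#' with the target peak-based mean extrema (points).
#'
#' @param x A `p53_pool_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.p53_pool_fit <- function(x, ...) {
  K <- nrow(x$pool$delta)
  sims <- simulate(x)
  old <- graphics::par(mfrow = grDevices::n2mfrow(K),
                       mar = c(3, 3, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (k in seq_len(K)) {
    sk <- sims[sims$subpopulation == k, ]
    tg <- x$targets[[k]]$peaks
    ylim <- range(sk$intensity, tg$f_max, tg$f_min, na.rm = TRUE)
    graphics::plot(sk$time_h, sk$intensity, type = "l", col = "red",
                   xlab = "time (h)", ylab = "p53 (a.u.)",
                   main = paste("subpopulation", k), ylim = ylim, ...)
    graphics::points(tg$t_max, tg$f_max, pch = 19, col = "blue")
    graphics::points(tg$t_min, tg$f_min, pch = 1, col = "blue")
  }
  invisible(x)
}
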