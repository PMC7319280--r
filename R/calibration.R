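#' Residuals of a model pool against peak-based means
#'
#' For each subpopulation the pool member is simulated, extrema of the
#' simulated reporter signal are detected with the same rules applied to
#' the data, and simulated and target extrema are paired by peak index.
#' Each paired extremum contributes a timing residual scaled by
#' `sigma_t` and a value residual scaled by `sigma_y` (a fraction of the
#' cluster's first-peak value); the initial value contributes one
#' residual; target peaks with no simulated counterpart contribute a
#' fixed penalty residual. Every cluster's block is multiplied by the
#' square root of its weight so the summed squares equal the weighted
#' SSR.
#'
#' @param pool A `p53_pool`.
#' @param targets List of `p53_peak_mean`, one per subpopulation.
#' @param times Observation grid (h).
#' @param sigma_t Timing scale, default 0.25 h (one frame).
#' @param sigma_y_frac Value scale as a fraction of the target's
#'   first-peak value, default 0.05.
#' @param penalty Residual per unmatched target extremum pair.
#' @param min_prominence,min_separation Extrema detection on the
#'   simulation.
#' @param sigma Smoothing kernel SD (h) applied to the simulated
#'   reporter signal before extrema detection, mirroring the processing
#'   of the data side (default 0.5).
#' @param weights Optional weights overriding the pool's.
#' @param perturbation Optional [perturbation_spec()] applied to every
#'   member (used when scoring perturbation-condition targets).
#' @return Numeric residual vector with attribute `cluster`.
#' @export
pool_residuals <- function(pool, targets, times = seq(0.5, 24, by = 0.25),
                           sigma_t = 0.25, sigma_y_frac = 0.05,
                           penalty = 5, min_prominence = 0.05,
                           min_separation = 2, sigma = 0.5,
                           weights = NULL, perturbation = NULL) {
  pool <- as_model_pool(pool)
  K <- nrow(pool$delta)
  stopifnot(length(targets) == K)
  w <- weights %||% pool$weights
  w <- w / sum(w)
  res <- numeric(0); who <- integer(0)
  for (k in seq_len(K)) {
    rk <- tryCatch(
      cluster_residuals(pool_member(pool, k), pool$scale, pool$offset,
                        targets[[k]], times, sigma_t, sigma_y_frac,
                        penalty, min_prominence, min_separation,
                        perturbation, sigma),
      error = function(e) NULL)
    if (is.null(rk))
      rk <- rep(penalty, target_residual_length(targets[[k]]))
    res <- c(res, sqrt(w[k]) * rk)
    who <- c(who, rep(k, length(rk)))
  }
  attr(res, "cluster") <- who
  res
}

# residual count for one target: initial value + (time, value) per
# maximum and per present minimum
target_residual_length <- function(target)
  1L + 2L * nrow(target$peaks) + 2L * sum(!is.na(target$peaks$t_min))

cluster_residuals <- function(params, scale, offset, target, times,
                              sigma_t, sigma_y_frac, penalty,
                              min_prominence, min_separation,
                              perturbation = NULL, sigma = 0.5) {
  sim <- p53_simulate(params, perturbation = perturbation, times = times)
  y <- scale * sim$observables$p53_total + offset
  if (sigma > 0) y <- gauss_smooth_vec(y, times, sigma)
  ext <- detect_extrema(y, times, min_prominence, min_separation)
  smx <- ext[ext$kind == "max", , drop = FALSE]
  smn <- ext[ext$kind == "min", , drop = FALSE]
  tg <- target$peaks
  sy <- sigma_y_frac * tg$f_max[1]
  out <- (y[1] - target$init) / sy
  for (i in seq_len(nrow(tg))) {
    if (nrow(smx) >= i) {
      out <- c(out, (smx$time[i] - tg$t_max[i]) / sigma_t,
                    (smx$value[i] - tg$f_max[i]) / sy)
    } else out <- c(out, penalty, penalty)
    if (!is.na(tg$t_min[i])) {
      if (nrow(smn) >= i) {
        out <- c(out, (smn$time[i] - tg$t_min[i]) / sigma_t,
                      (smn$value[i] - tg$f_min[i]) / sy)
      } else out <- c(out, penalty, penalty)
    }
  }
  out
}

#' Pool calibration objective
#'
#' J = sum_k w_k SSR_k + lambda * sum |Delta|: the cell-number-weighted
#' sum of squared extrema residuals plus the L1 penalty on the
#' subpopulation fold-change modifiers.
#'
#' @param pool A `p53_pool`.
#' @param targets Per-cluster `p53_peak_mean` list.
#' @param lambda L1 penalty weight (>= 0).
#' @param ... Passed to [pool_residuals()].
#' @return Scalar objective value.
#' @export
pool_objective <- function(pool, targets, lambda = 0, ...) {
  stopifnot(lambda >= 0)
  pool <- as_model_pool(pool)
  r <- pool_residuals(pool, targets, ...)
  sum(r^2) + lambda * sum(abs(pool$delta))
}

#' Weighted chi-square of a pool against targets
#'
#' chi2 = sum_k w_k sum_i r_ki^2 with the residuals of
#' [pool_residuals()]; also reports log10 chi2 (guarded by a floor for
#' perfect fits).
#'
#' @param pool A `p53_pool`.
#' @param targets Per-cluster `p53_peak_mean` list.
#' @param log_floor Lower guard for log10 chi2.
#' @param ... Passed to [pool_residuals()].
#' @return List with `chi2` and `log10_chi2`.
#' @export
weighted_chi2 <- function(pool, targets, log_floor = -6, ...) {
  r <- pool_residuals(as_model_pool(pool), targets, ...)
  chi2 <- sum(r^2)
  list(chi2 = chi2, log10_chi2 = max(log10(max(chi2, 0)), log_floor))
}

#' Calibrate a model pool to peak-based means
#'
#' Fits the 22 shared kinetic parameters (in log10 space) and the K x 6
#' subpopulation fold-change modifiers jointly to all subpopulation
#' peak-based means by deterministic trust-region least squares
#' (Levenberg-Marquardt on the residual vector). The L1 penalty on the
#' modifiers is handled by a smooth epsilon-approximation of |Delta|
#' appended as extra residuals. Multi-start: the first start is the
#' supplied starting parameter set with zero modifiers, further starts
#' are Latin-hypercube draws around it; the best final objective wins.
#' Deterministic given `seed`.
#'
#' @param targets List of `p53_peak_mean`, one per subpopulation; their
#'   `n_cells` provide the weights.
#' @param start Starting shared parameters (default the bundled
#'   reference set).
#' @param lambda L1 penalty weight.
#' @param scale,offset Observation model (fixed during the fit).
#' @param n_starts Number of starts (default 5).
#' @param start_spread Log10 SD-like half-range of the Latin-hypercube
#'   starts around `start` (default 0.2).
#' @param theta_bound Log10 box half-width for shared parameters around
#'   the start (default 3).
#' @param delta_bound Bound on |Delta| (log10), default 1.
#' @param maxit Iteration cap per start.
#' @param seed RNG seed for the start design.
#' @param times,sigma_t,sigma_y_frac,penalty,min_prominence,min_separation
#'   Residual settings, see [pool_residuals()].
#' @param l1_eps Smoothing of |Delta| in the penalty residuals.
#' @param weights Optional explicit weights (default from `n_cells`).
#' @param delta_start Optional starting modifier matrix (vectorized).
#' @param staged Precede every joint optimization by per-cluster fits of
#'   the 6 modifiers with the shared parameters held fixed (default
#'   TRUE); the joint fit then starts from a pool that already matches
#'   each target roughly, which keeps the trust-region steps well
#'   behaved.
#' @param quiet Suppress per-start progress messages.
#' @return Object of class `p53_pool_fit`.
#' @export
fit_pool <- function(targets, start = p53_reference_params(),
                     lambda = 0, scale = 100, offset = 0,
                     n_starts = 5, start_spread = 0.2, theta_bound = 3,
                     delta_bound = 1, maxit = 100, seed = 1,
                     times = seq(0.5, 24, by = 0.25), sigma_t = 0.25,
                     sigma_y_frac = 0.05, penalty = 5, sigma = 0.5,
                     min_prominence = 0.05, min_separation = 2,
                     l1_eps = 1e-6, weights = NULL, delta_start = NULL,
                     staged = TRUE, quiet = TRUE) {
  K <- length(targets)
  stopifnot(K >= 1)
  start <- as_p53_params(start)
  w <- weights %||% vapply(targets, function(t) t$n_cells, numeric(1))
  w <- w / sum(w)
  ns <- p53_noise_susceptible()
  lt0 <- log10(as.numeric(unclass(start)))
  nd <- 6L * K

  make_pool <- function(x) {
    theta <- 10^x[1:22]
    names(theta) <- p53_param_names()
    delta <- matrix(x[22 + seq_len(nd)], nrow = K, byrow = FALSE)
    colnames(delta) <- ns
    model_pool(p53_params(theta, hill = attr(start, "hill")), delta,
               weights = w, scale = scale, offset = offset)
  }
  resid_fn <- function(x) {
    pool <- make_pool(x)
    r <- pool_residuals(pool, targets, times = times, sigma_t = sigma_t,
                        sigma_y_frac = sigma_y_frac, penalty = penalty,
                        sigma = sigma,
                        min_prominence = min_prominence,
                        min_separation = min_separation)
    if (lambda > 0) {
      d <- x[22 + seq_len(nd)]
      r <- c(r, sqrt(lambda * sqrt(d^2 + l1_eps^2)))
    }
    # lmdif requires at least as many residuals as parameters; padding
    # with exact zeros changes neither objective nor gradient
    if (length(r) <= 22 + nd) r <- c(r, rep(0, 22 + nd + 1 - length(r)))
    r
  }
  lower <- c(lt0 - theta_bound, rep(-delta_bound, nd))
  upper <- c(lt0 + theta_bound, rep(delta_bound, nd))

  d0 <- if (is.null(delta_start)) rep(0, nd) else as.numeric(delta_start)
  starts <- list(c(lt0, d0))
  if (n_starts > 1) {
    set.seed(seed)
    U <- lhs::randomLHS(n_starts - 1, 22 + nd)
    for (i in seq_len(n_starts - 1)) {
      xi <- c(lt0, d0) + (U[i, ] * 2 - 1) *
        c(rep(start_spread, 22), rep(start_spread / 2, nd))
      starts[[i + 1]] <- pmin(pmax(xi, lower), upper)
    }
  }

  # per-cluster modifier fit with the shared parameters frozen: a small
  # Latin-hypercube pre-search picks the start (extrema pairing is
  # non-convex), and a weak shrinkage residual on the modifiers breaks
  # the flat directions of a single cluster toward zero
  stage1_shrink <- 0.1
  stage1 <- function(x) {
    theta <- p53_params(stats::setNames(10^x[1:22], p53_param_names()),
                        hill = attr(start, "hill"))
    pre <- rbind(rep(0, 6),
                 as.matrix(lhs::randomLHS(24, 6)) *
                   (2 * min(delta_bound, 0.65)) - min(delta_bound, 0.65))
    for (k in seq_len(K)) {
      idx <- 22 + (seq_len(6) - 1) * K + k
      nres <- target_residual_length(targets[[k]])
      fk <- function(d, shrink = stage1_shrink) {
        pk <- tryCatch(
          apply_modifiers(theta, stats::setNames(d, ns)),
          error = function(e) NULL)
        r <- if (is.null(pk)) rep(penalty, nres) else tryCatch(
          cluster_residuals(pk, scale, offset, targets[[k]], times,
                            sigma_t, sigma_y_frac, penalty,
                            min_prominence, min_separation, NULL, sigma),
          error = function(e) rep(penalty, nres))
        c(r, sqrt(shrink) * d)
      }
      run_lm <- function(st) tryCatch(
        minpack.lm::nls.lm(par = st, fn = fk,
                           lower = rep(-delta_bound, 6),
                           upper = rep(delta_bound, 6),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 60, ptol = 1e-10, ftol = 1e-10,
                             epsfcn = 1e-6)),
        error = function(e) NULL)
      pres <- apply(pre, 1, function(d) sum(fk(d)^2))
      fr <- run_lm(pmin(pmax(pre[which.min(pres), ], -delta_bound),
                        delta_bound))
      if (is.null(fr) || sum(fk(fr$par, 0)^2) > 25) {
        # cluster stuck on a penalty plateau: denser pre-search
        pre2 <- as.matrix(lhs::randomLHS(120, 6)) *
          (2 * min(delta_bound, 0.65)) - min(delta_bound, 0.65)
        pres2 <- apply(pre2, 1, function(d) sum(fk(d)^2))
        fr2 <- run_lm(pre2[which.min(pres2), ])
        if (!is.null(fr2) &&
            (is.null(fr) || fr2$deviance < fr$deviance)) fr <- fr2
      }
      if (!is.null(fr)) x[idx] <- fr$par
    }
    x
  }

  best <- NULL; trace <- data.frame(start = integer(), objective = numeric())
  for (s in seq_along(starts)) {
    if (staged) starts[[s]] <- stage1(starts[[s]])
    fitres <- tryCatch(
      minpack.lm::nls.lm(par = starts[[s]], fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ptol = 1e-10, ftol = 1e-10,
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(fitres)) next
    obj <- sum(resid_fn(fitres$par)^2)
    trace <- rbind(trace, data.frame(start = s, objective = obj))
    if (!quiet) message("start ", s, ": objective ", format(obj, digits = 5))
    if (is.null(best) || obj < best$obj)
      best <- list(par = fitres$par, obj = obj, info = fitres$info)
  }
  if (is.null(best)) stop("all optimization starts failed")

  pool <- make_pool(best$par)
  r <- pool_residuals(pool, targets, times = times, sigma_t = sigma_t,
                        sigma_y_frac = sigma_y_frac, penalty = penalty,
                        sigma = sigma,
                        min_prominence = min_prominence,
                        min_separation = min_separation)
  ssr <- sum(r^2)
  structure(list(pool = pool, objective = best$obj, ssr = ssr,
                 residuals = r, lambda = lambda,
                 n_specific = count_specific(pool),
                 trace = trace, seed = seed, targets = targets,
                 times = times,
                 control = list(sigma_t = sigma_t,
                                sigma_y_frac = sigma_y_frac,
                                penalty = penalty,
                                min_prominence = min_prominence,
                                min_separation = min_separation)),
            class = "p53_pool_fit")
}

#' L1 regularization path and penalty selection
#'
#' Fits the pool along an ascending lambda grid with warm starts; the
#' selected lambda is the largest one whose weighted SSR stays within a
#' relative tolerance of the unpenalized SSR. Modifiers below the zero
#' tolerance are then set to exactly zero and the count of
#' subpopulation-specific parameters is reported.
#'
#' @param targets Per-cluster `p53_peak_mean` list.
#' @param lambda_grid Ascending grid including 0.
#' @param ssr_tol Relative SSR tolerance (default 0.05).
#' @param ssr_floor Absolute SSR allowance per residual (default 5e-4,
#'   i.e. an average extra discrepancy of ~2% of sigma per residual);
#'   keeps the selection meaningful when the unpenalized SSR is nearly
#'   zero, as on noiseless synthetic targets.
#' @param zero_tol Modifier zero threshold (log10), default 1e-3.
#' @param prune_tol Magnitude below which a fitted modifier is a
#'   pruning candidate (default 0.05 log10, a fold change under 12%):
#'   after the penalty is selected, candidates are set to zero and the
#'   remaining parameters refitted; the pruned model is kept only while
#'   its SSR stays within the selection threshold. This removes the
#'   small non-zero residue that the smooth penalty approximation
#'   leaves on unidentifiable modifiers.
#' @param ... Passed to [fit_pool()].
#' @return List with `lambda`, `fit` (the selected `p53_pool_fit`, with
#'   sub-threshold modifiers zeroed), `path` (data frame lambda / ssr /
#'   n_specific) and `fits`.
#' @export
l1_path_select <- function(targets, lambda_grid = default_lambda_grid(),
                           ssr_tol = 0.05, ssr_floor = 5e-4,
                           zero_tol = 1e-3, prune_tol = 0.05,
                           path_maxit = 25, ...) {
  if (!length(lambda_grid)) stop("empty lambda grid")
  lambda_grid <- sort(lambda_grid)
  if (lambda_grid[1] != 0) stop("lambda grid must include 0")
  fits <- vector("list", length(lambda_grid))
  fits[[1]] <- fit_pool(targets, lambda = 0, ...)
  extra <- list(...)
  for (i in seq_along(lambda_grid)[-1]) {
    prev <- fits[[i - 1]]
    args <- c(list(targets = targets, lambda = lambda_grid[i],
                   start = prev$pool$shared,
                   delta_start = as.numeric(prev$pool$delta),
                   n_starts = 1, staged = FALSE, maxit = path_maxit),
              extra[setdiff(names(extra),
                            c("n_starts", "staged", "maxit"))])
    fits[[i]] <- do.call(fit_pool, args)
  }
  ssr <- vapply(fits, function(f) f$ssr, numeric(1))
  nsp <- vapply(fits, function(f)
    count_specific(f$pool, zero_tol), numeric(1))
  thresh <- max(ssr[1] * (1 + ssr_tol),
                ssr[1] + ssr_floor * length(fits[[1]]$residuals))
  ok <- ssr <= thresh + 1e-12
  sel <- max(which(ok))
  fit <- fits[[sel]]

  # SSR-guarded pruning: modifiers below prune_tol are set to exactly
  # zero as long as the pruned pool stays within the selection
  # threshold (removes the non-zero residue the smooth penalty
  # approximation leaves on unidentifiable modifiers). Entries are
  # tried jointly first, then one by one from the smallest.
  res_args <- extra[names(extra) %in%
    c("times", "sigma_t", "sigma_y_frac", "penalty", "sigma",
      "min_prominence", "min_separation", "weights")]
  eval_ssr <- function(pool)
    sum(do.call(pool_residuals, c(list(pool = pool, targets = targets),
                                  res_args))^2)
  cand <- which(abs(fit$pool$delta) < prune_tol & fit$pool$delta != 0)
  if (length(cand)) {
    pruned <- fit$pool
    pruned$delta[cand] <- 0
    # masked polish: refit the shared parameters and the surviving
    # modifiers with the pruned entries hard-fixed at zero
    keep <- setdiff(which(pruned$delta != 0), integer(0))
    base_delta <- pruned$delta
    hill <- attr(pruned$shared, "hill")
    mk <- function(par) {
      th <- p53_params(stats::setNames(10^par[1:22], p53_param_names()),
                       hill = hill)
      d <- base_delta
      if (length(keep)) d[keep] <- par[-(1:22)]
      model_pool(th, d, weights = pruned$weights,
                 scale = pruned$scale, offset = pruned$offset)
    }
    par0 <- c(log10(as.numeric(pruned$shared)),
              as.numeric(pruned$delta[keep]))
    fn <- function(par) tryCatch(
      as.numeric(do.call(pool_residuals,
        c(list(pool = mk(par), targets = targets), res_args))),
      error = function(e)
        rep(5, sum(vapply(targets, target_residual_length, integer(1)))))
    pf <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = 20,
          ptol = 1e-10, ftol = 1e-10, epsfcn = 1e-6)),
      error = function(e) NULL)
    polished <- if (is.null(pf)) pruned else mk(pf$par)
    s_pol <- eval_ssr(polished)
    if (s_pol <= thresh + 1e-12) {
      fit$pool <- polished
      fit$ssr <- s_pol
    } else if (eval_ssr(pruned) <= thresh + 1e-12) {
      fit$pool <- pruned
      fit$ssr <- eval_ssr(pruned)
    } else {
      for (i in cand[order(abs(fit$pool$delta[cand]))]) {
        trial <- fit$pool
        trial$delta[i] <- 0
        s <- eval_ssr(trial)
        if (s <= thresh + 1e-12) { fit$pool <- trial; fit$ssr <- s }
      }
    }
  }
  fit$pool$delta[abs(fit$pool$delta) < zero_tol] <- 0
  fit$n_specific <- count_specific(fit$pool, zero_tol)
  list(lambda = lambda_grid[sel], fit = fit,
       path = data.frame(lambda = lambda_grid, ssr = ssr,
                         n_specific = nsp),
       fits = fits)
}

#' @rdname l1_path_select
#' @export
default_lambda_grid <- function(n = 20, from = 1e-3, to = 10)
  c(0, 10^seq(log10(from), log10(to), length.out = n))
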