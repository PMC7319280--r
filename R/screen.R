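screen_features <- function() {
  list(t_max = 1:4, t_min = 1:4, ipi = 1:3, df = 2:4)
}

# features of one simulated pool member on the reporter scale
member_features <- function(params, scale, offset,
                            times = seq(0.5, 24, by = 0.25),
                            min_prominence = 0.05, min_separation = 2) {
  sim <- p53_simulate(params, times = times)
  y <- scale * sim$observables$p53_total + offset
  ext <- detect_extrema(y, times, min_prominence, min_separation)
  extract_features(ext, max_peaks = 4, cell_id = "m")
}

#' Feature-based sensitivity of the pool to a parameter perturbation
#'
#' Perturbs the named shared parameters multiplicatively by
#' `1 + delta * sign` and quantifies, for every subpopulation, the
#' relative change s = (F' - F) / F in the four phenotype features
#' (timing of maxima and minima, inter-peak interval, dampening factor)
#' in a peak-wise manner (peaks 1-4, IPIs 1-3, DF 2-4). Entries whose
#' feature is undefined in the perturbed simulation (pulsatility lost)
#' are marked NA.
#'
#' @param pool A `p53_pool` or `p53_pool_fit`.
#' @param parameters Character vector (size 1-3) of shared parameter
#'   names.
#' @param signs Vector of +1/-1, one per parameter.
#' @param delta Relative perturbation strength, default 0.01 (+1%);
#'   +/-0.30 probe stronger perturbations.
#' @param times Observation grid.
#' @return Data frame: `parameter` (collapsed combination), `feature`,
#'   `subpopulation`, `peak_index`, `s`.
#' @export
feature_sensitivity <- function(pool, parameters, signs = rep(1,
                                length(parameters)), delta = 0.01,
                                times = seq(0.5, 24, by = 0.25)) {
  pool <- as_model_pool(pool)
  stopifnot(all(parameters %in% p53_param_names()),
            length(signs) == length(parameters),
            all(signs %in% c(-1, 1)))
  combo <- paste(paste0(parameters, ifelse(signs > 0, "+", "-")),
                 collapse = "&")
  fset <- screen_features()
  K <- nrow(pool$delta)
  rows <- list()
  for (k in seq_len(K)) {
    base <- pool_member(pool, k)
    f0 <- member_features(base, pool$scale, pool$offset, times)
    pert <- unclass(base)
    pert[parameters] <- pert[parameters] * (1 + delta * signs)
    f1 <- tryCatch(
      member_features(p53_params(pert, hill = attr(base, "hill")),
                      pool$scale, pool$offset, times),
      error = function(e) NULL)
    for (fe in names(fset)) for (p in fset[[fe]]) {
      v0 <- f0$value[f0$feature == fe & f0$peak_index == p]
      v1 <- if (is.null(f1)) numeric(0)
            else f1$value[f1$feature == fe & f1$peak_index == p]
      s <- if (length(v0) == 1 && length(v1) == 1 && v0 != 0)
        (v1 - v0) / v0 else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = combo, feature = fe, subpopulation = k,
        peak_index = p, s = s)
    }
  }
  do.call(rbind, rows)
}

#' Condense peak-wise sensitivity coefficients to a single call
#'
#' Per (combination, feature, subpopulation): `no-effect` when every
#' considered peak has |s| below the lower threshold; `increase`
#' (`decrease`) when all peaks with |s| at or above the lower threshold
#' agree in positive (negative) sign; `inconsistent` otherwise;
#' `undefined` when any considered peak is undefined.
#'
#' @param report Output of [feature_sensitivity()] (possibly several
#'   combinations bound together).
#' @param theta_lo No-effect threshold (default 1e-4).
#' @param theta_hi Reporting threshold for strong effects (default 1e-3,
#'   returned as the `strong` flag).
#' @return Data frame: `parameter`, `feature`, `subpopulation`, `call`,
#'   `strong`.
#' @export
condense_sensitivity <- function(report, theta_lo = 1e-4,
                                 theta_hi = 1e-3) {
  stopifnot(theta_lo < theta_hi)
  key <- interaction(report$parameter, report$feature,
                     report$subpopulation, drop = TRUE)
  out <- lapply(split(report, key), function(g) {
    s <- g$s
    call <- if (anyNA(s)) "undefined"
      else if (all(abs(s) < theta_lo)) "no-effect"
      else {
        eff <- s[abs(s) >= theta_lo]
        if (all(eff > 0)) "increase"
        else if (all(eff < 0)) "decrease"
        else "inconsistent"
      }
    data.frame(parameter = g$parameter[1], feature = g$feature[1],
               subpopulation = g$subpopulation[1], call = call,
               strong = !anyNA(s) && any(abs(s) >= theta_hi))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate signed parameter combinations for the sensitivity screen
#'
#' Singles are enumerated with both directions (2m combinations); pairs
#' with the two non-redundant sign patterns per unordered pair
#' (same-sign and opposite-sign; the mirrored patterns are first-order
#' redundant), giving C(m, 2) x 2 combinations.
#'
#' @param parameters Parameter names (default all 22).
#' @param size 1 or 2.
#' @return Data frame with columns `p1`, `s1` and, for pairs, `p2`,
#'   `s2`; deterministic order.
#' @export
enumerate_combinations <- function(parameters = p53_param_names(),
                                   size = 2) {
  m <- length(parameters)
  if (size > m) stop("combination size exceeds the number of parameters")
  if (size == 1) {
    return(data.frame(p1 = rep(parameters, each = 2),
                      s1 = rep(c(1, -1), m)))
  }
  if (size != 2) stop("`size` must be 1 or 2")
  idx <- utils::combn(m, 2)
  data.frame(p1 = rep(parameters[idx[1, ]], each = 2),
             s1 = 1,
             p2 = rep(parameters[idx[2, ]], each = 2),
             s2 = rep(c(1, -1), ncol(idx)))
}

#' Select combinations matching the expected perturbation pattern
#'
#' A combination matches when all four phenotype features are condensed
#' as a consistent increase in at least `min_subpop` subpopulations; the
#' mirrored all-decrease pattern counts as a match for the sign-flipped
#' combination.
#'
#' @param condensed Output of [condense_sensitivity()].
#' @param min_subpop Minimum subpopulations (7 of 10 for pairs; 10 of 10
#'   for singles).
#' @return Data frame of matching combinations with the matched
#'   orientation (`"as-is"` or `"sign-flipped"`).
#' @export
match_expected_pattern <- function(condensed, min_subpop = 7) {
  fset <- names(screen_features())
  out <- lapply(split(condensed, condensed$parameter), function(g) {
    K <- length(unique(g$subpopulation))
    inc <- dec <- 0
    for (k in unique(g$subpopulation)) {
      calls <- g$call[g$subpopulation == k][match(fset,
                g$feature[g$subpopulation == k])]
      if (all(calls == "increase")) inc <- inc + 1
      if (all(calls == "decrease")) dec <- dec + 1
    }
    res <- NULL
    if (inc >= min_subpop)
      res <- data.frame(parameter = g$parameter[1],
                        orientation = "as-is", n_matching = inc)
    if (dec >= min_subpop)
      res <- rbind(res, data.frame(parameter = g$parameter[1],
                                   orientation = "sign-flipped",
                                   n_matching = dec))
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res))
    res <- data.frame(parameter = character(), orientation = character(),
                      n_matching = integer())
  res
}

#' Fit a parameter combination to perturbation targets
#'
#' Optimizes only the log10 fold changes of the named shared parameters
#' (applied identically to all subpopulations from the onset time); all
#' other parameters stay at their calibrated values. The objective is
#' the weighted extrema-residual SSR against the perturbation-condition
#' peak-based means, i.e. the weighted chi-square used for ranking.
#'
#' @param pool Calibrated `p53_pool` or `p53_pool_fit` (frozen).
#' @param parameters 2 or 3 shared parameter names.
#' @param targets Per-cluster `p53_peak_mean` list for the perturbation
#'   condition.
#' @param t_inh Perturbation onset (h), default -1 (pre-treatment).
#' @param bound Bound on |pi| (log10), default 1.5.
#' @param n_starts Number of starts (first at pi = 0).
#' @param start_spread Half-range of additional starts.
#' @param seed RNG seed for starts.
#' @param maxit Iteration cap.
#' @param weights Optional weights (default the target cell numbers).
#' @param ... Residual settings passed to [pool_residuals()].
#' @return Object of class `p53_combo_fit`: `parameters`, `pi`, `t_inh`,
#'   `chi2`, `log10_chi2`, `convergence`.
#' @export
fit_combination <- function(pool, parameters, targets, t_inh = -1,
                            bound = 1.5, n_starts = 3,
                            start_spread = 0.4, seed = 1, maxit = 50,
                            weights = NULL, ...) {
  pool <- as_model_pool(pool)
  stopifnot(length(parameters) %in% c(1, 2, 3),
            all(parameters %in% p53_param_names()))
  w <- weights %||% vapply(targets, function(t) t$n_cells, numeric(1))
  np <- length(parameters)
  nres <- sum(vapply(targets, target_residual_length, integer(1)))
  resid_fn <- function(pi) {
    pert <- perturbation_spec(parameters, pi, t_inh)
    tryCatch(
      pool_residuals(pool, targets, weights = w, perturbation = pert, ...),
      error = function(e) rep(1e3, nres))
  }
  starts <- list(rep(0, np))
  if (n_starts > 1) {
    set.seed(seed)
    U <- lhs::randomLHS(n_starts - 1, np)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- (U[i, ] * 2 - 1) * start_spread
  }
  best <- NULL
  for (s in starts) {
    fr <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = rep(-bound, np), upper = rep(bound, np),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ptol = 1e-9, ftol = 1e-9,
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(fr)) next
    obj <- sum(resid_fn(fr$par)^2)
    if (is.null(best) || obj < best$obj)
      best <- list(par = fr$par, obj = obj, info = fr$info)
  }
  if (is.null(best))
    return(structure(list(parameters = parameters,
                          pi = rep(NA_real_, np), t_inh = t_inh,
                          chi2 = Inf, log10_chi2 = Inf,
                          convergence = NA), class = "p53_combo_fit"))
  structure(list(parameters = parameters,
                 pi = stats::setNames(best$par, parameters),
                 t_inh = t_inh, chi2 = best$obj,
                 log10_chi2 = max(log10(max(best$obj, 0)), -6),
                 convergence = best$info),
            class = "p53_combo_fit")
}

#' @export
print.p53_combo_fit <- function(x, ...) {
  cat("combination fit:",
      paste(sprintf("%s (pi=%.3f)", x$parameters, x$pi), collapse=", "),
      "\n  chi2 =", format(x$chi2, digits = 5),
      " (onset", x$t_inh, "h)\n")
  invisible(x)
}

#' Rank combination fits by chi-square
#'
#' @param fits List of `p53_combo_fit`.
#' @param top Number of best fits to return (default 30).
#' @return Data frame ranked ascending by `chi2`; ties broken by the
#'   lexicographic order of sorted parameter names.
#' @export
rank_combinations <- function(fits, top = 30) {
  tab <- data.frame(
    combination = vapply(fits, function(f)
      paste(sort(f$parameters), collapse = "&"), character(1)),
    chi2 = vapply(fits, function(f) f$chi2, numeric(1)),
    log10_chi2 = vapply(fits, function(f) f$log10_chi2, numeric(1)))
  ord <- order(tab$chi2, tab$combination)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  utils::head(tab, top)
}

#' Validate a combination fit on time-variant perturbation datasets
#'
#' With the fitted fold changes frozen, each dataset is simulated with
#' the perturbation switched on at that dataset's onset time and scored
#' by the weighted chi-square against the dataset's assigned peak-based
#' means. The summary is the sum of the per-group log10 chi2 values,
#' where datasets sharing (approximately) the same onset form a group.
#'
#' @param fit A `p53_combo_fit`.
#' @param pool The calibrated pool.
#' @param datasets Named list; each element a list with `targets` (peak
#'   means) and `t_inh` (onset in h).
#' @param groups Optional list mapping group names to dataset names;
#'   default each dataset is its own group.
#' @param log_floor Guard for log10 of a perfect fit.
#' @param ... Residual settings.
#' @return List with `per_dataset` (data frame) and `summary_log10`.
#' @export
validate_time_variant <- function(fit, pool, datasets, groups = NULL,
                                  log_floor = -6, ...) {
  pool <- as_model_pool(pool)
  rows <- list()
  for (nmv in names(datasets)) {
    d <- datasets[[nmv]]
    pert <- perturbation_spec(fit$parameters, as.numeric(fit$pi),
                              d$t_inh)
    r <- tryCatch(
      pool_residuals(pool, d$targets, perturbation = pert, ...),
      error = function(e) NULL)
    if (is.null(r)) { warning("dataset ", nmv, " failed; skipped"); next }
    chi2 <- sum(r^2)
    rows[[nmv]] <- data.frame(dataset = nmv, t_inh = d$t_inh,
                              chi2 = chi2,
                              log10_chi2 = max(log10(max(chi2, 0)),
                                               log_floor))
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  if (is.null(groups))
    groups <- stats::setNames(as.list(per$dataset), per$dataset)
  summary_log10 <- sum(vapply(groups, function(g) {
    chi2 <- mean(per$chi2[per$dataset %in% g])
    max(log10(max(chi2, 0)), log_floor)
  }, numeric(1)))
  list(per_dataset = per, summary_log10 = summary_log10)
}

#' Qualitative population-readout filters for a combination fit
#'
#' Compares perturbed and unperturbed weighted population readouts and
#' applies the experimental-consistency checks: phosphorylated ATM
#' (kinase activity proxy) must not drop (its AUC must be at least that
#' of the unperturbed pool), Mdm2 protein must not collapse (peak at
#' least `phi` of unperturbed), Mdm2 mRNA must not explode (peak at
#' most `psi` of unperturbed); delayed accumulation of Mdm2 and Wip1
#' (time to half-maximum not earlier) is reported as a fourth check.
#'
#' @param fit A `p53_combo_fit`.
#' @param pool The calibrated pool.
#' @param phi Lower bound on the Mdm2 protein peak ratio (default 0.2).
#' @param psi Upper bound on the Mdm2 mRNA peak ratio (default 5).
#' @param times Readout grid.
#' @return List of logical verdicts (`patm_auc`, `mdm2_protein`,
#'   `mdm2_mrna`, `delayed_accumulation`) plus `pass` (the three
#'   mandatory checks).
#' @export
qualitative_filters <- function(fit, pool, phi = 0.2, psi = 5,
                                times = seq(0, 24, by = 0.25)) {
  pool <- as_model_pool(pool)
  ref <- population_readouts(pool, NULL, times)
  pert <- population_readouts(pool,
            perturbation_spec(fit$parameters, as.numeric(fit$pi),
                              fit$t_inh), times)
  auc <- function(y) sum(diff(times) * (utils::head(y, -1) +
                                        utils::tail(y, -1)) / 2)
  t_half <- function(y) times[which(y >= y[1] + (max(y) - y[1]) / 2)[1]]
  v <- list(
    patm_auc = auc(pert$patm) >= auc(ref$patm) * (1 - 1e-9),
    mdm2_protein = max(pert$mdm2) >= phi * max(ref$mdm2),
    mdm2_mrna = max(pert$mdm2_mrna) <= psi * max(ref$mdm2_mrna),
    delayed_accumulation =
      t_half(pert$mdm2) >= t_half(ref$mdm2) &&
      t_half(pert$wip1) >= t_half(ref$wip1))
  v$pass <- v$patm_auc && v$mdm2_protein && v$mdm2_mrna
  v
}

#' Group combination fits into mechanisms
#'
#' Combinations that are identical after mapping both the maximal
#' ATM-mediated p53 activation rate and its half-saturation constant to
#' the same process ("p53 activation by ATM", with the half-saturation
#' direction inverted: raising it lowers activation) are merged into one
#' mechanism; each group reports its shared signed processes.
#'
#' @param fits List of `p53_combo_fit` (the surviving combinations).
#' @return List of groups, each with `members` (combination labels) and
#'   `processes` (signed process labels).
#' @export
group_mechanisms <- function(fits) {
  key_of <- function(f) {
    proc <- vapply(seq_along(f$parameters), function(i) {
      p <- f$parameters[i]
      s <- sign(f$pi[i])
      if (p %in% c("beta_sp", "T_s")) {
        p <- "p53_activation_by_ATM"
        if (f$parameters[i] == "T_s") s <- -s
      }
      paste0(p, ifelse(s >= 0, "+", "-"))
    }, character(1))
    paste(sort(proc), collapse = " ")
  }
  keys <- vapply(fits, key_of, character(1))
  lapply(split(seq_along(fits), keys), function(i) {
    list(members = vapply(fits[i], function(f)
           paste(sort(f$parameters), collapse = "&"), character(1)),
         processes = strsplit(keys[i[1]], " ")[[1]])
  })
}
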