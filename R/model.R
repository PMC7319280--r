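#' Damage input specification
#'
#' The damage signal E(t) is dimensionless and bounded in [0, 1]: zero
#' before irradiation and, by default, a persistent unit step afterwards
#' (double-strand breaks persist over the observation window at high
#' dose). An optional exponential repair decay is available but off by
#' default.
#'
#' @param t_ir Irradiation time in hours (time origin convention:
#'   `t_ir = 0`).
#' @param decay Repair rate (1/h); 0 keeps the damage persistent.
#' @return Object of class `p53_damage`.
#' @export
damage_input <- function(t_ir = 0, decay = 0) {
  stopifnot(is.numeric(t_ir), length(t_ir) == 1L, !is.na(t_ir),
            is.numeric(decay), length(decay) == 1L, decay >= 0)
  structure(list(t_ir = t_ir, decay = decay), class = "p53_damage")
}

#' Perturbation specification
#'
#' A perturbation multiplies selected kinetic parameters by
#' \eqn{10^{\pi}} from an onset time onwards; before the onset the
#' parameter is unmodified. An empty specification is the unperturbed
#' condition.
#'
#' @param parameter Character vector of parameter names (any of the 22).
#' @param pi Numeric vector of log10 fold changes, same length.
#' @param t_inh Onset time(s) in hours, length 1 or same length; the
#'   default -1 h models inhibitor pre-treatment one hour before
#'   irradiation.
#' @return Object of class `p53_perturbation` (a data frame with columns
#'   `parameter`, `pi`, `t_inh`).
#' @export
perturbation_spec <- function(parameter = character(), pi = numeric(),
                              t_inh = -1) {
  if (length(parameter) == 0L) {
    out <- data.frame(parameter = character(), pi = numeric(),
                      t_inh = numeric())
    class(out) <- c("p53_perturbation", "data.frame")
    return(out)
  }
  if (!all(parameter %in% p53_param_names()))
    stop("unknown parameter(s) in perturbation: ",
         paste(setdiff(parameter, p53_param_names()), collapse = ", "))
  if (length(pi) != length(parameter))
    stop("`pi` must match `parameter` in length")
  t_inh <- rep_len(t_inh, length(parameter))
  stopifnot(all(is.finite(pi)), all(is.finite(t_inh)))
  out <- data.frame(parameter = as.character(parameter),
                    pi = as.numeric(pi), t_inh = as.numeric(t_inh))
  class(out) <- c("p53_perturbation", "data.frame")
  out
}

#' Pre-damage steady state
#'
#' Computes the resting state of the network in the absence of damage
#' (E = 0), used as the initial condition at the irradiation time. The
#' undamaged fixed point is available in closed form (no ATM-P, no
#' active p53, basal Mdm2/Wip1 turnover); it is polished by damped
#' Newton iteration and verified against a relative derivative
#' tolerance.
#'
#' @param params A `p53_params` object.
#' @param tol Relative tolerance on the derivatives at the fixed point.
#' @param max_iter Newton iteration budget.
#' @return Named numeric state vector (S, Pi, Pa, Zm, M, Zw, W).
#' @export
steady_state <- function(params, tol = 1e-9, max_iter = 50L) {
  p <- as_p53_params(params)
  v <- unclass(p)
  Zm <- v[["beta_mt"]] / v[["alpha_mt"]]
  M  <- v[["beta_mtm"]] * Zm / v[["alpha_m"]]
  Zw <- v[["beta_wt"]] / v[["alpha_wt"]]
  W  <- v[["beta_wtw"]] * Zw / v[["alpha_w"]]
  Pi <- v[["beta_p"]] / (v[["alpha_pi"]] + v[["alpha_mpi"]] * M)
  y <- c(S = 0, Pi = Pi, Pa = 0, Zm = Zm, M = M, Zw = Zw, W = W)

  rhs <- function(y) p53_rhs_r(0, y, p, E = 0)
  scale <- pmax(abs(y), 1e-8)
  for (i in seq_len(max_iter)) {
    f <- rhs(y)
    if (max(abs(f) / scale) < tol)
      return(y)
    # damped Newton step with a finite-difference Jacobian
    J <- matrix(0, 7, 7)
    h <- 1e-7 * pmax(abs(y), 1e-6)
    for (j in 1:7) {
      yj <- y; yj[j] <- yj[j] + h[j]
      J[, j] <- (rhs(yj) - f) / h[j]
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    y <- pmax(y + step, 0)
    scale <- pmax(abs(y), 1e-8)
  }
  f <- rhs(y)
  if (max(abs(f) / scale) < tol) return(y)
  stop("no stable pre-damage steady state found; max relative residual ",
       format(max(abs(f) / scale), digits = 3))
}

# Reference R implementation of the right-hand side (used for the
# steady-state solver; the integrator uses the compiled version).
p53_rhs_r <- function(t, y, params, E) {
  v <- unclass(params)
  n <- attr(params, "hill")
  S <- y[[1]]; Pi <- y[[2]]; Pa <- y[[3]]; Zm <- y[[4]]
  M <- y[[5]]; Zw <- y[[6]]; W <- y[[7]]
  act <- v[["beta_sp"]] * max(S, 0) / (v[["T_s"]] + max(S, 0))
  hn <- max(Pa, 0)^n
  hill <- hn / (v[["T_pa"]]^n + hn)
  c(v[["beta_s"]] * E - v[["alpha_s"]] * S - v[["alpha_ws"]] * W * S,
    v[["beta_p"]] - v[["alpha_pi"]] * Pi - v[["alpha_mpi"]] * M * Pi -
      act * Pi + v[["alpha_wpa"]] * W * Pa,
    act * Pi - v[["alpha_wpa"]] * W * Pa - v[["alpha_mpa"]] * M * Pa,
    v[["beta_mt"]] + v[["beta_pamt"]] * hill - v[["alpha_mt"]] * Zm,
    v[["beta_mtm"]] * Zm - v[["alpha_m"]] * M - v[["alpha_sm"]] * S * M,
    v[["beta_wt"]] + v[["beta_pawt"]] * hill - v[["alpha_wt"]] * Zw,
    v[["beta_wtw"]] * Zw - v[["alpha_w"]] * W)
}

state_names <- c("S", "Pi", "Pa", "Zm", "M", "Zw", "W")

#' Simulate the p53 network
#'
#' Integrates the stiff seven-variable system with a compiled
#' right-hand side (lsoda). The integration is restarted at every
#' parameter-switch time (perturbation onsets) so discontinuities are
#' handled exactly; the damage step itself is resolved inside the
#' compiled code.
#'
#' @param params A `p53_params` object (or named vector of the 22
#'   parameters).
#' @param damage A [damage_input()] object.
#' @param perturbation A [perturbation_spec()] object or `NULL`.
#' @param times Strictly increasing output grid in hours. The
#'   integration is internally extended back to the earliest of
#'   `times[1]`, `t_ir` and any perturbation onset.
#' @param y0 Initial state at the start of integration; default the
#'   pre-damage [steady_state()].
#' @param rtol,atol Solver tolerances.
#' @param neg_tol States below `-neg_tol` signal an error; smaller
#'   negative excursions are clipped to zero.
#' @return Object of class `p53_sim`: list with `times`, `states`
#'   (matrix, columns S, Pi, Pa, Zm, M, Zw, W) and `observables`
#'   (data frame with p53_total, mdm2_mrna, mdm2, wip1_mrna, wip1,
#'   patm).
#' @export
p53_simulate <- function(params, damage = damage_input(),
                         perturbation = NULL,
                         times = seq(0, 24, by = 0.25),
                         y0 = NULL, rtol = 1e-8, atol = 1e-10,
                         neg_tol = 1e-6) {
  p <- as_p53_params(params)
  if (is.null(perturbation)) perturbation <- perturbation_spec()
  stopifnot(inherits(perturbation, "p53_perturbation"),
            inherits(damage, "p53_damage"))
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("`times` must be a strictly increasing grid of length >= 2")

  t0 <- min(times[1], damage$t_ir,
            if (nrow(perturbation)) min(perturbation$t_inh) else Inf)
  tend <- times[length(times)]
  onsets <- sort(unique(perturbation$t_inh))
  onsets <- onsets[onsets > t0 & onsets < tend]
  bounds <- c(t0, onsets, tend)

  if (is.null(y0)) y0 <- steady_state(p)
  y <- stats::setNames(as.numeric(y0), state_names)

  full_t <- sort(unique(c(times, bounds)))
  out_rows <- NULL
  for (s in seq_len(length(bounds) - 1L)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    active <- perturbation[perturbation$t_inh <= a, , drop = FALSE]
    pv <- unclass(p)
    if (nrow(active)) {
      mult <- tapply(active$pi, active$parameter, sum)
      pv[names(mult)] <- pv[names(mult)] * 10^as.numeric(mult)
    }
    seg_t <- full_t[full_t >= a & full_t <= b]
    if (seg_t[1] > a) seg_t <- c(a, seg_t)
    if (seg_t[length(seg_t)] < b) seg_t <- c(seg_t, b)
    parms <- c(as.numeric(pv), attr(p, "hill"), damage$t_ir,
               damage$decay, 1)
    sol <- deSolve::lsoda(y = y, times = seg_t, func = "p53_derivs",
                          parms = parms, dllname = "p53pool",
                          initfunc = "p53_initmod", nout = 1,
                          outnames = "p53_total",
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed near t = ",
           format(sol[nrow(sol), 1], digits = 4), " h")
    y <- stats::setNames(as.numeric(sol[nrow(sol), 2:8]), state_names)
    keep <- if (s == 1L) TRUE else sol[, 1] > a
    out_rows <- rbind(out_rows, sol[keep, , drop = FALSE])
  }

  idx <- match(times, out_rows[, 1])
  if (anyNA(idx)) stop("internal error: output grid not covered")
  states <- out_rows[idx, 2:8, drop = FALSE]
  colnames(states) <- state_names
  if (min(states) < -neg_tol)
    stop("negative state beyond tolerance (min = ",
         format(min(states), digits = 3), ")")
  states[states < 0] <- 0
  if (any(!is.finite(states))) stop("non-finite state in solution")

  obs <- data.frame(time_h = times,
                    p53_total = states[, "Pi"] + states[, "Pa"],
                    mdm2_mrna = states[, "Zm"],
                    mdm2 = states[, "M"],
                    wip1_mrna = states[, "Zw"],
                    wip1 = states[, "W"],
                    patm = states[, "S"])
  structure(list(times = times, states = states, observables = obs,
                 params = p, damage = damage,
                 perturbation = perturbation),
            class = "p53_sim")
}

#' @export
print.p53_sim <- function(x, ...) {
  cat("p53 network simulation:", length(x$times), "time points over [",
      x$times[1], ",", x$times[length(x$times)], "] h\n")
  if (nrow(x$perturbation))
    cat("perturbed:",
        paste(sprintf("%s (pi=%.3g, t=%g h)", x$perturbation$parameter,
                      x$perturbation$pi, x$perturbation$t_inh),
              collapse = ", "), "\n")
  invisible(x)
}

#' Map simulated total p53 to a reporter trajectory
#'
#' The live-cell readout is the median nuclear reporter intensity in
#' arbitrary units; the observation model is affine in total p53:
#' y(t) = scale * (Pi + Pa)(t) + offset.
#'
#' @param sim A `p53_sim` object.
#' @param scale Positive gain (a.u. per concentration unit).
#' @param offset Non-negative baseline (a.u.).
#' @param cell_id Identifier attached to the output rows.
#' @return Data frame with columns `cell_id`, `time_h`, `intensity`.
#' @export
observe_p53 <- function(sim, scale = 1, offset = 0, cell_id = "cell_1") {
  stopifnot(inherits(sim, "p53_sim"), scale > 0, offset >= 0)
  data.frame(cell_id = cell_id, time_h = sim$times,
             intensity = scale * sim$observables$p53_total + offset)
}

#' Weighted population-level readouts of a model pool
#'
#' Simulates every subpopulation model of the pool and returns the
#' cell-number-weighted mean of each observable (total p53, Mdm2/Wip1
#' mRNA and protein, and the ATM-P proxy for phosphorylated
#' ATM/Chk2 levels).
#'
#' @param pool A [model_pool()] object.
#' @param perturbation A [perturbation_spec()] or `NULL`.
#' @param times Output grid (h).
#' @param damage A [damage_input()] object.
#' @return Data frame: `time_h` plus one column per observable.
#' @export
population_readouts <- function(pool, perturbation = NULL,
                                times = seq(0, 24, by = 0.25),
                                damage = damage_input()) {
  pool <- as_model_pool(pool)
  w <- pool$weights
  if (any(w < 0) || abs(sum(w)) < 1e-12)
    stop("pool weights must be non-negative and normalizable")
  w <- w / sum(w)
  acc <- NULL
  for (k in seq_along(w)) {
    pk <- apply_modifiers(pool$shared, pool$delta[k, ])
    sim <- p53_simulate(pk, damage = damage, perturbation = perturbation,
                        times = times)
    ob <- as.matrix(sim$observables[, -1])
    acc <- if (is.null(acc)) w[k] * ob else acc + w[k] * ob
  }
  cbind(data.frame(time_h = times), as.data.frame(acc))
}
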