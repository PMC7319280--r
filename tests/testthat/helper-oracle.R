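# Independent oracles, kept free of the package's compiled solver path.

# Right-hand side re-derived by hand in plain R (independent of the
# compiled code and of p53pool's internal R implementation).
oracle_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    E <- if (t >= t_ir) 1 else 0
    act <- beta_sp * S / (T_s + S)
    hill <- Pa^hill_n / (T_pa^hill_n + Pa^hill_n)
    list(c(
      S  = beta_s * E - alpha_s * S - alpha_ws * W * S,
      Pi = beta_p - alpha_pi * Pi - alpha_mpi * M * Pi - act * Pi +
           alpha_wpa * W * Pa,
      Pa = act * Pi - alpha_wpa * W * Pa - alpha_mpa * M * Pa,
      Zm = beta_mt + beta_pamt * hill - alpha_mt * Zm,
      M  = beta_mtm * Zm - alpha_m * M - alpha_sm * S * M,
      Zw = beta_wt + beta_pawt * hill - alpha_wt * Zw,
      W  = beta_wtw * Zw - alpha_w * W))
  })
}

# explicit Runge-Kutta integration of the oracle RHS (non-stiff scheme,
# different integrator family from the package's lsoda)
oracle_integrate <- function(params, y0, times, t_ir = 0) {
  parms <- c(as.numeric(unclass(params)), attr(params, "hill"), t_ir)
  names(parms) <- c(p53_param_names(), "hill_n", "t_ir")
  out <- deSolve::ode(y = y0, times = times, func = oracle_rhs,
                      parms = parms, method = "ode45",
                      rtol = 1e-9, atol = 1e-11, maxsteps = 1e5)
  out
}

# brute-force scan for local maxima of a sampled series
oracle_local_maxima <- function(y) {
  which(vapply(seq_along(y), function(i) {
    i > 1 && i < length(y) && y[i] >= y[i - 1] && y[i] > y[i + 1]
  }, logical(1)))
}

# Calinski-Harabasz by direct definition on a 1-D vector
oracle_ch_1d <- function(x, labels) {
  mu <- mean(x)
  K <- length(unique(labels)); N <- length(x)
  B <- sum(tapply(x, labels, function(v) length(v) * (mean(v) - mu)^2))
  W <- sum(tapply(x, labels, function(v) sum((v - mean(v))^2)))
  (B / (K - 1)) / (W / (N - K))
}

# step-down Holm adjustment by literal definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# exact two-sided Wilcoxon rank-sum p value by enumeration of all
# assignments of the pooled ranks to group A
oracle_wilcox_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  stats <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# reporter-scale feature value from an oracle integration
oracle_features <- function(params, scale = 100) {
  times <- seq(0.5, 24, by = 0.25)
  y0 <- steady_state(params)
  out <- oracle_integrate(params, y0, c(0, times))
  tot <- (out[-1, "Pi"] + out[-1, "Pa"]) * scale
  ext <- detect_extrema(tot, times)
  extract_features(ext, max_peaks = 4, cell_id = "oracle")
}

make_traj <- function(values, times = seq_along(values) - 1,
                      id = "c1") {
  data.frame(cell_id = id, time_h = times, intensity = values)
}
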