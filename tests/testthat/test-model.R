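test_that("parameter container validates names and positivity", {
  expect_length(p53_param_names(), 22L)
  expect_length(p53_noise_susceptible(), 6L)
  expect_true(all(p53_noise_susceptible() %in% p53_param_names()))
  p <- p53_reference_params()
  expect_s3_class(p, "p53_params")
  expect_true(all(unclass(p) > 0))
  bad <- unclass(p); bad[["beta_p"]] <- -1
  expect_error(p53_params(bad), "positive")
  expect_error(p53_params(unclass(p)[-1]), "missing")
})

test_that("modifiers multiply the flagged parameters by 10^delta", {
  p <- p53_reference_params()
  expect_identical(unclass(apply_modifiers(p, c(beta_p = 0))),
                   unclass(p))
  m <- apply_modifiers(p, c(beta_p = 0.65))
  expect_equal(m[["beta_p"]], p[["beta_p"]] * 10^0.65)
  expect_equal(10^0.65, 4.4668, tolerance = 1e-4)
  m2 <- apply_modifiers(p, c(beta_p = 0.3, beta_s = -0.2, beta_wt = 0))
  expect_equal(m2[["beta_wt"]], p[["beta_wt"]])
  expect_error(apply_modifiers(p, c(alpha_s = 0.1)), "noise-susceptible")
})

test_that("pre-damage steady state zeroes ATM-P and active p53 and is a fixed point", {
  p <- p53_reference_params()
  ss <- steady_state(p)
  expect_equal(unname(ss[["S"]]), 0)
  expect_equal(unname(ss[["Pa"]]), 0)
  # dW/dt = 0  =>  beta_wtw * Zw = alpha_w * W
  expect_equal(p[["beta_wtw"]] * ss[["Zw"]], p[["alpha_w"]] * ss[["W"]],
               tolerance = 1e-9)
  # long undamaged integration converges to the same point
  long <- oracle_integrate(p, ss + abs(ss) * 0.2 + 0.01,
                           seq(0, 500, by = 50), t_ir = Inf)
  expect_equal(as.numeric(long[nrow(long), 2:8]), unname(ss),
               tolerance = 1e-5)
})

test_that("undamaged simulation stays at the fixed point", {
  p <- p53_reference_params()
  sim <- p53_simulate(p, damage = damage_input(t_ir = Inf),
                      times = seq(0, 100, by = 1))
  ss <- steady_state(p)
  for (j in 1:7)
    expect_equal(sim$states[, j], rep(unname(ss[j]), 101),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("step damage elicits >= 4 uniform p53 pulses", {
  sim <- p53_simulate(p53_reference_params())
  tot <- sim$observables$p53_total
  ext <- detect_extrema(tot, sim$times)
  mx <- ext[ext$kind == "max", ]
  expect_gte(nrow(mx), 4)
  ipi <- diff(mx$time[1:4])
  expect_lt(stats::sd(ipi) / mean(ipi), 0.2)
  expect_true(all(mx$time >= 0), TRUE)
  expect_identical(ext$kind[1], "max")
  expect_true(all(diff(ext$time) > 0))
})

test_that("solutions match an independent integrator", {
  p <- p53_reference_params()
  times <- seq(0, 24, by = 1)
  sim <- p53_simulate(p, times = times)
  orc <- oracle_integrate(p, steady_state(p), times)
  for (v in c("S", "Pi", "Pa", "Zm", "M", "Zw", "W")) {
    scale <- max(abs(orc[, v]))
    expect_lt(max(abs(sim$states[, v] - orc[, v])) / scale, 1e-4)
  }
})

test_that("a perturbation starting at the end of the window is a no-op", {
  p <- p53_reference_params()
  base <- p53_simulate(p)
  pert <- p53_simulate(p, perturbation = perturbation_spec("beta_p", 0.5,
                                                           t_inh = 24))
  expect_equal(pert$states, base$states, tolerance = 1e-10)
})

test_that("zero-modifier simulation is bit-identical to the unmodified one", {
  p <- p53_reference_params()
  z <- apply_modifiers(p, stats::setNames(rep(0, 6),
                                          p53_noise_susceptible()))
  expect_identical(p53_simulate(z)$states, p53_simulate(p)$states)
})

test_that("reporter observation is affine in total p53", {
  sim <- p53_simulate(p53_reference_params())
  tr <- observe_p53(sim, scale = 1, offset = 0)
  expect_equal(tr$intensity, sim$observables$p53_total)
  tr2 <- observe_p53(sim, scale = 2, offset = 3)
  expect_equal(tr2$intensity, 2 * sim$observables$p53_total + 3)
})

test_that("population readouts are the weighted mean over members", {
  p <- p53_reference_params()
  pool1 <- model_pool(p, matrix(0, 1, 6), 1)
  single <- population_readouts(pool1, times = seq(0, 6, 0.5))
  member <- p53_simulate(p, times = seq(0, 6, 0.5))$observables
  expect_equal(single$p53_total, member$p53_total, tolerance = 1e-10)
  # two identical members, any weights: equal to either one
  pool2 <- model_pool(p, matrix(0, 2, 6), c(0.3, 0.7))
  two <- population_readouts(pool2, times = seq(0, 6, 0.5))
  expect_equal(two$p53_total, member$p53_total, tolerance = 1e-10)
  # weighted-mean arithmetic on distinct members
  d <- matrix(0, 2, 6, dimnames = list(NULL, p53_noise_susceptible()))
  d[2, "beta_p"] <- 0.2
  pool3 <- model_pool(p, d, c(0.25, 0.75))
  mix <- population_readouts(pool3, times = seq(0, 6, 0.5))
  m1 <- p53_simulate(pool_member(pool3, 1), times = seq(0, 6, 0.5))
  m2 <- p53_simulate(pool_member(pool3, 2), times = seq(0, 6, 0.5))
  expect_equal(mix$p53_total,
               0.25 * m1$observables$p53_total +
               0.75 * m2$observables$p53_total, tolerance = 1e-10)
})
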