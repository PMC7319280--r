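test_that("gaussian smoothing preserves constants and lines, reproduces the kernel", {
  t <- seq(0, 24, by = 0.25)
  const <- make_traj(rep(5, length(t)), t)
  expect_equal(smooth_trajectories(const)$intensity, const$intensity)
  # interior of a straight line is unchanged (kernel symmetry)
  lin <- make_traj(2 + 3 * t, t)
  sm <- smooth_trajectories(lin)$intensity
  inner <- t >= 1.5 & t <= 22.5
  expect_equal(sm[inner], lin$intensity[inner], tolerance = 1e-12)
  # a unit impulse returns the truncated, renormalized kernel
  y <- rep(0, length(t)); y[49] <- 1   # t = 12
  sm2 <- smooth_trajectories(make_traj(y, t), sigma = 0.5)$intensity
  w <- exp(-0.5 * ((t - 12) / 0.5)^2)
  w[abs(t - 12) > 1.5] <- 0
  norm <- vapply(seq_along(t), function(i) {
    j <- abs(t - t[i]) <= 1.5
    sum(exp(-0.5 * ((t[j] - t[i]) / 0.5)^2))
  }, numeric(1))
  expect_equal(sm2, w / norm, tolerance = 1e-12)
  # too-narrow kernel warns and returns the input
  expect_warning(out <- smooth_trajectories(lin, sigma = 0.1),
                 "sampling interval")
  expect_equal(out$intensity, lin$intensity)
})

test_that("extrema detection matches a brute-force scan on a sine wave", {
  t <- seq(0, 24, by = 0.25)
  y <- sin(2 * pi * t / 5.5)
  ext <- detect_extrema(y, t, refine = FALSE)
  mx <- ext[ext$kind == "max", ]
  idx <- oracle_local_maxima(y)
  # brute-force candidates thinned by the 2 h separation rule
  keep <- idx[1]
  for (i in idx[-1]) if (t[i] - t[keep[length(keep)]] >= 2)
    keep <- c(keep, i)
  expect_equal(mx$time, t[keep])
  # grid maxima sit nearest the analytic times 1.375 + 5.5 k
  expect_equal(mx$time, c(1.5, 7, 12.5, 18, 23.5), tolerance = 0.26)
  # alternation and interior minima
  expect_true(all(ext$kind[seq(1, nrow(ext), 2)] == "max"))
  expect_true(all(diff(ext$time) > 0))
})

test_that("monotone and two-pulse traces are handled", {
  t <- seq(0, 10, by = 0.25)
  expect_identical(nrow(detect_extrema(t * 2, t)), 0L)
  y <- exp(-(t - 2)^2) + 0.5 * exp(-(t - 7)^2)
  ext <- detect_extrema(y, t)
  expect_identical(sum(ext$kind == "max"), 2L)
  expect_identical(sum(ext$kind == "min"), 1L)
  expect_error(detect_extrema(c(1, 2), c(0, 1)), "3 samples")
})

test_that("sub-grid refinement reproduces a quadratic vertex", {
  t <- seq(0, 4, by = 0.5)
  y <- 10 - (t - 1.8)^2
  ext <- detect_extrema(y, t, min_separation = 1)
  expect_equal(ext$time[1], 1.8, tolerance = 1e-9)
  expect_equal(ext$value[1], 10, tolerance = 1e-9)
})

test_that("features follow their defining arithmetic", {
  ext <- data.frame(kind = c("max", "min", "max"),
                    time = c(2, 5, 7), value = c(100, 40, 50))
  class(ext) <- c("p53_extrema", "data.frame")
  f <- extract_features(ext, cell_id = "c")
  get <- function(fe, p) f$value[f$feature == fe & f$peak_index == p]
  expect_equal(get("ipi", 1), 5)
  expect_equal(get("df", 1), 1)
  expect_equal(get("df", 2), 2)
  expect_equal(get("amplitude", 1), 60)
  expect_equal(get("neg_slope", 1), (40 - 100) / 3)
  expect_equal(get("pos_slope", 2), (50 - 40) / 2)
  # single maximum: df = 1, no IPI rows
  single <- ext[1, , drop = FALSE]
  fs <- extract_features(single, cell_id = "c")
  expect_equal(fs$value[fs$feature == "df"], 1)
  expect_false("ipi" %in% fs$feature)
  # four maxima 100, 80, 60, 50: df_4 = 2
  e4 <- data.frame(kind = rep(c("max", "min"), 4)[1:7],
                   time = 1:7,
                   value = c(100, 30, 80, 30, 60, 30, 50))
  class(e4) <- c("p53_extrema", "data.frame")
  f4 <- extract_features(e4, cell_id = "c")
  expect_equal(f4$value[f4$feature == "df" & f4$peak_index == 4], 2)
  # empty sequence: empty result
  expect_identical(nrow(extract_features(e4[0, ], cell_id = "c")), 0L)
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0, 0, 0)), c(0, 0, 0))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
  }
})

test_that("feature comparison uses the exact two-sided rank-sum test", {
  fa <- data.frame(cell_id = c("a1", "a2"), feature = "ipi",
                   peak_index = 1, value = c(1, 2))
  fb <- data.frame(cell_id = c("b1", "b2"), feature = "ipi",
                   peak_index = 1, value = c(3, 4))
  res <- compare_features(fa, fb, features = "ipi")
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$p_value, oracle_wilcox_exact(c(1, 2), c(3, 4)))
  # a single tested family member: adjusted equals raw
  expect_equal(res$p_adjusted, res$p_value)
  # identical groups: adjusted p = 1
  res2 <- compare_features(fa, fa, features = "ipi")
  expect_equal(res2$p_adjusted, 1)
  expect_error(compare_features(fa[0, ], fb, features = "ipi"), "ipi")
})

test_that("timing features are invariant to affine intensity rescaling", {
  sim <- p53_simulate(p53_reference_params())
  t1 <- observe_p53(sim, scale = 100, cell_id = "c")
  t2 <- observe_p53(sim, scale = 700, offset = 55, cell_id = "c")
  f1 <- trajectory_features(t1)
  f2 <- trajectory_features(t2)
  for (fe in c("t_max", "t_min", "ipi", "df")) {
    v1 <- f1$value[f1$feature == fe]
    v2 <- f2$value[f2$feature == fe]
    if (fe == "df") {
      # dampening is invariant under pure scaling, not under offsets
      v2off <- trajectory_features(
        observe_p53(sim, scale = 700, cell_id = "c"))
      v2 <- v2off$value[v2off$feature == fe]
    }
    expect_equal(v1, v2, tolerance = 1e-8)
  }
})
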