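test_that("combination enumeration has the expected cardinalities", {
  pairs <- enumerate_combinations(size = 2)
  expect_identical(nrow(pairs), 462L)            # C(22, 2) * 2
  key <- paste(pmin(pairs$p1, pairs$p2), pmax(pairs$p1, pairs$p2),
               pairs$s1 * pairs$s2)
  expect_false(anyDuplicated(key) > 0)
  expect_identical(nrow(enumerate_combinations(letters[1:3], 2)), 6L)
  singles <- enumerate_combinations(size = 1)
  expect_identical(nrow(singles), 44L)
  expect_error(enumerate_combinations(letters[1:2], 3), "size")
})

test_that("condensation applies the effect thresholds", {
  rep1 <- data.frame(parameter = "x", feature = "ipi", subpopulation = 1,
                     peak_index = 1:3, s = c(5e-5, 8e-5, 2e-5))
  expect_identical(condense_sensitivity(rep1)$call, "no-effect")
  rep2 <- rep1; rep2$s <- c(2e-3, 3e-3, 1.5e-3)
  c2 <- condense_sensitivity(rep2)
  expect_identical(c2$call, "increase")
  expect_true(c2$strong)
  rep3 <- rep1[1:2, ]; rep3$s <- c(2e-3, -2e-3)
  expect_identical(condense_sensitivity(rep3)$call, "inconsistent")
  rep4 <- rep1; rep4$s <- c(-2e-3, -3e-4, -5e-5)
  expect_identical(condense_sensitivity(rep4)$call, "decrease")
  rep5 <- rep1; rep5$s[2] <- NA
  expect_identical(condense_sensitivity(rep5)$call, "undefined")
})

test_that("an unperturbed sensitivity run yields zero coefficients", {
  pool <- p53_demo_pool(1)
  rep0 <- feature_sensitivity(pool, "beta_p", delta = 0)
  expect_true(all(abs(rep0$s[!is.na(rep0$s)]) < 1e-12))
  fset <- table(rep0$feature)
  expect_equal(as.integer(fset[c("t_max", "t_min", "ipi", "df")]),
               c(4L, 4L, 3L, 3L))
})

test_that("sensitivity coefficients match a finite-difference oracle", {
  pool <- p53_demo_pool(1)
  delta <- 0.01
  for (par in c("beta_sp", "beta_p")) {
    rep1 <- feature_sensitivity(pool, par, signs = 1, delta = delta)
    base <- oracle_features(p53_reference_params())
    p_up <- unclass(p53_reference_params())
    p_up[[par]] <- p_up[[par]] * (1 + delta)
    up <- oracle_features(p53_params(p_up))
    for (i in seq_len(nrow(rep1))) {
      if (is.na(rep1$s[i]) || abs(rep1$s[i]) <= 1e-3) next
      b <- base$value[base$feature == rep1$feature[i] &
                      base$peak_index == rep1$peak_index[i]]
      u <- up$value[up$feature == rep1$feature[i] &
                    up$peak_index == rep1$peak_index[i]]
      if (!length(b) || !length(u)) next
      s_or <- (u - b) / b
      expect_equal(rep1$s[i], s_or, tolerance = 0.05)
    }
  }
})

test_that("expected-pattern matching respects the subpopulation threshold", {
  mk <- function(n_inc, K = 10, par = "x+") {
    do.call(rbind, lapply(seq_len(K), function(k)
      data.frame(parameter = par,
                 feature = c("t_max", "t_min", "ipi", "df"),
                 subpopulation = k,
                 call = if (k <= n_inc) "increase" else "inconsistent",
                 strong = TRUE)))
  }
  expect_identical(nrow(match_expected_pattern(mk(10), 10)), 1L)
  expect_identical(nrow(match_expected_pattern(mk(6), 7)), 0L)
  expect_identical(nrow(match_expected_pattern(mk(7), 7)), 1L)
  # mirrored all-decrease counts as a sign-flipped match
  dec <- mk(10)
  dec$call <- "decrease"
  md <- match_expected_pattern(dec, 10)
  expect_identical(md$orientation, "sign-flipped")
  # relaxing the threshold never shrinks the matched set
  for (n in 1:10) {
    at10 <- nrow(match_expected_pattern(mk(n), 10))
    at7 <- nrow(match_expected_pattern(mk(n), 7))
    expect_gte(at7, at10)
  }
})

test_that("ranking is ascending with lexicographic tie-break", {
  mkfit <- function(params, chi2)
    structure(list(parameters = params, pi = rep(0, length(params)),
                   t_inh = -1, chi2 = chi2,
                   log10_chi2 = log10(max(chi2, 1e-6)),
                   convergence = 1), class = "p53_combo_fit")
  fits <- list(mkfit(c("beta_p", "beta_s"), 3),
               mkfit(c("alpha_m", "alpha_s"), 1),
               mkfit(c("alpha_mpi", "beta_sp"), 2))
  rk <- rank_combinations(fits)
  expect_identical(rk$combination,
                   c("alpha_m&alpha_s", "alpha_mpi&beta_sp",
                     "beta_p&beta_s"))
  ties <- list(mkfit(c("beta_s", "beta_p"), 1), mkfit(c("alpha_m"), 1))
  expect_identical(rank_combinations(ties)$combination[1], "alpha_m")
  expect_identical(nrow(rank_combinations(fits, top = 2)), 2L)
})

test_that("null perturbations pass the qualitative filters, ATM loss fails", {
  pool <- p53_demo_pool(1)
  null_fit <- structure(list(parameters = "beta_p", pi = c(beta_p = 0),
                             t_inh = -1), class = "p53_combo_fit")
  v0 <- qualitative_filters(null_fit, pool)
  expect_true(v0$pass)
  expect_true(v0$delayed_accumulation)
  atm_down <- structure(list(parameters = "beta_s", pi = c(beta_s = -0.5),
                             t_inh = -1), class = "p53_combo_fit")
  v1 <- qualitative_filters(atm_down, pool)
  expect_false(v1$patm_auc)
  expect_false(v1$pass)
  # strongly boosted p53-driven transcription exceeds a tightened
  # transcript-excess tolerance and trips the filter
  mrna_up <- structure(list(parameters = "beta_pamt",
                            pi = c(beta_pamt = 1.3),
                            t_inh = -1), class = "p53_combo_fit")
  v2 <- qualitative_filters(mrna_up, pool, psi = 3)
  expect_false(v2$mdm2_mrna)
  expect_true(qualitative_filters(mrna_up, pool, psi = 5)$mdm2_mrna)
})

test_that("time-variant validation guards perfect fits and no-op onsets", {
  pool <- p53_demo_pool(1)
  grid <- seq(0.5, 24, by = 0.25)
  tg <- list(peak_based_mean(observe_p53(p53_simulate(pool_member(pool, 1),
                                                      times = grid),
                                         scale = 100, cell_id = "m")))
  null_fit <- structure(list(parameters = "beta_p", pi = c(beta_p = 0),
                             t_inh = -1), class = "p53_combo_fit")
  v <- validate_time_variant(null_fit, pool,
                             list(d1 = list(targets = tg, t_inh = 1.5)))
  expect_equal(v$per_dataset$chi2, 0, tolerance = 1e-12)
  expect_equal(v$per_dataset$log10_chi2, -6)  # floor guard
  # an onset after the observation window matches the unperturbed value
  late_fit <- structure(list(parameters = "beta_p", pi = c(beta_p = 0.6),
                             t_inh = -1), class = "p53_combo_fit")
  v2 <- validate_time_variant(late_fit, pool,
                              list(late = list(targets = tg, t_inh = 30)))
  expect_equal(v2$per_dataset$chi2, 0, tolerance = 1e-12)
})

test_that("mechanism grouping merges the activation-process aliases", {
  mk <- function(params, pi)
    structure(list(parameters = params,
                   pi = stats::setNames(pi, params), t_inh = -1,
                   chi2 = 1), class = "p53_combo_fit")
  fits <- list(
    mk(c("alpha_mpi", "alpha_m", "beta_sp"), c(0.3, 0.3, -0.3)),
    mk(c("alpha_mpi", "alpha_m", "T_s"), c(0.3, 0.3, 0.3)),
    mk(c("alpha_mpa", "alpha_sm", "beta_sp"), c(-0.3, -0.3, -0.3)),
    mk(c("alpha_mpa", "alpha_sm", "T_s"), c(-0.3, -0.3, 0.3)))
  groups <- group_mechanisms(fits)
  expect_length(groups, 2L)
  sizes <- sort(unname(vapply(groups, function(g) length(g$members),
                              integer(1))))
  expect_identical(sizes, c(2L, 2L))
  # disjoint combinations stay apart
  g2 <- group_mechanisms(list(mk(c("alpha_m", "beta_p"), c(0.1, 0.1)),
                              mk(c("alpha_s", "beta_mt"), c(0.1, 0.1))))
  expect_length(g2, 2L)
})
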