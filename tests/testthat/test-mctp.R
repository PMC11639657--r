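test_that("a single raw contrast reproduces the asymptotic z-test", {
  set.seed(13)
  x1 <- rnorm(12); x2 <- rnorm(12, 0.5)
  des <- two_sample_design(x1, x2)
  sch <- weight_scheme(des, "weighted")
  C <- as_contrast_matrix(matrix(c(-1, 1), 1))
  mc <- mctp(des, sch, C, approx = "normal", transform = "raw")
  fit <- relative_effects(des, sch)
  cov <- effect_covariance(des, sch, fit)
  delta <- unname(fit$p_hat[2] - fit$p_hat[1])
  U <- as.numeric(C %*% cov$sigma_hat %*% t(C))
  z <- sqrt(sch$g_n / U) * delta
  expect_equal(mc$comparisons$statistic, z, tolerance = 1e-12)
  expect_equal(mc$comparisons$p_adj, 2 * stats::pnorm(-abs(z)),
               tolerance = 1e-9)
  expect_equal(mc$crit, stats::qnorm(0.975), tolerance = 1e-9)
  expect_equal(mc$comparisons$lower,
               delta - stats::qnorm(0.975) * sqrt(U / sch$g_n),
               tolerance = 1e-9)
})

test_that("symmetric two-sample data give null statistics and symmetric SCIs", {
  x <- c(1, 2, 3, 4, 5, 6)
  des <- two_sample_design(x, x)
  sch <- weight_scheme(des)
  C <- as_contrast_matrix(matrix(c(-1, 1), 1))
  for (tr in c("raw", "fisher")) {
    mc <- mctp(des, sch, C, transform = tr)
    expect_equal(mc$comparisons$estimate, 0, tolerance = 1e-12)
    expect_equal(mc$comparisons$statistic, 0, tolerance = 1e-12)
    expect_equal(mc$comparisons$p_adj, 1, tolerance = 1e-9)
    expect_equal(mc$comparisons$lower, -mc$comparisons$upper,
                 tolerance = 1e-9)
  }
})

test_that("MCTP marginal reproduces the Brunner-Munzel statistic and df", {
  set.seed(23)
  for (b in 1:20) {
    x1 <- round(rnorm(sample(8:14, 1)), 1)
    x2 <- round(rnorm(sample(8:14, 1), 0.3), 1)
    des <- two_sample_design(x1, x2)
    sch <- weight_scheme(des, "weighted")
    C <- as_contrast_matrix(matrix(c(-1, 1), 1))
    mc <- mctp(des, sch, C, transform = "raw", sci = FALSE)
    bm <- bm_oracle(x1, x2)
    expect_equal(mc$comparisons$statistic, bm$stat, tolerance = 1e-10)
    expect_equal(mc$df, bm$df, tolerance = 1e-10)
  }
})

test_that("family df follows the homogeneous-group closed form", {
  # two identical groups of n0 clusters: for the pairwise contrast the
  # projected influence values of the two groups have identical empirical
  # variability, so each nu_l collapses to the balanced Welch form
  # (sum_i v^2)^2 / (sum_i v^4/(n0-1)) = 2 * (n0 - 1)
  set.seed(43)
  n0 <- 6
  block <- data.frame(cluster = rep(1:n0, each = 2), value = rnorm(2 * n0))
  dat <- do.call(rbind, lapply(1:2, function(i) cbind(group = i, block)))
  des <- clustered_design(dat)
  sch <- weight_scheme(des)
  nu <- satterthwaite_df(des, sch, as_contrast_matrix(matrix(c(-1, 1), 1)))
  expect_equal(as.numeric(nu), 2 * (n0 - 1), tolerance = 1e-9)
})

test_that("family df is floored at one and degenerates to Inf without variability", {
  set.seed(53)
  des <- random_design(d = 3)
  nu <- satterthwaite_df(des, weight_scheme(des),
                         contrast_matrix("tukey", 3))
  expect_gte(as.numeric(nu), 1)
  const <- clustered_design(data.frame(group = rep(1:2, each = 4),
                                       cluster = rep(1:2, 4), value = 2))
  expect_equal(as.numeric(satterthwaite_df(const, weight_scheme(const),
                                           contrast_matrix("centering", 2))),
               Inf)
})

test_that("Fisher transform round-trips and preserves the effect range", {
  x <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z_inv(fisher_z(x)), x, tolerance = 1e-12)
  # interval for a null effect is tanh-symmetric
  sci <- fisher_sci(0, matrix(2), g_n = 30, crit = 2.4)
  w <- 2.4 * sqrt(2 / 30)
  expect_equal(sci$lower, -tanh(w), tolerance = 1e-12)
  expect_equal(sci$upper, tanh(w), tolerance = 1e-12)
  # extreme estimate with small variance stays strictly inside (-1, 1)
  sci2 <- fisher_sci(0.95, matrix(0.1), g_n = 50, crit = 2.4)
  expect_true(sci2$lower > -1 && sci2$upper < 1)
  expect_warning(fisher_sci(1, matrix(0.1), g_n = 50, crit = 2), "clipped")
})

test_that("adjusted p-values are never smaller than marginal ones", {
  set.seed(63)
  for (b in 1:10) {
    des <- random_design(d = 3, n_max = 6)
    sch <- weight_scheme(des)
    mc <- mctp(des, sch, contrast_matrix("tukey", 3), sci = FALSE)
    marg <- 2 * stats::pt(-abs(mc$comparisons$statistic), mc$df)
    expect_true(all(mc$comparisons$p_adj >= marg - 5e-3))
  }
})

test_that("the global max-test is consonant with per-contrast decisions", {
  set.seed(73)
  for (b in 1:10) {
    des <- random_design(d = 3, n_max = 6)
    sch <- weight_scheme(des)
    mc <- mctp(des, sch, contrast_matrix("tukey", 3), alpha = 0.2)
    expect_equal(mc$p_value, min(mc$comparisons$p_adj))
    global_rej <- mc$p_value <= mc$alpha
    any_sci_excludes <-
      any(mc$comparisons$lower > 0 | mc$comparisons$upper < 0)
    any_stat_exceeds <- mc$global_statistic >= mc$crit
    # p-value decision and critical-value decision coincide up to
    # integration tolerance; skip knife-edge cases
    if (abs(mc$global_statistic - mc$crit) > 1e-2) {
      expect_equal(global_rej, any_stat_exceeds)
      expect_equal(any_sci_excludes, any_stat_exceeds)
    }
  }
})

test_that("raw and Fisher scales mostly agree on rejection decisions", {
  set.seed(83)
  n <- 60; mismatch <- 0; used <- 0
  for (b in seq_len(n)) {
    des <- random_design(d = 2, n_max = 6, vals = 1:8)
    sch <- weight_scheme(des)
    C <- as_contrast_matrix(matrix(c(-1, 1), 1))
    delta <- abs(diff(relative_effects(des, sch)$p_hat))
    if (delta > 0.3) next
    used <- used + 1
    pr <- mctp(des, sch, C, transform = "raw", sci = FALSE)$p_value
    pf_ <- mctp(des, sch, C, transform = "fisher", sci = FALSE)$p_value
    mismatch <- mismatch + ((pr <= 0.05) != (pf_ <= 0.05))
  }
  expect_lte(mismatch / max(used, 1), 0.05)
})

test_that("degenerate contrast variance is reported by name", {
  const <- clustered_design(data.frame(group = rep(1:2, each = 4),
                                       cluster = rep(1:2, 4), value = 2))
  expect_error(mctp(const, weight_scheme(const),
                    contrast_matrix("tukey", 2)),
               "degenerate variance")
})
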