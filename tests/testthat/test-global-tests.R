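test_that("Wald quadratic form matches a hand-computed pseudo-inverse value", {
  C <- contrast_matrix("centering", 2)
  res <- nparcluster:::.wald_quadform(c(0.6, 0.4), diag(2), C, 20, "wald")
  expect_equal(res$statistic, 0.4, tolerance = 1e-12)
  expect_equal(res$df$df, 1L)
  expect_equal(res$p_value, stats::pchisq(0.4, 1, lower.tail = FALSE))
})

test_that("identical groups give a null Wald statistic; constant data error", {
  set.seed(12)
  block <- data.frame(cluster = rep(1:5, each = 2),
                      value = rnorm(10))
  dat <- rbind(cbind(group = 1, block), cbind(group = 2, block))
  des <- clustered_design(dat)
  sch <- weight_scheme(des)
  fit <- relative_effects(des, sch)
  cov <- effect_covariance(des, sch, fit)
  res <- wald_test(fit, cov, contrast_matrix("centering", 2))
  expect_equal(res$statistic, 0, tolerance = 1e-20)
  expect_equal(res$p_value, 1)

  const <- clustered_design(data.frame(group = rep(1:2, each = 4),
                                       cluster = rep(1:2, 4), value = 1))
  cfit <- relative_effects(const)
  ccov <- effect_covariance(const, weight_scheme(const), cfit)
  expect_error(wald_test(cfit, ccov, contrast_matrix("centering", 2)),
               "degenerate")
  expect_error(anova_test(const, weight_scheme(const), cfit, ccov,
                          contrast_matrix("centering", 2)),
               "degenerate")
})

test_that("ANOVA-type F test reduces to Brunner-Munzel for two unclustered samples", {
  set.seed(21)
  for (b in 1:25) {
    x1 <- round(rnorm(sample(8:14, 1)), 1)
    x2 <- round(rnorm(sample(8:14, 1), 0.4), 1)
    des <- two_sample_design(x1, x2)
    sch <- weight_scheme(des, "weighted")
    fit <- relative_effects(des, sch)
    cov <- effect_covariance(des, sch, fit)
    at <- anova_test(des, sch, fit, cov, contrast_matrix("centering", 2))
    bm <- bm_oracle(x1, x2)
    expect_equal(at$statistic, bm$stat^2, tolerance = 1e-10)
    expect_equal(at$df$f1, 1, tolerance = 1e-10)
    expect_equal(at$df$f2, bm$df, tolerance = 1e-10)
    expect_equal(at$p_value,
                 2 * stats::pt(abs(bm$stat), bm$df, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("chi-squared variant of the ANOVA-type test is more liberal", {
  set.seed(31)
  des <- random_design(d = 3, n_max = 6)
  sch <- weight_scheme(des)
  fit <- relative_effects(des, sch)
  cov <- effect_covariance(des, sch, fit)
  C <- contrast_matrix("centering", 3)
  f <- anova_test(des, sch, fit, cov, C, approx = "F")
  x2 <- anova_test(des, sch, fit, cov, C, approx = "chi2")
  expect_equal(f$statistic, x2$statistic)
  expect_lte(x2$p_value, f$p_value + 1e-12)
})

test_that("quadratic forms depend on the contrast only through its row space", {
  set.seed(41)
  des <- random_design(d = 4, n_max = 6)
  sch <- weight_scheme(des)
  fit <- relative_effects(des, sch)
  cov <- effect_covariance(des, sch, fit)
  C1 <- contrast_matrix("centering", 4)
  C2 <- as_contrast_matrix(2 * unclass(C1)[c(3, 1, 4, 2), ],
                           check_rank = FALSE)
  C3 <- contrast_matrix("tukey", 4)   # same row space as centering
  w1 <- wald_test(fit, cov, C1); w2 <- wald_test(fit, cov, C2)
  a1 <- anova_test(des, sch, fit, cov, C1)
  a2 <- anova_test(des, sch, fit, cov, C2)
  a3 <- anova_test(des, sch, fit, cov, C3)
  expect_equal(w1$statistic, w2$statistic, tolerance = 1e-10)
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-10)
  expect_equal(a1$statistic, a3$statistic, tolerance = 1e-10)
  expect_equal(a1$df$f1, a3$df$f1, tolerance = 1e-10)
})

test_that("test statistics are invariant under monotone transforms", {
  set.seed(51)
  des <- random_design(d = 3, n_max = 6)
  des2 <- clustered_design(data.frame(group = des$obs_group,
                                      cluster = des$obs_cluster,
                                      value = exp(des$x)),
                           group_order = as.character(1:3))
  C <- contrast_matrix("centering", 3)
  res <- lapply(list(des, des2), function(dd) {
    sch <- weight_scheme(dd)
    fit <- relative_effects(dd, sch)
    cov <- effect_covariance(dd, sch, fit)
    c(wald_test(fit, cov, C)$statistic,
      anova_test(dd, sch, fit, cov, C)$statistic,
      h0f_test(dd, sch, C)$statistic)
  })
  expect_identical(res[[1]], res[[2]])
})

test_that("denominator df grows with the number of clusters", {
  set.seed(61)
  for (n0 in c(6, 12, 24)) {
    rows <- data.frame(group = rep(1:2, each = 2 * n0),
                       cluster = rep(rep(1:n0, each = 2), 2),
                       value = rnorm(4 * n0))
    des <- clustered_design(rows)
    sch <- weight_scheme(des)
    fit <- relative_effects(des, sch)
    cov <- effect_covariance(des, sch, fit)
    at <- anova_test(des, sch, fit, cov, contrast_matrix("centering", 2))
    expect_gte(at$df$f2, des$n_total / 4)
  }
})

test_that("tests of equal distribution functions run and detect scale shifts", {
  set.seed(71)
  # equal distributions: moderate p-values expected on average; here we
  # only check validity of the output contract
  des <- random_design(d = 3, n_max = 6)
  sch <- weight_scheme(des)
  C <- contrast_matrix("centering", 3)
  for (tp in c("wald", "anova")) {
    r <- h0f_test(des, sch, C, type = tp)
    expect_gte(r$statistic, 0)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
  expect_error(h0f_test(toy_design(), C = contrast_matrix("centering", 2)),
               ">=2 clusters")
})
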