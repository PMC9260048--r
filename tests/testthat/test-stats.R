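test_that("two-level repeated-measures ANOVA reduces to the paired t-test", {
  # toy triple: rows (1,2), (2,4), (3,6); paired t = 2*sqrt(3), F = t^2 = 12
  a <- rm_anova_network(rbind(c(1, 2), c(2, 4), c(3, 6)))
  expect_equal(a$F, 12)
  expect_equal(c(a$df_effect, a$df_error), c(1, 2))
  expect_equal(a$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  # property over random instances
  for (seed in 1:25) {
    m <- with_seed(seed, matrix(rnorm(2 * sample(3:12, 1)), ncol = 2))
    t_or <- t.test(m[, 1], m[, 2], paired = TRUE)
    a <- rm_anova_network(m)
    expect_equal(a$F, unname(t_or$statistic)^2, tolerance = 1e-9)
    expect_equal(a$p, t_or$p.value, tolerance = 1e-9)
  }
})

test_that("ANOVA decomposition matches aov's within-subject error stratum", {
  for (seed in 1:5) {
    n <- 7; k <- 8
    m <- with_seed(seed, matrix(rnorm(n * k, sd = 3), n, k))
    d <- data.frame(y = as.vector(m),
                    subject = factor(rep(seq_len(n), k)),
                    level = factor(rep(seq_len(k), each = n)))
    fit <- summary(aov(y ~ level + Error(subject / level), data = d))
    tab <- fit[["Error: subject:level"]][[1]]
    a <- rm_anova_network(m)
    expect_equal(a$F, tab["level", "F value"], tolerance = 1e-9)
    expect_equal(a$p, tab["level", "Pr(>F)"], tolerance = 1e-9)
    expect_equal(a$df_error, tab["Residuals", "Df"])
  }
})

test_that("ANOVA edge cases: null effects, location shifts, degeneracy", {
  m <- with_seed(1, matrix(rnorm(6), 6, 1))[, c(1, 1, 1)]  # identical columns
  expect_warning(a <- rm_anova_network(m), "zero within-subject error")
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # location invariance
  m2 <- with_seed(2, matrix(rnorm(40), 8, 5))
  expect_equal(rm_anova_network(m2)$F, rm_anova_network(m2 + 17)$F,
               tolerance = 1e-9)
  # perfectly consistent effect with zero error: F = +Inf, p = 0
  m3 <- cbind(1:4, (1:4) + 1)
  expect_warning(a3 <- rm_anova_network(m3), "Inf")
  expect_equal(a3$F, Inf)
  expect_equal(a3$p, 0)
  expect_error(rm_anova_network(matrix(1:2, 1)), "at least 2")
  # partial eta squared stays in [0, 1]
  expect_true(rm_anova_network(m2)$eta_sq >= 0 &&
                rm_anova_network(m2)$eta_sq <= 1)
})

test_that("Tukey post hocs reduce to the paired comparison at k = 2", {
  for (seed in 1:25) {
    m <- with_seed(seed + 100, matrix(rnorm(2 * sample(3:10, 1)), ncol = 2))
    ph <- tukey_posthoc(m)
    expect_equal(nrow(ph), 1L)
    expect_equal(ph$p_tukey, ph$p_raw, tolerance = 1e-9)
  }
})

test_that("Tukey adjustment never reduces the raw p at k >= 3", {
  for (seed in 1:10) {
    k <- with_seed(seed, sample(3:8, 1))
    m <- with_seed(seed + 7, matrix(rnorm(6 * k), 6, k))
    ph <- tukey_posthoc(m)
    expect_equal(nrow(ph), choose(k, 2))
    expect_true(all(ph$p_tukey >= ph$p_raw - 1e-12))
    expect_true(all(ph$p_tukey >= 0 & ph$p_tukey <= 1))
  }
  # eight levels give the 28 network pairs
  m8 <- with_seed(3, matrix(rnorm(48), 6, 8,
                            dimnames = list(NULL, network_labels())))
  expect_equal(nrow(tukey_posthoc(m8)), 28L)
})

test_that("identical columns give all adjusted p = 1", {
  m <- with_seed(4, matrix(rnorm(5), 5, 4))
  expect_warning(ph <- tukey_posthoc(m), "zero error variance")
  expect_true(all(ph$p_tukey == 1))
  expect_true(all(ph$mean_diff == 0))
})

test_that("paired target contrasts follow hand arithmetic", {
  b <- c(10, 20, 30)
  res <- paired_target_contrast(b + c(1, 2, 3), b)
  expect_equal(res$T, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(res$df, 2)
  # null: a = b
  expect_equal(paired_target_contrast(b, b), list(T = 0, df = 2, p = 1))
  # constant nonzero difference: zero variance -> error
  expect_error(paired_target_contrast(b + 5, b), "zero variance")
  expect_error(paired_target_contrast(1:2, 1:2), "at least 3")
})

test_that("pearson_r matches hand covariance arithmetic", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("statistics are invariant to subject (row) permutation", {
  m <- with_seed(9, matrix(runif(48, 0, 100), 6, 8))
  perm <- with_seed(10, sample(6))
  expect_equal(rm_anova_network(m)$F, rm_anova_network(m[perm, ])$F,
               tolerance = 1e-9)
  expect_equal(tukey_posthoc(m)$p_tukey, tukey_posthoc(m[perm, ])$p_tukey,
               tolerance = 1e-9)
})
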