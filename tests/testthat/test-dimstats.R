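test_that("PCA eigenvalues match the 2x2 closed form and conserve the trace", {
  # two standardized items with correlation r have eigenvalues 1+r, 1-r
  set.seed(8)
  n <- 4000
  z <- rnorm(n)
  x1 <- 0.7071 * z + 0.7071 * rnorm(n)
  x2 <- 0.7071 * z + 0.7071 * rnorm(n)
  df <- data.frame(I1 = x1, I2 = x2)
  ev <- pca_eigen(df, c("I1", "I2"))
  r <- cor(x1, x2)
  expect_equal(ev, c(1 + r, 1 - r), tolerance = 1e-9)
  expect_equal(sum(ev), 2, tolerance = 1e-9)

  expect_error(pca_eigen(data.frame(I1 = rep(1, 5), I2 = 1:5),
                         c("I1", "I2")), "constant")
})

test_that("one-factor cohorts satisfy the eigenvalue-ratio rule", {
  coh <- archetype_cohort(2000, seed = 17)
  ev <- pca_eigen(coh, panss_scale()$subscales$Positive)
  expect_equal(sum(ev), 7, tolerance = 1e-9)
  expect_gte(eigen_ratio_verdict(ev[1], ev[2])$ratio, 3)
})

test_that("eigenvalue-ratio verdicts reproduce printed cells", {
  expect_equal(eigen_ratio_verdict(3.172, 0.949),
               list(ratio = 3.342, unidimensional = TRUE))
  expect_equal(eigen_ratio_verdict(4.080, 2.130),
               list(ratio = 1.915, unidimensional = FALSE))
  expect_equal(eigen_ratio_verdict(1, 1),
               list(ratio = 1, unidimensional = FALSE))
  expect_error(eigen_ratio_verdict(1, 0), "positive")
})

test_that("Bartlett sphericity matches hand arithmetic", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  out <- bartlett_sphericity(R, 100)
  expect_equal(out$statistic, 28.049, tolerance = 1e-3)
  expect_equal(out$df, 1)
  expect_lt(out$p_value, 1e-6)

  id <- diag(3)
  out_id <- bartlett_sphericity(id, 50)
  expect_equal(out_id$statistic, 0)
  expect_equal(out_id$p_value, 1)

  expect_gt(bartlett_sphericity(R, 1000)$statistic, out$statistic)
})

test_that("KMO equals 0.5 for two variables and exceeds 0.6 for one factor", {
  R2 <- matrix(c(1, 0.37, 0.37, 1), 2)
  expect_equal(kmo(R2), 0.5, tolerance = 1e-12)

  R7 <- matrix(0.6, 7, 7); diag(R7) <- 1
  expect_gt(kmo(R7), 0.6)
})

test_that("Cronbach's alpha follows the variance decomposition", {
  # sample variances 1, covariance 0.5 by construction
  df <- data.frame(a = c(-1, 0, 1), b = c(-1, 1, 0))
  expect_equal(cronbach_alpha(df, c("a", "b")), 2 / 3, tolerance = 1e-12)

  dup <- data.frame(x = 1:6, y = 1:6, z = 1:6)
  expect_equal(cronbach_alpha(dup, c("x", "y", "z")), 1)

  set.seed(12)
  indep <- as.data.frame(matrix(rnorm(5000 * 4), ncol = 4))
  expect_lt(abs(cronbach_alpha(indep, names(indep))), 0.1)

  expect_error(cronbach_alpha(df, "a"), "at least 2")
})

test_that("alpha grows with item count on a one-factor cohort", {
  coh <- archetype_cohort(1500, seed = 23)
  items <- panss_scale()$items
  alphas <- vapply(c(3, 7, 16), function(k)
    cronbach_alpha(coh, items[seq_len(k)]), 0)
  expect_true(all(diff(alphas) > 0))
})

test_that("subsample comparison finds no difference between random halves", {
  cfg <- panss_cohort_config(3000, seed = 31, covariates = TRUE)
  halves <- split_sample(simulate_cohort(cfg), seed = 5)
  rep <- compare_subsamples(halves$evaluation, halves$validation)
  expect_true(all(abs(rep$continuous$cohen_d) < 0.1))
  expect_true(all(rep$continuous$df ==
                    nrow(halves$evaluation) + nrow(halves$validation) - 2))
  expect_true(all(rep$categorical$cramer_phi < 0.1))

  # identical groups: exact zeros
  same <- compare_subsamples(halves$evaluation, halves$evaluation)
  expect_true(all(abs(same$continuous$t) < 1e-12))
  expect_true(all(abs(same$continuous$cohen_d) < 1e-12))
  expect_true(all(same$categorical$chisq < 1e-12))
})

test_that("the dimensionality report bundles PCA, Bartlett and KMO", {
  coh <- archetype_cohort(1200, seed = 19)
  rep <- dimensionality_report(coh, panss_scale()$subscales$Negative)
  expect_true(rep$unidimensional)
  expect_lt(rep$bartlett_p, 0.001)
  expect_gt(rep$kmo, 0.6)
  expect_equal(rep$ratio, round(rep$eigen1 / rep$eigen2, 3))
})
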