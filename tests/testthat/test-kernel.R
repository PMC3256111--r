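test_that("latent scores are standard-normal quantiles of mid-ranks", {
  sc <- tiny_scale()
  one <- ratings_from_matrix(matrix(3L, 1, 3), sc)
  expect_equal(latent_scores(one, sc$items)$theta, 0)

  # distinct totals at N=3: quantiles at 1/4, 2/4, 3/4
  m <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  ls <- latent_scores(ratings_from_matrix(m, sc), sc$items)
  expect_equal(ls$theta, c(-0.6744898, 0, 0.6744898), tolerance = 1e-6)

  # tied totals share theta, and theta is nondecreasing in the total
  m4 <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1), c(3, 3, 3))
  ls4 <- latent_scores(ratings_from_matrix(m4, sc), sc$items)
  expect_equal(ls4$theta[2], ls4$theta[3])
  expect_true(all(diff(ls4$theta[order(ls4$summed)]) >= 0))
})

test_that("the default bandwidth follows 1.1 N^(-1/5)", {
  expect_equal(default_bandwidth(100), 0.4379179, tolerance = 1e-6)
  expect_equal(default_bandwidth(3594), 0.2139326, tolerance = 1e-6)
  expect_lt(default_bandwidth(1e7), default_bandwidth(100))
  expect_error(default_bandwidth(1), "at least 2")
})

test_that("kernel OCC estimates equal the brute-force weighted average", {
  grid <- latent_grid(11)
  values <- c(1L, 4L, 4L, 7L, 2L)
  theta <- c(-1.3, -0.2, 0.1, 1.7, 0.4)
  P <- estimate_occ(values, theta, grid, h = 0.5)
  expect_lt(max(abs(P - occ_brute(values, theta, grid, 0.5))), 1e-12)

  # constant responses give a degenerate curve
  Pc <- estimate_occ(rep(4L, 6), rnorm(6), grid, h = 0.3)
  expect_equal(Pc[, "4"], rep(1, 11))
  expect_true(all(Pc[, colnames(Pc) != "4"] == 0))

  # symmetric subjects at +-1 with options 1 and 7, evaluated at 0
  Ps <- estimate_occ(c(1L, 7L), c(-1, 1), grid = 0, h = 1)
  expect_equal(unname(drop(Ps)), c(0.5, 0, 0, 0, 0, 0, 0.5))

  expect_error(estimate_occ(c(1L, NA), c(0, 1), grid, 0.5), "complete")
  expect_error(estimate_occ(1L, 0, grid, 0), "positive")
})

test_that("ICC moments follow from the option probabilities", {
  degenerate <- matrix(0, 5, 7, dimnames = list(NULL, 1:7))
  degenerate[, 4] <- 1
  icc <- icc_from_occ(degenerate)
  expect_equal(icc$e, rep(4, 5))
  expect_equal(icc$v, rep(0, 5))

  two_point <- matrix(0, 1, 7, dimnames = list(NULL, 1:7))
  two_point[1, 1] <- 0.5; two_point[1, 7] <- 0.5
  expect_equal(icc_from_occ(two_point), data.frame(e = 4, v = 9))

  unif <- matrix(1 / 7, 1, 7, dimnames = list(NULL, 1:7))
  expect_equal(icc_from_occ(unif), data.frame(e = 4, v = 4))
})

test_that("expected subscale score sums ICCs and is isotonic", {
  grid <- latent_grid(21)
  const <- replicate(7, data.frame(e = rep(1, 21), v = 0), simplify = FALSE)
  expect_equal(expected_subscale_score(const, grid), rep(7, 21))
  const7 <- replicate(7, data.frame(e = rep(7, 21), v = 0), simplify = FALSE)
  expect_equal(expected_subscale_score(const7, grid), rep(49, 21))

  inc <- replicate(7, data.frame(e = 4 + 0.4 * grid, v = 1),
                   simplify = FALSE)
  expect_true(all(diff(expected_subscale_score(inc, grid)) > 0))

  # a local dip is projected away
  wig <- list(data.frame(e = c(1, 2, 1.8, 3, 4, rep(4, 16)), v = 1))
  proj <- expected_subscale_score(wig, grid)
  expect_true(all(diff(proj) >= 0))

  expect_error(expected_subscale_score(list(data.frame(e = 1:3, v = 1)),
                                       grid), "share")
})

test_that("item information is squared ICC slope over conditional variance", {
  grid <- latent_grid(31)
  flat <- data.frame(e = rep(4, 31), v = rep(1, 31))
  expect_equal(item_information(flat, grid), rep(0, 31))

  lin <- data.frame(e = 4 + 0.5 * grid, v = rep(1, 31))
  expect_equal(item_information(lin, grid), rep(0.25, 31))

  lin2 <- data.frame(e = 4 + 1.0 * grid, v = rep(1, 31))
  expect_equal(item_information(lin2, grid),
               4 * item_information(lin, grid))

  degen <- data.frame(e = rep(4, 31), v = rep(0, 31))
  expect_equal(item_information(degen, grid), rep(0, 31))
})

test_that("summed-score SE is the root of summed conditional variances", {
  grid <- latent_grid(11)
  degen <- replicate(7, data.frame(e = 4, v = rep(0, 11)), simplify = FALSE)
  expect_equal(summed_score_se(degen), rep(0, 11))

  iccs <- replicate(7, data.frame(e = 4, v = rep(9 / 7, 11)),
                    simplify = FALSE)
  expect_equal(summed_score_se(iccs), rep(3, 11))
  expect_equal(summed_score_se(rev(iccs)), summed_score_se(iccs))
})

test_that("score density obeys the change of variables and integrates to 1", {
  grid <- latent_grid(101)
  theta <- qnorm(ppoints(20000))
  d <- score_density(theta, 28 + 7 * grid, grid, h = 0.12)
  sel <- abs(grid) <= 2
  expect_lt(max(abs(d$density[sel] - dnorm(d$score[sel], 28, 7))), 5e-3)
  area <- sum(diff(d$score) * (d$density[-1] + d$density[-101]) / 2)
  expect_equal(area, 1, tolerance = 1e-3)

  expect_error(score_density(theta, rep(10, 101), grid, h = 0.12), "flat")
})

test_that("ICC slope is evaluated at the median-option crossing", {
  grid <- latent_grid()
  lin <- data.frame(e = 4 + 0.5 * grid, v = 1)
  expect_equal(icc_slope_at_median(lin, grid, 4), 0.5)

  par <- data.frame(e = 4 + grid^2, v = 1)
  expect_equal(icc_slope_at_median(par, grid, 4), 0)

  const <- data.frame(e = rep(2.2, 51), v = 1)
  expect_equal(icc_slope_at_median(const, grid, 4), 0)
})

test_that("item-total correlation is Pearson with the summed score", {
  sc <- tiny_scale(1)
  x <- c(1L, 3L, 5L, 7L, 2L)
  expect_equal(item_total_correlation(x, x), 1)
  set.seed(2)
  tot <- sample(7:21, 30, TRUE)
  v <- sample(1:7, 30, TRUE)
  expect_equal(item_total_correlation(v, tot), cor(v, tot))
  expect_equal(item_total_correlation(8 - v, tot),
               -item_total_correlation(v, tot))
  expect_true(is.na(item_total_correlation(rep(3L, 5), 1:5)))
})

test_that("the ksirt fit bundles coherent curves and methods", {
  coh <- archetype_cohort(400, seed = 21)
  fit <- ksirt(coh, subscale = "Positive")
  expect_s3_class(fit, "ksirt")
  expect_equal(fit$bandwidth, default_bandwidth(400))
  expect_length(fit$occ, 7)
  expect_true(all(diff(fit$curves$T) >= 0))
  expect_true(all(fit$curves$se >= 0))
  expect_named(coef(fit), fit$items)
  expect_equal(predict(fit, 0), approx(fit$grid, fit$curves$T, 0)$y)
  expect_equal(dim(predict(fit, c(-1, 0, 1), type = "items")), c(3, 7))
  expect_output(print(fit), "Positive subscale")
  expect_output(print(summary(fit)), "Item diagnostics")
})

test_that("information of a flat item lies below an ideal item's", {
  grid <- latent_grid()
  sel <- grid >= -2 & grid <= 2
  I_ideal <- item_information(
    icc_from_occ(true_occ(make_archetype("ideal"), grid)), grid)
  I_flat <- item_information(
    icc_from_occ(true_occ(make_archetype("flat"), grid)), grid)
  expect_true(all(I_flat[sel] < I_ideal[sel]))
})
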