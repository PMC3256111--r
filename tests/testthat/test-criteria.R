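grid <- latent_grid()

test_that("criterion 1 counts option levels reached by the ICC maximum", {
  icc_62 <- data.frame(e = seq(1, 6.2, length.out = 51), v = 1)
  expect_equal(criterion1_options_used(icc_62),
               list(count = 6L, rating = "Yes"))
  icc_44 <- data.frame(e = seq(1, 4.4, length.out = 51), v = 1)
  expect_equal(criterion1_options_used(icc_44),
               list(count = 4L, rating = "No"))
})

test_that("criterion 2 separates rapid, late and absent option rises", {
  ideal <- true_occ(make_archetype("ideal"), grid)
  T_ideal <- 7 * icc_from_occ(ideal)$e
  expect_equal(criterion2_rapid_increase(ideal, T_ideal, grid), "Yes")

  # evenly spread low-discrimination curves: every non-extreme option <= 0.3
  flat_even <- true_occ(grm_item(0.3, seq(-5.5, 5.5, length.out = 6)), grid)
  expect_lte(max(flat_even[, 2:6]), 0.3)
  expect_equal(criterion2_rapid_increase(
    flat_even, 7 * icc_from_occ(flat_even)$e, grid), "No")

  # thresholds shifted up: rises only above the median expected score
  shifted <- true_occ(grm_item(1.8, seq(-2, 2, length.out = 6) + 1.5), grid)
  expect_equal(criterion2_rapid_increase(
    shifted, 7 * icc_from_occ(shifted)$e, grid), "Somewhat")
})

test_that("criterion 3 counts modal-region ordering violations", {
  ideal <- true_occ(make_archetype("ideal"), grid)
  expect_equal(criterion3_region_ordering(ideal, grid),
               list(violations = 0L, rating = "Yes"))

  dis <- true_occ(make_archetype("disordered_regions"), grid)
  res <- criterion3_region_ordering(dis, grid)
  expect_gte(res$violations, 1)
  expect_true(res$rating %in% c("Somewhat", "No"))

  degenerate <- matrix(0, 51, 7, dimnames = list(NULL, 1:7))
  degenerate[, 4] <- 1
  expect_equal(criterion3_region_ordering(degenerate, grid)$violations, 6L)
  expect_equal(criterion3_region_ordering(degenerate, grid)$rating, "No")
})

test_that("criterion 4 flags displaced or missing option supports", {
  ideal <- true_occ(make_archetype("ideal"), grid)
  T_ideal <- 7 * icc_from_occ(ideal)$e
  expect_equal(criterion4_span(ideal, T_ideal, grid),
               list(displaced = 0L, rating = "Yes"))

  flat <- true_occ(make_archetype("flat"), grid)
  res <- criterion4_span(flat, 7 * icc_from_occ(flat)$e, grid)
  expect_gte(res$displaced, 4)
  expect_equal(res$rating, "No")

  degenerate <- matrix(0, 51, 7, dimnames = list(NULL, 1:7))
  degenerate[, 4] <- 1
  expect_equal(criterion4_span(degenerate, rep(28, 51) + seq(0, 1, length.out = 51),
                               grid)$displaced, 6L)
})

test_that("criterion 5 applies the 0.40 slope cut inclusively", {
  expect_equal(criterion5_slope(0.510), "Yes")
  expect_equal(criterion5_slope(0.382), "No")
  expect_equal(criterion5_slope(0.40), "Yes")
})

test_that("the Yes-count rule classifies and never punishes improvement", {
  expect_equal(classify_item(c("Yes", "Somewhat", "Somewhat", "Yes", "Yes")),
               list(yes_count = 3L, rating = "Good", retained = TRUE))
  expect_equal(classify_item(c("Yes", "Yes", "Yes", "Yes", "No"))$rating,
               "Very Good")
  expect_equal(classify_item(rep("No", 5)),
               list(yes_count = 0L, rating = "Weak", retained = FALSE))

  # monotonicity over the full rating lattice: upgrading any single
  # criterion never lowers the global class
  lv <- c(No = 1, Somewhat = 2, Yes = 3)
  cls_rank <- c(Weak = 1, Good = 2, "Very Good" = 3)
  combos <- expand.grid(c1 = c("No", "Yes"), c2 = names(lv), c3 = names(lv),
                        c4 = c("No", "Yes"), c5 = c("No", "Yes"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    base <- unlist(combos[i, ])
    r0 <- cls_rank[classify_item(base)$rating]
    for (j in 1:5) {
      up <- base
      if (lv[up[j]] < 3) {
        up[j] <- "Yes"
        expect_gte(cls_rank[classify_item(up)$rating], r0)
      }
    }
  }
})

test_that("short-form selection keeps non-Weak items within their subscales", {
  sc <- panss_scale()
  fx <- load_criteria_fixture()
  cls <- data.frame(item = fx$item, retained = fx$rating != "Weak")
  short <- select_short_form(cls, sc)
  expect_length(short$items, 19)
  expect_equal(vapply(short$subscales, length, 0L),
               c(Positive = 6L, Negative = 6L, General = 7L))
  expect_true(all(unlist(short$subscales) %in% sc$items))

  all_in <- data.frame(item = sc$items, retained = TRUE)
  expect_equal(select_short_form(all_in, sc)$items, sc$items)

  none_neg <- data.frame(item = sc$items,
                         retained = !grepl("^N", sc$items))
  expect_error(select_short_form(none_neg, sc), "Negative")
})

test_that("criterion tallies report Yes counts and percentages", {
  fx <- load_criteria_fixture()
  expect_equal(criterion_counts(fx, "General", 2),
               list(count = 7L, percent = 43.75))
  expect_error(criterion_counts(fx, "Unknown", 2), "no items")
})

test_that("estimated criteria rate ideal items Very Good and flat Weak", {
  coh <- archetype_cohort(3000, seed = 2, weak = c(P7 = "flat"))
  fit <- ksirt(coh, subscale = "Positive")
  cls <- item_criteria(fit)
  expect_equal(cls$rating[cls$item == "P7"], "Weak")
  expect_true(all(cls$rating[cls$item != "P7"] == "Very Good"))
  expect_false(cls$retained[cls$item == "P7"])
})
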