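test_that("mode-transition link has its logistic anchor points", {
  p <- learner_params(capacity = 8.4, slope = 2)
  expect_equal(p_category_mode(8.4, p), 0.5)
  expect_gt(p_category_mode(20, learner_params(capacity = 8.4,
                                               slope = 50)), 0.999)
  flat <- learner_params(capacity = 8.4, slope = 0)
  expect_equal(p_category_mode(c(0, 5, 15), flat), rep(0.5, 3))
  # monotone nondecreasing in H'
  hs <- seq(0, 20, by = 0.5)
  expect_true(all(diff(p_category_mode(hs, p)) >= 0))
  expect_error(p_category_mode(-1, p), ">= 0")
})

test_that("pure XXY modes produce their defining accuracy patterns", {
  fx <- xxy_fixture()
  bat <- generate_test_battery(fx$grammar, xxy_novel_fixture(fx), seed = 42)
  nolapse <- learner_params(lapse = 0)

  cat_r <- simulate_responses_xxy(bat, 7, nolapse, seed = 1,
                                  mode = "CATEGORY_BASED")
  expect_true(all(cat_r$correct))

  ib <- simulate_responses_xxy(bat, 7, nolapse, seed = 1,
                               mode = "ITEM_BOUND")
  expect_true(all(ib$correct[ib$test_type == "FAM_XXY"]))
  # item-bound NEW_XXY acceptance sits at the profile's base level
  many <- do.call(rbind, lapply(1:300, function(s)
    simulate_responses_xxy(bat, 7, nolapse, seed = s, mode = "ITEM_BOUND")))
  new_acc <- mean(many$response[many$test_type == "NEW_XXY"] == "accept")
  expect_equal(new_acc, default_mode_profiles()$ITEM_BOUND[["NEW_XXY"]],
               tolerance = 0.05)
})

test_that("faster source rates raise NEW_XXY acceptance across seeds", {
  fx <- xxy_fixture()
  bat <- generate_test_battery(fx$grammar, xxy_novel_fixture(fx), seed = 42)
  p <- learner_params(capacity = 6, slope = 2)
  h_slow <- 4.45
  h_fast <- 1.71 * h_slow
  acc <- vapply(c(slow = h_slow, fast = h_fast), function(h) {
    r <- do.call(rbind, lapply(1:150, function(s)
      simulate_responses_xxy(bat, h, p, seed = 1000 + s)))
    mean(r$response[r$test_type == "NEW_XXY"] == "accept")
  }, numeric(1))
  expect_gt(acc["fast"], acc["slow"])
})

test_that("pure aXb modes produce their defining accuracy patterns", {
  ax <- axb_fixture()
  bat <- generate_test_battery(ax$grammar, ax$novel_x, seed = 5)
  nolapse <- learner_params(lapse = 0)

  ver <- simulate_responses_axb(bat, 5, nolapse, seed = 1, mode = "VERIDICAL")
  expect_true(all(ver$correct))

  over0 <- learner_params(lapse = 0, drift = 0)
  ov <- simulate_responses_axb(bat, 5, over0, seed = 1,
                               mode = "OVERGENERALIZER")
  expect_true(all(ov$response == "accept"))
  expect_equal(mean(ov$correct), 0.5)
})

test_that("overgeneralizers with positive drift accept more early than late", {
  ax <- axb_fixture()
  bat <- generate_test_battery(ax$grammar, ax$novel_x, seed = 5)
  p <- learner_params(lapse = 0, drift = 0.08)
  r <- do.call(rbind, lapply(1:200, function(s) {
    out <- simulate_responses_axb(bat, 5, p, seed = s,
                                  mode = "OVERGENERALIZER")
    out$participant_id <- s
    out$trial_index <- out$item_index
    out$answer <- out$response
    out
  }))
  tr <- positional_acceptance_trend(r)
  expect_gt(tr$early_mean, tr$late_mean)
  expect_lt(tr$p.value, 0.01)
})

test_that("maximal lapse and guessing pin every accuracy at chance", {
  fx <- xxy_fixture()
  bat <- generate_test_battery(fx$grammar, xxy_novel_fixture(fx), seed = 42)
  # lapse -> 0.5 mixes every response to a fair coin
  coin <- learner_params(lapse = 0.4999)
  r <- do.call(rbind, lapply(1:300, function(s)
    simulate_responses_xxy(bat, 7, coin, seed = s, mode = "ITEM_BOUND")))
  by_type <- tapply(r$correct, r$test_type, mean)
  expect_equal(unname(by_type), rep(0.5, 4), tolerance = 0.03,
               ignore_attr = TRUE)

  ax <- axb_fixture()
  bat_a <- generate_test_battery(ax$grammar, ax$novel_x, seed = 5)
  g <- do.call(rbind, lapply(1:300, function(s)
    simulate_responses_axb(bat_a, 5, learner_params(lapse = 0), seed = s,
                           mode = "GUESS")))
  expect_equal(mean(g$correct), 0.5, tolerance = 0.03)
})

test_that("simulate_cohort yields the designed row counts, reproducibly", {
  fx <- xxy_fixture()
  nov <- xxy_novel_fixture(fx)
  ax <- axb_fixture("low", "L1")
  conds <- list(
    xxy_slow = cohort_condition("xxy", fx$grammar, xxy_timing(), 28, nov),
    xxy_fast = cohort_condition("xxy", fx$grammar, xxy_timing(), 28, nov,
                                speed_factor = 1.71),
    axb_slow = cohort_condition("axb", ax$grammar, axb_timing(), 29,
                                ax$novel_x),
    axb_fast = cohort_condition("axb", ax$grammar, axb_timing(), 28,
                                ax$novel_x, speed_factor = 1.34))
  co <- simulate_cohort(conds, learner_params(), master_seed = 11)
  expect_equal(sum(co$responses$experiment == "xxy"), 56 * 20)
  expect_equal(sum(co$responses$experiment == "axb"), 57 * 12)
  expect_equal(nrow(co$covariates), 113)
  expect_true(all(co$covariates$memo_hits <= 13 & co$covariates$memo_fas <= 13))
  expect_true(all(co$covariates$digit_span >= 2))

  co2 <- simulate_cohort(conds, learner_params(), master_seed = 11)
  expect_identical(co$responses, co2$responses)
  expect_identical(co$covariates, co2$covariates)

  # sped conditions carry proportionally higher source rates
  meta <- co$conditions
  expect_equal(meta$h_prime[meta$condition == "xxy_fast"],
               1.71 * meta$h_prime[meta$condition == "xxy_slow"],
               tolerance = 1e-9)

  tidy <- export_tidy_responses(co)
  expect_equal(nrow(tidy), nrow(co$responses))
  expect_true(all(c("digit_span", "ravens_percentile") %in% names(tidy)))
})
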