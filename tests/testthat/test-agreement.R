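test_that("identical readings give zero bias and degenerate limits", {
  pr <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                   sv_ref = c(100, 90, 80, 95, 85, 75))
  pr$sv_dev <- pr$sv_ref
  a <- bland_altman_repeated(pr)
  expect_equal(a$bias, 0)
  expect_equal(a$sd_diff, 0)
  expect_equal(c(a$loa_low, a$loa_high), c(0, 0))
  expect_equal(a$percentage_error, 0)
  expect_false(a$suppressed)
})

test_that("pooled statistics match hand computation on two subjects", {
  pr <- data.frame(subject_id = c("a", "a", "b", "b"),
                   sv_ref = c(100, 100, 100, 100),
                   sv_dev = c(90, 95, 80, 85))
  a <- bland_altman_repeated(pr, method = "pooled_naive")
  expect_equal(a$bias, -12.5)
  expect_equal(a$sd_diff, sqrt(125 / 3), tolerance = 1e-12)  # ~6.455
  expect_equal(a$loa_low, -12.5 - 1.96 * sqrt(125 / 3), tolerance = 1e-12)
  expect_equal(a$loa_high, -12.5 + 1.96 * sqrt(125 / 3), tolerance = 1e-12)
})

test_that("variance components widen the limits when subjects differ", {
  # toy cohort: MSW = 45.25, MSB = 90.25, n0 = 2 -> sd^2 = 67.75
  toy <- toy_cohort()
  a <- bland_altman_repeated(data.frame(subject_id = toy$subject_id,
                                        sv_ref = toy$sv_ref,
                                        sv_dev = toy$sv_probe))
  expect_equal(a$bias, -0.25)
  expect_equal(a$sd_diff, sqrt(67.75), tolerance = 1e-12)
  expect_identical(a$method, "repeated_varying")
})

test_that("repeated_varying equals pooled_naive with one pair per subject", {
  set.seed(31)
  pr <- data.frame(subject_id = sprintf("s%02d", 1:12),
                   sv_ref = runif(12, 60, 110))
  pr$sv_dev <- pr$sv_ref + rnorm(12, -3, 6)
  a <- bland_altman_repeated(pr, "repeated_varying")
  b <- bland_altman_repeated(pr, "pooled_naive")
  expect_equal(a$sd_diff, b$sd_diff)
  expect_equal(a$bias, b$bias)
  expect_true("SUBJECTS_WITH_SINGLE_OBSERVATION" %in% a$warnings)
})

test_that("a single subject falls back to the pooled estimator", {
  pr <- data.frame(subject_id = "only", sv_ref = c(100, 90, 80),
                   sv_dev = c(96, 92, 78))
  a <- bland_altman_repeated(pr, "repeated_varying")
  expect_identical(a$method, "pooled_naive")
  expect_true("FELL_BACK_TO_POOLED_SINGLE_SUBJECT" %in% a$warnings)
})

test_that("bias is invariant to row permutation", {
  set.seed(8)
  pr <- data.frame(subject_id = rep(letters[1:5], each = 4),
                   sv_ref = runif(20, 50, 110))
  pr$sv_dev <- pr$sv_ref + rnorm(20, 2, 5)
  a <- bland_altman_repeated(pr)
  b <- bland_altman_repeated(pr[sample(nrow(pr)), ])
  expect_equal(a$bias, b$bias)
  expect_equal(a$sd_diff, b$sd_diff)
})

test_that("a known additive offset is recovered within 2 SE", {
  p <- protocol_config(seed = 17)
  co <- simulate_cohort(p, list(device_model("x", slope = 1, offset = 7,
                                             noise_sd = 5,
                                             trend_noise_sd = 0)))
  a <- bland_altman_repeated(data.frame(subject_id = co$subject_id,
                                        sv_ref = co$sv_ref,
                                        sv_dev = co$sv_x))
  se <- a$sd_diff / sqrt(a$n_pairs)
  expect_lt(abs(a$bias - 7), 2 * se)
})

test_that("percentage error follows its definition and scale invariance", {
  expect_equal(percentage_error(0, 80), 0)
  expect_equal(percentage_error(18.67, 104.6), 100 * 1.96 * 18.67 / 104.6)
  expect_equal(percentage_error(18.67, 104.6), 34.98, tolerance = 1e-3)
  expect_equal(percentage_error(100 / 1.96, 100), 100)
  # homogeneous of degree 0: scaling every SV leaves it unchanged
  expect_equal(percentage_error(3 * 12, 3 * 90), percentage_error(12, 90))
  expect_error(percentage_error(5, 0), "mean_ref")
  expect_error(percentage_error(-1, 10), "sd_diff")
})

test_that("limits are suppressed only under significant proportional bias", {
  p <- protocol_config(seed = 2)
  co <- simulate_cohort(p, list(device_teb(), device_ssd()))
  teb <- suppress_loa_if_proportional(
    bland_altman_repeated(data.frame(subject_id = co$subject_id,
                                     sv_ref = co$sv_ref,
                                     sv_dev = co$sv_teb)))
  expect_true(teb$suppressed)
  expect_true(is.na(teb$loa_low) && is.na(teb$percentage_error))

  teb_raw <- bland_altman_repeated(data.frame(subject_id = co$subject_id,
                                              sv_ref = co$sv_ref,
                                              sv_dev = co$sv_teb))
  ssd <- bland_altman_repeated(data.frame(subject_id = co$subject_id,
                                          sv_ref = co$sv_ref,
                                          sv_dev = co$sv_ssd))
  expect_lt(abs(ssd$bias), 2)
  # a zero threshold is degenerate and never suppresses
  expect_false(suppress_loa_if_proportional(teb_raw, 0)$suppressed)
  # a flat slope (p = 1) is never suppressed
  flat <- teb_raw
  flat$proportional_bias_slope <- 0
  flat$proportional_bias_p <- 1
  expect_false(suppress_loa_if_proportional(flat)$suppressed)
})

test_that("input validation rejects unusable pair sets", {
  expect_error(bland_altman_repeated(data.frame(subject_id = "a",
                                                sv_ref = 1, sv_dev = 2)),
               "at least 2")
  expect_error(bland_altman_repeated(data.frame(subject_id = c("a", "b"),
                                                sv_ref = c(10, -5),
                                                sv_dev = c(9, 5))),
               "positive")
})
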