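test_that("cohort design respects windows, rates and determinism", {
  d <- make_cohort_design(1, 100, age_range = c(0, 100), sex_ratio = 0.5,
                          seed = 1)
  expect_equal(nrow(d), 100)
  expect_true(all(d$age_years >= 0 & d$age_years <= 100))
  expect_false(anyDuplicated(d$subject_id) > 0)

  d0 <- make_cohort_design(3, 50, left_handed_rate = 0, ambidextrous_rate = 0,
                           seed = 2)
  expect_equal(sum(d0$handedness == "left"), 0)

  # each cohort draws only within its own window; union covers the range
  d3 <- make_cohort_design(8, 200, age_range = c(0, 100), seed = 3)
  w <- attr(d3, "age_windows")
  for (ch in rownames(w)) {
    ages <- d3$age_years[d3$cohort_id == ch]
    expect_true(all(ages >= w[ch, 1] & ages <= w[ch, 2]))
  }
  expect_equal(unname(w[1, 1]), 0); expect_equal(unname(w[nrow(w), 2]), 100)
  expect_true(all(sort(w[, 1])[-1] <= sort(w[, 2])[-nrow(w)]))  # overlap

  expect_identical(make_cohort_design(4, 100, seed = 9),
                   make_cohort_design(4, 100, seed = 9))
  expect_error(make_cohort_design(2, 10, age_range = c(0, 120)), "110")
  expect_error(make_cohort_design(2, 10, left_handed_rate = 1.2), "proportion")
})

test_that("left-handed fraction matches the target rate at consortium scale", {
  # 12 cohorts, 14,220 subjects, 9.3% left-handed
  d <- make_cohort_design(12, 1185, left_handed_rate = 0.093, seed = 4)
  expect_equal(nrow(d), 14220)
  p_hat <- mean(d$handedness == "left")
  se <- sqrt(0.093 * (1 - 0.093) / 14220)
  expect_lt(abs(p_hat - 0.093), 3 * se)
})

test_that("trajectory evaluation composes smooth, sex and cohort terms", {
  # constant model
  t0 <- trajectory_truth(mu_powers = 1, mu_coefficients = c(0.1, 0),
                         sigma_powers = 1,
                         sigma_coefficients = c(log(0.05), 0),
                         cohort_ids = "c1")
  ev <- trajectory_eval(t0, c(0, 40, 99), "female", "c1")
  expect_equal(ev$mu, rep(0.1, 3))
  expect_equal(ev$sigma, rep(0.05, 3))

  # linear-in-age: slope 0.001/yr on shifted age, intercept -0.02
  t1 <- trajectory_truth(mu_powers = 1, mu_coefficients = c(-0.02, 0.001),
                         sigma_powers = 1,
                         sigma_coefficients = c(log(0.05), 0),
                         age_offset = 0, cohort_ids = "c1")
  expect_equal(trajectory_eval(t1, 40, "female", "c1")$mu, 0.02)

  # flipping sex shifts mu by exactly the sex effect
  t2 <- trajectory_truth(mu_powers = 1, mu_coefficients = c(0.01, 0),
                         sigma_powers = 1,
                         sigma_coefficients = c(log(0.04), 0),
                         sex_effect_mu = 0.013, cohort_ids = "c1")
  expect_equal(trajectory_eval(t2, 30, "male", "c1")$mu -
                 trajectory_eval(t2, 30, "female", "c1")$mu, 0.013)
  expect_error(trajectory_eval(t2, 30, "female", "nope"), "unknown cohort")
})

test_that("a truth that can leave (-1, 1) warns at construction", {
  expect_warning(
    trajectory_truth(mu_powers = 1, mu_coefficients = c(0.8, 0),
                     sigma_powers = 1, sigma_coefficients = c(log(0.2), 0),
                     cohort_ids = "c1"),
    "truncated")
})

test_that("simulated LI matches the generating distribution", {
  sub <- make_cohort_design(1, 10000, seed = 5)
  t0 <- trajectory_truth(mu_powers = 1, mu_coefficients = c(0, 0),
                         sigma_powers = 1,
                         sigma_coefficients = c(log(0.05), 0),
                         cohort_ids = "cohort_01")
  obs <- simulate_li_observations(sub, t0, seed = 6)
  expect_lt(abs(mean(obs$li)), 3 * 0.05 / sqrt(10000))

  t1 <- trajectory_truth(mu_powers = 1, mu_coefficients = c(0.05, 0),
                         sigma_powers = 1,
                         sigma_coefficients = c(log(0.02), 0),
                         cohort_ids = "cohort_01")
  obs1 <- simulate_li_observations(sub, t1, seed = 7)
  expect_lt(abs(sd(obs1$li) - 0.02) / 0.02, 0.05)  # within 5 percent
  expect_true(all(abs(obs1$li) < 1))

  # bit-identical under the same seed
  expect_identical(obs1, simulate_li_observations(sub, t1, seed = 7))
  expect_false(identical(obs1$li,
                         simulate_li_observations(sub, t1, seed = 8)$li))
})

test_that("cohort offsets realize with the stated spread", {
  tt <- trajectory_truth(mu_powers = 1, mu_coefficients = c(0, 0),
                         sigma_powers = 1,
                         sigma_coefficients = c(log(0.05), 0),
                         cohort_sd_mu = 0.02, cohort_sd_sigma = 0.1,
                         cohort_ids = sprintf("c%03d", 1:60), seed = 12)
  # chi-square bounds on a sample SD of 60 normal draws
  s <- sd(tt$cohort_offsets_mu)
  lo <- 0.02 * sqrt(qchisq(0.0015, 59) / 59)
  hi <- 0.02 * sqrt(qchisq(0.9985, 59) / 59)
  expect_gt(s, lo); expect_lt(s, hi)
  expect_lt(abs(sd(tt$cohort_offsets_sigma) - 0.1), 0.1 * 0.5)
})

test_that("bilateral measures encode the drawn LI exactly", {
  sub <- make_cohort_design(2, 100, seed = 8)
  truth <- fixture_truth(n_cohorts = 2, seed = 9)
  meas <- simulate_bilateral_measures(sub, truth, baseline = 500, seed = 10)
  obs <- simulate_li_observations(sub, truth, seed = 10)

  # same seed protocol: recomputed LI equals the drawn LI
  li_back <- laterality_index(meas$left_value, meas$right_value)
  expect_equal(li_back, obs$li, tolerance = 1e-12)

  # round trip through the laterality-table builder
  tab <- build_laterality_table(meas, sub)
  expect_equal(tab$li, obs$li, tolerance = 1e-12)
  expect_equal(tab$age_years, obs$age_years)

  # arithmetic of the left/right mapping
  expect_equal(meas$right_value + meas$left_value,
               rep(1000, nrow(meas)))  # 2 * baseline
  b <- baseline_profile(500)
  expect_equal(b(c(3, 93)), c(500, 500))
})
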