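test_that("median derivative reproduces analytic derivatives", {
  lin <- analytic_chart(function(a) 0.001 * a)
  d <- median_derivative(lin)
  expect_equal(d$derivative, rep(0.001, 500), tolerance = 1e-10)

  flat <- analytic_chart(function(a) rep(0.02, length(a)))
  expect_equal(median_derivative(flat)$derivative, rep(0, 500))

  wave <- analytic_chart(function(a) sin(a / 20) / 50)
  dw <- median_derivative(wave)
  expect_lt(max(abs(dw$derivative - cos(wave$age_grid / 20) / 1000)), 1e-5)

  short <- analytic_chart(function(a) a, age_grid = c(0, 1))
  expect_error(median_derivative(short), "grid too short")
})

test_that("reversal detection finds sign changes with interpolated ages", {
  lin <- analytic_chart(function(a) (a - 50) / 1000)
  ev <- detect_reversals(lin)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$age_years, 50, tolerance = 1e-6)
  expect_equal(ev$direction, "left_to_right")

  pos <- analytic_chart(function(a) 0.01 + 0.0001 * a)
  expect_equal(nrow(detect_reversals(pos)), 0)

  down <- analytic_chart(function(a) (30 - a) / 1000)
  expect_equal(detect_reversals(down)$direction, "right_to_left")
  expect_equal(detect_reversals(down)$age_years, 30, tolerance = 1e-6)
})

test_that("reversal counts obey sign parity and excursion suppression", {
  # same sign at both ends -> even number of crossings
  s_curve <- analytic_chart(function(a) 0.01 * sin(a / 8))  # many crossings
  ev <- detect_reversals(s_curve)
  m <- s_curve$values[, 1]
  same_sign <- sign(m[1]) == sign(m[length(m)])
  expect_equal(nrow(ev) %% 2 == 0, same_sign)

  # micro-oscillation below the excursion threshold is suppressed
  micro <- analytic_chart(function(a) ifelse(a < 40, -0.05 + 0.001 * a,
                                             1e-5 * sin(a)))
  all_ev <- detect_reversals(micro, min_excursion = 0)
  few_ev <- detect_reversals(micro, min_excursion = 0.005)
  expect_gt(nrow(all_ev), nrow(few_ev))
  expect_equal(nrow(few_ev), 1)  # only the genuine crossing near age 40

  # grid-refinement stability: crossing ages move < 0.25 years
  coarse <- analytic_chart(function(a) (a - 35) / 800,
                           age_grid = seq(0, 100, length.out = 500))
  fine <- analytic_chart(function(a) (a - 35) / 800,
                         age_grid = seq(0, 100, length.out = 2000))
  expect_lt(abs(detect_reversals(coarse)$age_years -
                  detect_reversals(fine)$age_years), 0.25)
})

test_that("epoch slopes quantify the rate of change of |median|", {
  eps <- default_epochs()
  expect_equal(eps$lo, c(2, 5, 12, 20, 40, 60))
  expect_equal(eps$hi, c(5, 12, 20, 40, 60, 100))

  lin <- analytic_chart(function(a) 0.001 * a)
  s <- epoch_slopes(lin)
  expect_equal(s$slope, rep(0.001, 6), tolerance = 1e-9)

  flat <- analytic_chart(function(a) rep(-0.03, length(a)))
  expect_equal(epoch_slopes(flat)$slope, rep(0, 6))

  # V-shaped |median| with vertex at the midlife midpoint (age 50):
  # the midlife slope cancels to ~0 while the two half-epochs carry +/- legs
  v <- analytic_chart(function(a) abs(a - 50) / 1000)
  sv <- epoch_slopes(v)
  expect_lt(abs(sv$slope[sv$epoch == "midlife"]), 2e-5)
  halves <- data.frame(name = c("down", "up"), lo = c(40, 50), hi = c(50, 60))
  sh <- epoch_slopes(v, halves)
  expect_equal(sh$slope, c(-0.001, 0.001), tolerance = 1e-3)

  # attenuation sign convention: shrinking |median| gives negative slope
  att <- analytic_chart(function(a) -0.05 * exp(-a / 30))
  expect_true(all(epoch_slopes(att)$slope < 0))

  # |.| symmetry: negating the median leaves the slopes unchanged
  neg <- analytic_chart(function(a) -0.001 * a)
  expect_equal(epoch_slopes(neg)$slope, s$slope)

  expect_error(epoch_slopes(lin, data.frame(name = "x", lo = 150, hi = 160)),
               "2 points")
})

test_that("snapshot summaries evaluate median and prevalence at the six ages", {
  m0 <- constant_model(0, 0.05)
  snap <- snapshot_summary(list("AF/FA" = m0))
  expect_equal(nrow(snap), 6)
  expect_equal(snap$age_years, c(3, 9, 17, 30, 50, 80))
  expect_equal(snap$pct_right, rep(50, 6))

  m1 <- constant_model(0.03, 0.05)
  snap1 <- snapshot_summary(list("CST/volume" = m1), ages = 30)
  expect_equal(snap1$median_li, 0.03)
  expect_equal(snap1$pct_right, 100 * pnorm(0.6), tolerance = 1e-9)
  expect_equal(snap1$tract, "CST"); expect_equal(snap1$feature, "volume")
  # prevalence exceeds 50 iff the median is rightward
  expect_true(all((snap1$pct_right > 50) == (snap1$median_li > 0)))

  m2 <- constant_model(0.01, 0.05, age_range = c(5, 60))
  expect_error(snapshot_summary(list("AF/FA" = m2)), "outside")
})
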