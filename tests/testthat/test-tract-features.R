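test_that("laterality index matches its defining identities", {
  expect_identical(laterality_index(0.5, 0.5), 0)    # perfect symmetry
  expect_equal(laterality_index(1, 3), 0.5)
  expect_equal(laterality_index(3, 1), -0.5)
  # rightward asymmetry is positive
  expect_gt(laterality_index(0.4, 0.41), 0)
})

test_that("laterality index is antisymmetric, scale-invariant and bounded", {
  set.seed(101)
  a <- exp(runif(500, log(1e-6), log(1e6)))
  b <- exp(runif(500, log(1e-6), log(1e6)))
  expect_equal(laterality_index(a, b), -laterality_index(b, a))
  for (c_scale in c(1e-4, 0.5, 1, 7, 1e5)) {
    expect_equal(laterality_index(c_scale * a, c_scale * b),
                 laterality_index(a, b), tolerance = 1e-12)
  }
  expect_true(all(abs(laterality_index(a, b)) < 1))
})

test_that("laterality index rejects degenerate input, naming the hemisphere", {
  expect_error(laterality_index(0, 1), "left")
  expect_error(laterality_index(1, -2), "right")
  expect_error(laterality_index(NaN, 1), "left")
  expect_error(laterality_index(1, Inf), "right")
})

test_that("weighted tract mean aggregates voxel samples correctly", {
  expect_equal(weighted_tract_mean(c(2, 2, 2), c(5, 1, 9)), 2)
  expect_equal(weighted_tract_mean(c(1, 3), c(1, 1)), 2)
  expect_equal(weighted_tract_mean(c(1, 3), c(1, 3)), 2.5)
  # weight-rescaling invariance and range containment
  set.seed(102)
  v <- rnorm(50); w <- rexp(50)
  expect_equal(weighted_tract_mean(v, w), weighted_tract_mean(v, 13 * w))
  m <- weighted_tract_mean(v, w)
  expect_gte(m, min(v)); expect_lte(m, max(v))
  expect_error(weighted_tract_mean(v, rep(0, 50)), "zero")
  expect_error(weighted_tract_mean(v, w[-1]), "length")
})

test_that("tract volume and mean streamline length follow their definitions", {
  expect_equal(tract_volume(10, c(1, 1, 1)), 10)
  expect_equal(tract_volume(0, c(2, 2, 2)), 0)
  expect_equal(tract_volume(8, c(1.25, 1.25, 1.25)), 15.625)
  expect_error(tract_volume(-1, c(1, 1, 1)), "negative")
  expect_equal(mean_streamline_length(100), 100)
  expect_equal(mean_streamline_length(c(80, 120)), 100)
  expect_error(mean_streamline_length(numeric(0)), "empty")
  # sampling check: mean of draws near the distribution mean
  set.seed(103)
  draws <- rgamma(1000, shape = 100, rate = 1)  # mean 100, sd 10
  se <- 10 / sqrt(1000)
  expect_lt(abs(mean_streamline_length(draws) - 100), 3 * se)
})

test_that("laterality table joins covariates and filters degenerate rows", {
  covs <- data.frame(subject_id = c("s1", "s2", "s3"),
                     age_years = c(10, 40, 70), sex = c("female", "male", "female"),
                     cohort_id = "c1", handedness = "right")
  grid <- expand.grid(subject_id = covs$subject_id,
                      tract = c("AF", "CST"),
                      feature = feature_labels(),
                      stringsAsFactors = FALSE)
  meas <- data.frame(grid, left_value = 1.0, right_value = 1.5)
  tab <- build_laterality_table(meas, covs)
  expect_equal(nrow(tab), 3 * 2 * 6)
  expect_true(all(tab$li == laterality_index(1.0, 1.5)))
  expect_equal(tab$age_years[tab$subject_id == "s2"][1], 40)

  meas$left_value[5] <- 0  # degenerate extraction
  expect_message(tab2 <- build_laterality_table(meas, covs), "excluded")
  expect_equal(nrow(tab2), nrow(tab) - 1)
  expect_equal(nrow(attr(tab2, "exclusions")), 1)

  meas$subject_id[1] <- "ghost"
  expect_error(build_laterality_table(meas, covs), "ghost")
})

test_that("tract and feature vocabularies have the documented sizes", {
  expect_length(tract_labels(), 30)
  expect_length(feature_labels(), 6)
})
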