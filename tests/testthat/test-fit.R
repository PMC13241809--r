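test_that("intercept-only fit equals the closed-form Gaussian MLE", {
  set.seed(21)
  y <- rnorm(400, 0.03, 0.04)
  obs <- data.frame(li = y, age_years = runif(400, 0, 100),
                    sex = "female", cohort_id = "c1")
  m <- fit_location_scale(obs, fp_spec(numeric(0)), fp_spec(numeric(0)))
  expect_true(m$converged)
  expect_equal(unname(m$coef_mu[1]), mean(y), tolerance = 1e-8)
  # maximum-likelihood SD uses divisor n
  expect_equal(unname(exp(m$coef_sigma[1])),
               sqrt(mean((y - mean(y))^2)), tolerance = 1e-8)
  expect_equal(m$loglik,
               sum(dnorm(y, mean(y), sqrt(mean((y - mean(y))^2)), log = TRUE)),
               tolerance = 1e-8)
})

test_that("small-n fits match a multi-start generic optimizer", {
  set.seed(22)
  n <- 150
  age <- runif(n, 0, 100)
  y <- rnorm(n, -0.02 + 0.0005 * age, 0.04 * exp(0.002 * age))
  obs <- data.frame(li = y, age_years = age, sex = "female", cohort_id = "c1")
  m <- fit_location_scale(obs, fp_spec(1), fp_spec(1))
  a <- age + 1
  nll <- function(th) {
    -sum(dnorm(y, th[1] + th[2] * a, exp(th[3] + th[4] * a), log = TRUE))
  }
  best <- Inf
  for (s in 1:5) {
    st <- c(rnorm(1, 0, 0.1), rnorm(1, 0, 0.01),
            log(sd(y)) + rnorm(1, 0, 0.5), rnorm(1, 0, 0.005))
    o <- nlminb(st, nll,
                control = list(rel.tol = 1e-14, eval.max = 5000,
                               iter.max = 2000))
    best <- min(best, o$objective)
  }
  expect_equal(m$loglik, -best, tolerance = 1e-6)
})

test_that("two-cohort fixed-effects fit matches an oracle with sum-zero offsets", {
  set.seed(23)
  n <- 200
  age <- runif(n, 0, 90)
  coh <- rep(c("a", "b"), each = n / 2)
  sexv <- rep(c("female", "male"), n / 2)
  male <- as.numeric(sexv == "male")
  cb <- ifelse(coh == "a", 1, -1)
  y <- rnorm(n, 0.02 + 0.0003 * age + 0.01 * male + 0.008 * cb,
             0.05 * exp(0.1 * cb))
  obs <- data.frame(li = y, age_years = age, sex = sexv, cohort_id = coh)
  m <- fit_location_scale(obs, fp_spec(1), fp_spec(1),
                          fit_control(cohort = "fixed"))
  a <- age + 1
  nll <- function(th) {
    -sum(dnorm(y, th[1] + th[2] * a + th[3] * male + th[4] * cb,
               exp(th[5] + th[6] * a + th[7] * male + th[8] * cb),
               log = TRUE))
  }
  best <- Inf
  set.seed(24)
  for (s in 1:5) {
    o <- nlminb(rnorm(8, 0, 0.05) + c(0, 0, 0, 0, log(0.05), 0, 0, 0), nll,
                control = list(rel.tol = 1e-14, eval.max = 9000,
                               iter.max = 3000))
    best <- min(best, o$objective)
  }
  expect_equal(m$loglik, -best, tolerance = 1e-6)
  # fixed offsets sum to zero and k counts the free parameters
  expect_equal(sum(m$u_mu), 0, tolerance = 1e-10)
  expect_equal(m$k, 4 + 4)  # (int + age + sex + offset) on each predictor
})

test_that("BIC uses the counted parameter total", {
  set.seed(25)
  sub <- make_cohort_design(2, 300, seed = 25)
  truth <- fixture_truth(n_cohorts = 2, seed = 26)
  obs <- simulate_li_observations(sub, truth, seed = 27)
  m <- fit_location_scale(obs, fp_spec(c(0, 1)), fp_spec(1))
  # mu: intercept + 2 FP + sex = 4; log-sigma: intercept + 1 FP + sex = 3;
  # ridge cohort offsets: 2 per predictor = 4
  expect_equal(m$k, 4 + 3 + 4)
  expect_equal(m$bic, -2 * m$loglik + m$k * log(m$n))
  # converged fit beats the intercept-only baseline
  m0 <- fit_location_scale(obs, fp_spec(numeric(0)), fp_spec(numeric(0)),
                           fit_control(cohort = "none"))
  expect_gte(m$loglik, m0$loglik)
})

test_that("likelihood is additive over duplicated data", {
  set.seed(28)
  age <- runif(250, 0, 100)
  obs <- data.frame(li = rnorm(250, 0.01 + 3e-4 * age, 0.05),
                    age_years = age, sex = "female", cohort_id = "c1")
  m1 <- fit_location_scale(obs, fp_spec(1), fp_spec(1))
  m2 <- fit_location_scale(rbind(obs, obs), fp_spec(1), fp_spec(1))
  expect_equal(m2$coef_mu, m1$coef_mu, tolerance = 1e-4)
  expect_equal(m2$coef_sigma, m1$coef_sigma, tolerance = 1e-4)
  expect_equal(m2$loglik, 2 * m1$loglik, tolerance = 1e-7)
})

test_that("fitted curves are invariant to the age-offset reparameterization", {
  set.seed(29)
  age <- runif(300, 0, 80)
  obs <- data.frame(li = rnorm(300, -0.01 + 4e-4 * age, 0.04),
                    age_years = age, sex = "female", cohort_id = "c1")
  m_a <- fit_location_scale(obs, fp_spec(1), fp_spec(1),
                            fit_control(age_offset = 1))
  obs_shift <- transform(obs, age_years = age_years + 5)
  m_b <- fit_location_scale(obs_shift, fp_spec(1), fp_spec(1),
                            fit_control(age_offset = -4))
  grid <- seq(5, 75, length.out = 50)
  expect_equal(predict(m_a, grid)$mu, predict(m_b, grid + 5)$mu,
               tolerance = 1e-6)
  expect_equal(predict(m_a, grid)$sigma, predict(m_b, grid + 5)$sigma,
               tolerance = 1e-6)
})

test_that("degenerate designs are rejected", {
  obs <- data.frame(li = rnorm(7), age_years = runif(7, 1, 9),
                    sex = "female", cohort_id = "c1")
  expect_error(fit_location_scale(obs, fp_spec(c(1, 2, 3)), fp_spec(c(1, 2))),
               "too few")
  obs$sex <- c("f", "m")[1 + (seq_len(7) %% 2)]
  expect_error(fit_location_scale(obs, fp_spec(1), fp_spec(1)),
               "female/male")
})

test_that("model selection picks the smallest BIC with deterministic ties", {
  set.seed(30)
  sub <- make_cohort_design(2, 400, seed = 30)
  truth <- fixture_truth(n_cohorts = 2, seed = 31)
  obs <- simulate_li_observations(sub, truth, seed = 32)

  sel_staged <- select_model(obs, power_set = c(0, 1), max_order = 2,
                             strategy = "staged")
  sel_grid <- select_model(obs, power_set = c(0, 1), max_order = 2,
                           strategy = "full_grid")
  # 5 specs from powers {0, 1} at order <= 2
  rep_staged <- attr(sel_staged, "selection_report")
  rep_grid <- attr(sel_grid, "selection_report")
  expect_equal(nrow(rep_staged), 10)   # 5 mu-stage + 5 sigma-stage
  expect_equal(nrow(rep_grid), 25)
  expect_true(all(c("spec_mu", "spec_sigma", "bic", "converged") %in%
                    names(rep_grid)))
  # the staged optimum can never beat the exhaustive grid
  expect_lte(min(rep_grid$bic, na.rm = TRUE), sel_staged$bic + 1e-9)
  # grid winner attains the grid minimum over converged candidates
  expect_equal(sel_grid$bic,
               min(rep_grid$bic[rep_grid$converged], na.rm = TRUE))
})

test_that("direct BIC comparison decides between two candidates", {
  set.seed(33)
  age <- runif(1200, 0, 100)
  # strongly curved truth: log-age term needed
  obs <- data.frame(li = rnorm(1200, -0.05 + 0.02 * log(age + 1), 0.04),
                    age_years = age, sex = "female", cohort_id = "c1")
  m_log <- fit_location_scale(obs, fp_spec(0), fp_spec(numeric(0)))
  m_flat <- fit_location_scale(obs, fp_spec(numeric(0)), fp_spec(numeric(0)))
  expect_equal(m_log$bic, -2 * m_log$loglik + m_log$k * log(1200))
  expect_lt(m_log$bic, m_flat$bic)
})
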