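# Shared fixtures: small ground-truth trajectories and hand-built model /
# chart objects used across the test files.

# gently curved leftward-to-stable truth with sex and cohort structure
fixture_truth <- function(n_cohorts = 4, seed = 11,
                          cohort_sd_mu = 0.01, cohort_sd_sigma = 0.05) {
  trajectory_truth(
    mu_powers = 0, mu_coefficients = c(-0.03, 0.01),
    sigma_powers = 1, sigma_coefficients = c(log(0.05), 0.0005),
    sex_effect_mu = 0.005, sex_effect_sigma = 0,
    cohort_sd_mu = cohort_sd_mu, cohort_sd_sigma = cohort_sd_sigma,
    cohort_ids = sprintf("cohort_%02d", seq_len(n_cohorts)),
    seed = seed
  )
}

# population median of a truth: equal-weight average over both sexes and the
# realized cohorts (matching what a fitted population curve estimates)
truth_population_mu <- function(truth, ages) {
  chs <- names(truth$cohort_offsets_mu)
  rowMeans(vapply(chs, function(ch) {
    (trajectory_eval(truth, ages, "female", ch)$mu +
       trajectory_eval(truth, ages, "male", ch)$mu) / 2
  }, numeric(length(ages))))
}

truth_population_sigma <- function(truth, ages) {
  chs <- names(truth$cohort_offsets_mu)
  rowMeans(vapply(chs, function(ch) {
    (trajectory_eval(truth, ages, "female", ch)$sigma +
       trajectory_eval(truth, ages, "male", ch)$sigma) / 2
  }, numeric(length(ages))))
}

# hand-built normative model with constant mu and sigma (no sex, no cohorts)
constant_model <- function(mu, sigma, age_range = c(0, 100)) {
  structure(list(
    spec_mu = fp_spec(1), spec_sigma = fp_spec(1),
    coef_mu = c("(Intercept)" = mu, "age^1" = 0),
    coef_sigma = c("(Intercept)" = log(sigma), "age^1" = 0),
    u_mu = numeric(0), u_sigma = numeric(0),
    tau2_mu = NA_real_, tau2_sigma = NA_real_,
    cohort_method = "none", cohorts = "c1",
    has_sex = FALSE, age_offset = 1, age_range = age_range,
    n = 1000L, k = 4L, loglik = 0, bic = 0, converged = TRUE,
    iterations = 1L, grad_norm = 0,
    vcov_mu = diag(2) * 0, vcov_mu_names = c("(Intercept)", "age^1")
  ), class = "normative_model")
}

# chart built directly from an analytic median function of age
analytic_chart <- function(median_fun, age_grid = seq(0, 100, length.out = 500),
                           tract = "AF", feature = "FA") {
  m <- median_fun(age_grid)
  structure(list(
    tract = tract, feature = feature,
    context = list(sex = "average", cohort = "population"),
    age_grid = age_grid, levels = 50,
    values = matrix(m, ncol = 1, dimnames = list(NULL, "p50")),
    spec_mu = "FP(1)", spec_sigma = "FP(1)", bic = NA_real_, n = length(m)
  ), class = "centile_chart")
}
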