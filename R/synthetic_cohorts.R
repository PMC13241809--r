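# Multi-cohort synthetic lifespan data with known ground-truth asymmetry
# trajectories. The generator emulates the structure of large aggregated
# lifespan consortia: dozens of cohorts with heterogeneous, overlapping age
# windows; an LI response that is normal with an age-varying mean and SD
# (both fractional-polynomial smooths); additive sex effects on both
# predictors; and cohort-level offsets on the mean and the log-SD.

#' Ground-truth lateralization trajectory
#'
#' Defines the data-generating normal location-scale model for the LI:
#' `mu = f_mu(age) + sex_effect_mu * [sex == male] + u_mu[cohort]` and
#' `log sigma = f_sigma(age) + sex_effect_sigma * [male] + u_sigma[cohort]`,
#' with `f_mu`, `f_sigma` fractional polynomials in shifted age. "female" is
#' the reference sex level. Cohort offsets are drawn `N(0, tau^2)` once, at
#' construction, from `seed`.
#'
#' @param mu_powers,mu_coefficients FP powers of `f_mu` and coefficients
#'   (intercept first, then one per basis column).
#' @param sigma_powers,sigma_coefficients same for `f_sigma`, log scale.
#' @param sex_effect_mu,sex_effect_sigma additive effect of the "male" level
#'   on `mu` and on `log sigma`.
#' @param cohort_sd_mu,cohort_sd_sigma SDs (tau) of the cohort offsets.
#' @param cohort_ids character vector of cohort labels to realize offsets for.
#' @param age_offset years added to age before the FP transforms.
#' @param seed integer seed for the cohort-offset draws.
#' @param design_range age range (years) over which the truth must be valid;
#'   used to check that `|mu| + 3 sigma < 1` so simulated LI stays in (-1, 1).
#' @return an object of class `trajectory_truth`.
#' @export
trajectory_truth <- function(mu_powers, mu_coefficients,
                             sigma_powers, sigma_coefficients,
                             sex_effect_mu = 0, sex_effect_sigma = 0,
                             cohort_sd_mu = 0, cohort_sd_sigma = 0,
                             cohort_ids = "cohort_01",
                             age_offset = 1, seed = 1L,
                             design_range = c(0, 100)) {
  spec_mu <- fp_spec(mu_powers)
  spec_sigma <- fp_spec(sigma_powers)
  stopifnot(length(mu_coefficients) == length(spec_mu$powers) + 1L,
            length(sigma_coefficients) == length(spec_sigma$powers) + 1L,
            cohort_sd_mu >= 0, cohort_sd_sigma >= 0,
            length(cohort_ids) >= 1L)
  offs <- with_seed(derive_seed(seed, "cohort_offsets"), {
    list(mu = stats::rnorm(length(cohort_ids), 0, cohort_sd_mu),
         sigma = stats::rnorm(length(cohort_ids), 0, cohort_sd_sigma))
  })
  names(offs$mu) <- names(offs$sigma) <- cohort_ids
  truth <- structure(list(
    spec_mu = spec_mu, mu_coefficients = as.numeric(mu_coefficients),
    spec_sigma = spec_sigma, sigma_coefficients = as.numeric(sigma_coefficients),
    sex_effect_mu = sex_effect_mu, sex_effect_sigma = sex_effect_sigma,
    cohort_sd_mu = cohort_sd_mu, cohort_sd_sigma = cohort_sd_sigma,
    cohort_offsets_mu = offs$mu, cohort_offsets_sigma = offs$sigma,
    age_offset = age_offset, design_range = as.numeric(design_range)
  ), class = "trajectory_truth")

  chk <- trajectory_check(truth)
  if (!chk$ok) {
    warning(sprintf(
      "truth admits |mu| + 3*sigma >= 1 (max %.3f at age %.1f); LI draws may be truncated",
      chk$max_val, chk$at_age))
  }
  truth
}

# max over a design grid (both sexes, all cohorts) of |mu| + 3 sigma
trajectory_check <- function(truth) {
  ages <- seq(truth$design_range[1], truth$design_range[2], length.out = 201)
  ages <- ages[ages + truth$age_offset > 0]  # FP needs positive shifted age
  if (length(ages) == 0L) return(list(ok = TRUE, max_val = NA, at_age = NA))
  worst <- -Inf; at <- NA_real_
  for (sex in c("female", "male")) {
    for (ch in names(truth$cohort_offsets_mu)) {
      ev <- trajectory_eval(truth, ages, sex, ch)
      v <- abs(ev$mu) + 3 * ev$sigma
      if (max(v) > worst) { worst <- max(v); at <- ages[which.max(v)] }
    }
  }
  list(ok = worst < 1, max_val = worst, at_age = at)
}

#' Evaluate a ground-truth trajectory
#'
#' @param truth a [trajectory_truth()].
#' @param age ages in years (vectorized).
#' @param sex `"female"` (reference) or `"male"`.
#' @param cohort_id a cohort with a realized offset in `truth`.
#' @return list with numeric vectors `mu` and `sigma` (`sigma > 0`).
#' @export
trajectory_eval <- function(truth, age, sex, cohort_id) {
  stopifnot(inherits(truth, "trajectory_truth"))
  sex <- match.arg(sex, c("female", "male"))
  if (!cohort_id %in% names(truth$cohort_offsets_mu)) {
    stop("unknown cohort: ", cohort_id)
  }
  is_male <- as.numeric(sex == "male")
  bmu <- fp_basis(age, truth$spec_mu, truth$age_offset)
  bsg <- fp_basis(age, truth$spec_sigma, truth$age_offset)
  mu <- truth$mu_coefficients[1] +
    drop(bmu %*% truth$mu_coefficients[-1]) +
    truth$sex_effect_mu * is_male +
    truth$cohort_offsets_mu[[cohort_id]]
  eta <- truth$sigma_coefficients[1] +
    drop(bsg %*% truth$sigma_coefficients[-1]) +
    truth$sex_effect_sigma * is_male +
    truth$cohort_offsets_sigma[[cohort_id]]
  list(mu = mu, sigma = exp(eta))
}

#' Generate a multi-cohort cross-sectional subject design
#'
#' Draws one record per subject: age uniform within the subject's cohort age
#' window, sex and handedness independent at the stated rates. Cohort windows
#' come from `age_window_sampler`; the default sampler produces staggered,
#' overlapping windows whose union covers `age_range`, mimicking aggregated
#' lifespan consortia in which each cohort contributes a limited age band.
#'
#' @param n_cohorts number of cohorts (>= 1).
#' @param subjects_per_cohort subjects in each cohort (>= 1; recycled).
#' @param age_range overall lifespan range to cover, within `[0, 110]`.
#' @param age_window_sampler either `NULL` (default staggered sampler) or a
#'   function `(n_cohorts, age_range)` returning an `n_cohorts x 2` matrix of
#'   per-cohort `[lo, hi]` windows.
#' @param sex_ratio probability a subject is female.
#' @param left_handed_rate,ambidextrous_rate,unknown_hand_rate handedness
#'   category probabilities (remainder right-handed).
#' @param seed integer seed.
#' @return data.frame of subject records: `subject_id`, `age_years`, `sex`,
#'   `cohort_id`, `handedness`; cohort windows in attribute `"age_windows"`.
#' @export
make_cohort_design <- function(n_cohorts, subjects_per_cohort,
                               age_range = c(0, 100),
                               age_window_sampler = NULL,
                               sex_ratio = 0.5,
                               left_handed_rate = 0.093,
                               ambidextrous_rate = 0.01,
                               unknown_hand_rate = 0,
                               seed = 1L) {
  stopifnot(n_cohorts >= 1, all(subjects_per_cohort >= 1))
  probs <- c(left_handed_rate, ambidextrous_rate, unknown_hand_rate, sex_ratio)
  if (any(probs < 0 | probs > 1) ||
      left_handed_rate + ambidextrous_rate + unknown_hand_rate > 1) {
    stop("rates must be proportions in [0, 1] and sum to at most 1")
  }
  if (age_range[1] < 0 || age_range[2] > 110 || age_range[1] >= age_range[2]) {
    stop("age_range must be an increasing interval within [0, 110]")
  }
  n_per <- rep_len(subjects_per_cohort, n_cohorts)

  with_seed(derive_seed(seed, "cohort_design"), {
    windows <- if (is.null(age_window_sampler)) {
      default_window_sampler(n_cohorts, age_range)
    } else {
      age_window_sampler(n_cohorts, age_range)
    }
    windows <- matrix(as.numeric(windows), ncol = 2)
    if (any(windows[, 1] < 0) || any(windows[, 2] > 110) ||
        any(windows[, 1] >= windows[, 2])) {
      stop("cohort age windows must be increasing intervals within [0, 110]")
    }

    cohort_ids <- sprintf("cohort_%02d", seq_len(n_cohorts))
    n_total <- sum(n_per)
    cohort <- rep(cohort_ids, n_per)
    lo <- rep(windows[, 1], n_per)
    hi <- rep(windows[, 2], n_per)
    ages <- stats::runif(n_total, lo, hi)
    sex <- ifelse(stats::runif(n_total) < sex_ratio, "female", "male")
    hand <- sample(c("left", "ambidextrous", "unknown", "right"), n_total,
                   replace = TRUE,
                   prob = c(left_handed_rate, ambidextrous_rate,
                            unknown_hand_rate,
                            1 - left_handed_rate - ambidextrous_rate -
                              unknown_hand_rate))
    out <- data.frame(
      subject_id = sprintf("sub_%06d", seq_len(n_total)),
      age_years = ages, sex = sex, cohort_id = cohort, handedness = hand,
      stringsAsFactors = FALSE
    )
    rownames(windows) <- cohort_ids
    attr(out, "age_windows") <- windows
    out
  })
}

# staggered overlapping windows whose union covers the full range: anchors
# evenly spaced, half-widths drawn uniformly, end windows pinned to the range
default_window_sampler <- function(n_cohorts, age_range) {
  lo <- age_range[1]; hi <- age_range[2]
  if (n_cohorts == 1L) return(matrix(c(lo, hi), ncol = 2))
  centers <- seq(lo, hi, length.out = n_cohorts)
  span <- hi - lo
  # half-widths cover at least one inter-anchor gap so adjacent windows overlap
  gap <- span / (n_cohorts - 1)
  half <- stats::runif(n_cohorts, gap, pmin(gap + 0.25 * span, span))
  w <- cbind(pmax(lo, centers - half), pmin(hi, centers + half))
  w[1, 1] <- lo
  w[n_cohorts, 2] <- hi
  w
}

#' Simulate lateralization-index observations
#'
#' Draws one LI per subject from `Normal(mu, sigma)` at the subject's
#' covariates under `truth`. Draws outside (-1, 1) - rare by the truth-spec
#' requirement `|mu| + 3 sigma < 1` - are redrawn and counted in the
#' `"n_redraws"` attribute.
#'
#' @param subjects subject design from [make_cohort_design()].
#' @param truth a [trajectory_truth()] with offsets for every cohort present.
#' @param tract,feature labels stamped onto the observations.
#' @param seed integer seed.
#' @param max_redraws per-subject redraw budget before aborting.
#' @return data.frame of laterality observations (covariates + `tract`,
#'   `feature`, `li`).
#' @export
simulate_li_observations <- function(subjects, truth, tract = "AF",
                                     feature = "FA", seed = 1L,
                                     max_redraws = 100L) {
  stopifnot(inherits(truth, "trajectory_truth"))
  missing_cohorts <- setdiff(unique(subjects$cohort_id),
                             names(truth$cohort_offsets_mu))
  if (length(missing_cohorts) > 0) {
    stop("truth has no offsets for cohort(s): ",
         paste(missing_cohorts, collapse = ", "))
  }
  n <- nrow(subjects)
  mu <- numeric(n); sg <- numeric(n)
  for (sex in c("female", "male")) {
    for (ch in unique(subjects$cohort_id)) {
      i <- subjects$sex == sex & subjects$cohort_id == ch
      if (!any(i)) next
      ev <- trajectory_eval(truth, subjects$age_years[i], sex, ch)
      mu[i] <- ev$mu; sg[i] <- ev$sigma
    }
  }
  li <- with_seed(derive_seed(seed, paste("li", tract, feature, sep = "/")), {
    x <- stats::rnorm(n, mu, sg)
    redraws <- 0L
    for (k in seq_len(max_redraws)) {
      out_i <- which(abs(x) >= 1)
      if (length(out_i) == 0L) break
      redraws <- redraws + length(out_i)
      x[out_i] <- stats::rnorm(length(out_i), mu[out_i], sg[out_i])
    }
    if (any(abs(x) >= 1)) {
      stop("redraw budget exhausted; truth places too much mass outside (-1, 1)")
    }
    attr(x, "n_redraws") <- redraws
    x
  })
  out <- data.frame(
    subject_id = subjects$subject_id,
    age_years = subjects$age_years,
    sex = subjects$sex,
    cohort_id = subjects$cohort_id,
    handedness = subjects$handedness %||% "unknown",
    tract = tract, feature = feature,
    li = as.numeric(li),
    stringsAsFactors = FALSE
  )
  attr(out, "n_redraws") <- attr(li, "n_redraws")
  out
}

#' Baseline bilateral feature profile
#'
#' A strictly positive baseline value `B(age)` for one tract-feature, used to
#' map a target LI to a left/right pair. Plumbing for end-to-end tests; any
#' positive function of age works because the LI is scale-invariant.
#'
#' @param value either a single positive constant or a function of age
#'   returning strictly positive values.
#' @return function of age.
#' @export
baseline_profile <- function(value) {
  if (is.function(value)) return(value)
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  function(age) rep(value, length(age))
}

#' Simulate bilateral left/right measures with a known LI
#'
#' Draws `LI_i` exactly as [simulate_li_observations()] (same seed protocol),
#' then sets `right = B(age) * (1 + LI_i)` and `left = B(age) * (1 - LI_i)`,
#' so that `(right - left) / (right + left)` recovers `LI_i`.
#'
#' @inheritParams simulate_li_observations
#' @param baseline a [baseline_profile()] (or positive constant / function).
#' @return data.frame of bilateral measures: `subject_id`, `tract`,
#'   `feature`, `left_value`, `right_value`.
#' @export
simulate_bilateral_measures <- function(subjects, truth, baseline = 500,
                                        tract = "AF", feature = "FA",
                                        seed = 1L, max_redraws = 100L) {
  B <- baseline_profile(baseline)
  b <- B(subjects$age_years)
  if (any(!is.finite(b) | b <= 0)) stop("baseline must be strictly positive")
  obs <- simulate_li_observations(subjects, truth, tract, feature, seed,
                                  max_redraws)
  data.frame(
    subject_id = obs$subject_id,
    tract = tract, feature = feature,
    left_value = b * (1 - obs$li),
    right_value = b * (1 + obs$li),
    stringsAsFactors = FALSE
  )
}
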