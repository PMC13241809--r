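# Centile charts and rightward-prevalence curves from a fitted normative
# model. Under the normal family the p-th centile at a given age and context
# is mu + sigma * qnorm(p / 100), and the fraction of the population with a
# rightward asymmetry (LI > 0) is Phi(mu / sigma).

#' Default centile levels (percent)
#' @export
DEFAULT_LEVELS <- c(2.5, 25, 50, 75, 97.5)

#' Compute smooth centile curves across a dense age grid
#'
#' Population charts set cohort offsets to zero; charts are produced at a sex
#' context (`"female"`, `"male"`, or the equal-weight `"average"`).
#'
#' @param model a fitted `normative_model`.
#' @param age_grid strictly increasing ages (years); default 500 equally
#'   spaced points spanning the fitted age range. Grids extending beyond the
#'   fitted range are allowed but flagged with a warning (extrapolation).
#' @param levels strictly increasing centile levels in (0, 100).
#' @param sex sex context.
#' @param cohort `"population"` or a fitted cohort id.
#' @param tract,feature labels stamped onto the chart.
#' @return an object of class `centile_chart`: list with `age_grid`,
#'   `levels`, `values` (grid x levels matrix), `context`, and model
#'   metadata.
#' @export
centile_curves <- function(model, age_grid = NULL,
                           levels = DEFAULT_LEVELS,
                           sex = "average", cohort = "population",
                           tract = model$tract %||% "tract",
                           feature = model$feature %||% "feature") {
  stopifnot(inherits(model, "normative_model"))
  if (is.null(age_grid)) {
    age_grid <- seq(model$age_range[1], model$age_range[2], length.out = 500)
  }
  if (length(age_grid) == 0L) stop("empty age grid")
  if (is.unsorted(age_grid, strictly = TRUE)) {
    stop("age_grid must be strictly increasing")
  }
  if (min(age_grid) < model$age_range[1] - 1e-9 ||
      max(age_grid) > model$age_range[2] + 1e-9) {
    warning("age grid extends beyond the fitted age range (extrapolation)")
  }
  levels <- as.numeric(levels)
  if (any(levels <= 0 | levels >= 100) || is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly increasing percentages in (0, 100)")
  }
  pr <- predict(model, age_grid, sex = sex, cohort = cohort)
  z <- stats::qnorm(levels / 100)
  values <- outer(pr$mu, rep(1, length(levels))) +
    outer(pr$sigma, z)
  colnames(values) <- sprintf("p%g", levels)
  structure(list(
    tract = tract, feature = feature,
    context = list(sex = sex, cohort = cohort),
    age_grid = as.numeric(age_grid), levels = levels, values = values,
    spec_mu = format(model$spec_mu), spec_sigma = format(model$spec_sigma),
    bic = model$bic, n = model$n
  ), class = "centile_chart")
}

#' @export
print.centile_chart <- function(x, ...) {
  cat(sprintf("Centile chart: %s / %s (%s, %s)\n", x$tract, x$feature,
              x$context$sex, x$context$cohort))
  cat(sprintf("  %d ages in [%.2f, %.2f]; levels: %s\n",
              length(x$age_grid), min(x$age_grid), max(x$age_grid),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

# median (50th centile) curve of a chart; errors if absent
chart_median <- function(chart) {
  stopifnot(inherits(chart, "centile_chart"))
  i <- which(abs(chart$levels - 50) < 1e-9)
  if (length(i) != 1L) stop("chart does not contain the 50th centile level")
  chart$values[, i]
}

#' Percentage of the population that is right-lateralized
#'
#' Model-based prevalence `100 * Phi(mu / sigma)`, i.e. the probability of a
#' positive LI under the fitted normal distribution at each age. With
#' `sex = "average"` the two sex-specific prevalences are computed and
#' averaged with equal weight.
#'
#' @param model fitted `normative_model`.
#' @param ages ages in years.
#' @param sex `"female"`, `"male"`, or `"average"`.
#' @param cohort `"population"` or a fitted cohort id.
#' @return numeric vector of percentages in `[0, 100]`.
#' @export
prevalence_right <- function(model, ages, sex = "average",
                             cohort = "population") {
  one <- function(s) {
    pr <- predict(model, ages, sex = s, cohort = cohort)
    if (any(pr$sigma <= 0)) stop("non-positive sigma")  # log link forbids this
    100 * stats::pnorm(pr$mu / pr$sigma)
  }
  if (sex == "average" && model$has_sex) {
    (one("female") + one("male")) / 2
  } else if (sex == "average") {
    one("female")
  } else {
    one(sex)
  }
}

#' Empirical right-lateralization percentage
#'
#' The raw-data counterpart of [prevalence_right()]: the percentage of
#' observations with `li > 0` among those within each age bin.
#'
#' @param observations laterality table.
#' @param ages bin centers in years.
#' @param half_width half-width of the age bin in years.
#' @return numeric vector (NA where a bin is empty).
#' @export
prevalence_right_empirical <- function(observations, ages, half_width = 2) {
  vapply(ages, function(a) {
    i <- abs(observations$age_years - a) <= half_width
    if (!any(i)) return(NA_real_)
    100 * mean(observations$li[i] > 0)
  }, numeric(1))
}
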