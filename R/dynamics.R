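# Lifespan dynamics derived from fitted centile charts: first derivative of
# the median LI trajectory, zero-crossings of the median (lateralization
# reversals), mean slopes of |median LI| within predefined life epochs, and
# snapshot summaries at representative ages.

#' Default lifespan epochs
#'
#' Six half-open epochs `[lo, hi)` (the last closed): early childhood 2-5,
#' childhood 5-12, adolescence 12-20, early adulthood 20-40, midlife 40-60,
#' older adulthood 60-100 years. Ages below 2 belong to no epoch.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
default_epochs <- function() {
  data.frame(
    name = c("early_childhood", "childhood", "adolescence",
             "early_adulthood", "midlife", "older_adulthood"),
    lo = c(2, 5, 12, 20, 40, 60),
    hi = c(5, 12, 20, 40, 60, 100),
    stringsAsFactors = FALSE
  )
}

#' Default snapshot ages
#'
#' The median age of each default epoch: 3, 9, 17, 30, 50, 80 years.
#' @export
DEFAULT_SNAPSHOT_AGES <- c(3, 9, 17, 30, 50, 80)

#' First derivative of the median LI trajectory
#'
#' Finite-difference derivative of the 50th-centile curve: central
#' differences on interior grid points, one-sided at the two ends.
#'
#' @param chart a `centile_chart` containing the 50th level, grid length >= 3.
#' @return data.frame with `age` and `derivative` (LI units per year).
#' @export
median_derivative <- function(chart) {
  m <- chart_median(chart)
  g <- chart$age_grid
  n <- length(g)
  if (n < 3L) stop("age grid too short for differentiation (need >= 3 points)")
  d <- numeric(n)
  d[1] <- (m[2] - m[1]) / (g[2] - g[1])
  d[n] <- (m[n] - m[n - 1]) / (g[n] - g[n - 1])
  i <- 2:(n - 1)
  d[i] <- (m[i + 1] - m[i - 1]) / (g[i + 1] - g[i - 1])
  data.frame(age = g, derivative = d)
}

#' Detect lateralization reversals (zero-crossings of the median LI)
#'
#' One event per sign change of the median curve between adjacent grid
#' points; the crossing age is found by linear interpolation. Direction is
#' `"left_to_right"` when the median goes from negative to positive.
#' Crossings whose flanking excursions (the largest |median| between this
#' crossing and the neighbouring crossing or grid end, on both sides) are
#' both below `min_excursion` are suppressed, which filters numerical
#' micro-oscillations around zero.
#'
#' @param chart a `centile_chart` containing the 50th level.
#' @param min_excursion suppression threshold in LI units (default 0: report
#'   every sign change).
#' @return data.frame with columns `tract`, `feature`, `sex`, `age_years`,
#'   `direction` (zero rows when the median never changes sign).
#' @export
detect_reversals <- function(chart, min_excursion = 0) {
  m <- chart_median(chart)
  g <- chart$age_grid
  s <- sign(m)
  idx <- which(s[-length(s)] * s[-1] < 0)
  keep <- logical(length(idx))
  ages <- numeric(length(idx))
  dir <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    ages[j] <- g[i] + (g[i + 1] - g[i]) * (0 - m[i]) / (m[i + 1] - m[i])
    dir[j] <- if (m[i] < 0) "left_to_right" else "right_to_left"
    # flanking segments run to the neighbouring crossing (or grid end)
    left_start <- if (j == 1L) 1L else idx[j - 1L] + 1L
    right_end <- if (j == length(idx)) length(m) else idx[j + 1L]
    keep[j] <- max(abs(m[left_start:i])) >= min_excursion ||
      max(abs(m[(i + 1):right_end])) >= min_excursion
  }
  if (min_excursion <= 0) keep[] <- TRUE
  data.frame(
    tract = rep(chart$tract, sum(keep)),
    feature = rep(chart$feature, sum(keep)),
    sex = rep(chart$context$sex, sum(keep)),
    age_years = ages[keep],
    direction = dir[keep],
    stringsAsFactors = FALSE
  )
}

#' Mean slope of |median LI| within each lifespan epoch
#'
#' For each epoch, the mean of the first-difference derivative of the
#' absolute median curve over grid points inside `[lo, hi)`; on a uniform
#' grid this equals `(|median|(hi) - |median|(lo)) / (hi - lo)`. Positive
#' slopes mean strengthening asymmetry, negative mean attenuation. The
#' absolute value is taken before differencing, so an epoch containing a
#' zero-crossing mixes signs (the magnitude first attenuates, then rebuilds).
#'
#' @param chart a `centile_chart` containing the 50th level.
#' @param epochs data.frame like [default_epochs()].
#' @return data.frame with `tract`, `feature`, `sex`, `epoch`, `lo`, `hi`,
#'   `slope` (LI units per year).
#' @export
epoch_slopes <- function(chart, epochs = default_epochs()) {
  m <- abs(chart_median(chart))
  g <- chart$age_grid
  slopes <- vapply(seq_len(nrow(epochs)), function(e) {
    i <- which(g >= epochs$lo[e] & g < epochs$hi[e] |
                 (epochs$hi[e] == max(epochs$hi) & g == epochs$hi[e]))
    if (length(i) < 2L) {
      stop("epoch ", epochs$name[e], " intersects the grid in < 2 points")
    }
    mean(diff(m[i]) / diff(g[i]))
  }, numeric(1))
  data.frame(
    tract = chart$tract, feature = chart$feature, sex = chart$context$sex,
    epoch = epochs$name, lo = epochs$lo, hi = epochs$hi, slope = slopes,
    stringsAsFactors = FALSE
  )
}

#' Snapshot summaries of median LI and rightward prevalence
#'
#' For every fitted model, evaluates the population median LI and the
#' model-based percentage of right-lateralized individuals at representative
#' snapshot ages, producing the two heatmap tables (tracts x ages).
#'
#' @param models named list of `normative_model` objects; names like
#'   `"AF/FA"` or set `tract`/`feature` elements on each model.
#' @param ages snapshot ages (default 3, 9, 17, 30, 50, 80 years).
#' @param sex sex context passed to [predict.normative_model()].
#' @return data.frame with `tract`, `feature`, `age_years`, `median_li`,
#'   `pct_right`; one row per model x age.
#' @export
snapshot_summary <- function(models, ages = DEFAULT_SNAPSHOT_AGES,
                             sex = "average") {
  stopifnot(length(models) >= 1L)
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    lab <- names(models)[i] %||% sprintf("model_%d", i)
    parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
    tract <- m$tract %||% parts[1]
    feature <- m$feature %||% if (length(parts) > 1) parts[2] else "feature"
    if (any(ages < m$age_range[1] - 1e-9 | ages > m$age_range[2] + 1e-9)) {
      stop("snapshot age outside the fitted age support for ", lab)
    }
    pr <- predict(m, ages, sex = sex)
    data.frame(
      tract = tract, feature = feature, age_years = ages,
      median_li = pr$mu,
      pct_right = prevalence_right(m, ages, sex = sex),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
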