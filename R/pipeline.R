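# End-to-end pipeline: simulate (or ingest) -> laterality table -> per
# tract-feature BIC model selection -> centile charts -> reversals, epoch
# slopes, snapshots -> optional handedness contrasts. Deterministic given the
# config seed; every fitted model is logged with its BIC and convergence
# status, and every output carries the config hash for provenance.

#' Build a pipeline configuration
#'
#' All defaults follow the package's standard analysis settings: the full
#' 8-power FP set at order up to 3, staged BIC search, centile levels 2.5 /
#' 25 / 50 / 75 / 97.5, the six lifespan epochs and their median snapshot
#' ages, and a 500-point age grid.
#'
#' @param input `NULL` to simulate from `truth`, or a path to a long-format
#'   observation file for [read_observations()].
#' @param truth a [trajectory_truth()] (required when `input` is `NULL`).
#' @param tracts,features labels to process.
#' @param n_cohorts,subjects_per_cohort,age_range simulation design (used
#'   only when `input` is `NULL`).
#' @param power_set,max_order,strategy model-selection settings.
#' @param age_offset years added to age before FP transforms.
#' @param grid_size dense age-grid length for charts.
#' @param levels centile levels (percent).
#' @param epochs epoch table as in [default_epochs()].
#' @param snapshot_ages representative ages for the heatmap tables.
#' @param min_excursion reversal suppression threshold (LI units).
#' @param handedness whether to run the handedness-stratified contrast.
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir where artifacts are written.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, truth = NULL,
                            tracts = c("AF", "CST"),
                            features = c("FA", "volume"),
                            n_cohorts = 6, subjects_per_cohort = 350,
                            age_range = c(0, 100),
                            power_set = FP_POWER_SET, max_order = 3,
                            strategy = "staged",
                            age_offset = 1, grid_size = 500,
                            levels = DEFAULT_LEVELS,
                            epochs = default_epochs(),
                            snapshot_ages = DEFAULT_SNAPSHOT_AGES,
                            min_excursion = 0,
                            handedness = FALSE,
                            seed = 1L, output_dir = "wmasym_out") {
  cfg <- list(
    input = input, truth = truth, tracts = tracts, features = features,
    n_cohorts = n_cohorts, subjects_per_cohort = subjects_per_cohort,
    age_range = age_range, power_set = power_set, max_order = max_order,
    strategy = strategy, age_offset = age_offset, grid_size = grid_size,
    levels = levels, epochs = epochs, snapshot_ages = snapshot_ages,
    min_excursion = min_excursion, handedness = handedness,
    seed = as.integer(seed), output_dir = output_dir
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration (YAML)
#'
#' The trajectory-truth object, if present, is serialized field-by-field so
#' configs round-trip unchanged.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$truth)) {
    t <- x$truth
    x$truth <- list(
      mu_powers = t$spec_mu$powers, mu_coefficients = t$mu_coefficients,
      sigma_powers = t$spec_sigma$powers,
      sigma_coefficients = t$sigma_coefficients,
      sex_effect_mu = t$sex_effect_mu, sex_effect_sigma = t$sex_effect_sigma,
      cohort_sd_mu = t$cohort_sd_mu, cohort_sd_sigma = t$cohort_sd_sigma,
      cohort_offsets_mu = as.list(t$cohort_offsets_mu),
      cohort_offsets_sigma = as.list(t$cohort_offsets_sigma),
      age_offset = t$age_offset, design_range = t$design_range
    )
  }
  if (!is.null(x$epochs)) x$epochs <- as.list(x$epochs)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$truth)) {
    t <- x$truth
    truth <- trajectory_truth(
      mu_powers = t$mu_powers, mu_coefficients = t$mu_coefficients,
      sigma_powers = t$sigma_powers, sigma_coefficients = t$sigma_coefficients,
      sex_effect_mu = t$sex_effect_mu, sex_effect_sigma = t$sex_effect_sigma,
      cohort_sd_mu = 0, cohort_sd_sigma = 0,
      cohort_ids = names(t$cohort_offsets_mu),
      age_offset = t$age_offset, design_range = unlist(t$design_range)
    )
    truth$cohort_sd_mu <- t$cohort_sd_mu
    truth$cohort_sd_sigma <- t$cohort_sd_sigma
    truth$cohort_offsets_mu <- unlist(t$cohort_offsets_mu)
    truth$cohort_offsets_sigma <- unlist(t$cohort_offsets_sigma)
    x$truth <- truth
  }
  if (!is.null(x$epochs)) {
    x$epochs <- as.data.frame(x$epochs, stringsAsFactors = FALSE)
  }
  cfg <- do.call(pipeline_config, x[setdiff(names(x), character(0))])
  cfg
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical YAML serialization, stamped on every pipeline output.
#' The output directory is excluded: the same analysis written to two
#' locations carries the same hash.
#'
#' @param config a `pipeline_config`.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  config$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full asymmetry-chart pipeline
#'
#' Stages: (1) simulate bilateral measures from the configured truth, or
#' ingest an observation file; (2) build the laterality table; (3) per
#' tract-feature, BIC-select the normative model; (4) write centile charts;
#' (5) derive reversals, epoch slopes, and snapshot heatmaps; (6) optionally
#' fit handedness strata and write the Cohen's d contrast. All outputs land
#' under `config$output_dir`; a structured log (one JSON record per fitted
#' model) is written alongside.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the fitted models, charts, and the summary
#'   tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(config$output_dir, "run_log.jsonl")
  log_con <- file(log_path, "wb")
  on.exit(close(log_con))
  log_rec <- function(stage, ...) {
    writeLines(jsonlite::toJSON(list(stage = stage, config_hash = hash, ...),
                                auto_unbox = TRUE, digits = NA), log_con)
  }
  stage_error <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # stage 1-2: observations
  li_tab <- tryCatch({
    if (is.null(config$input)) {
      if (is.null(config$truth)) stop("config needs either input or truth")
      design <- make_cohort_design(
        config$n_cohorts, config$subjects_per_cohort,
        age_range = config$age_range,
        seed = derive_seed(config$seed, "design"))
      tabs <- list()
      for (tr in config$tracts) for (fe in config$features) {
        meas <- simulate_bilateral_measures(
          design, config$truth, baseline = 500, tract = tr, feature = fe,
          seed = derive_seed(config$seed, paste("sim", tr, fe, sep = "/")))
        tabs[[paste(tr, fe, sep = "/")]] <- build_laterality_table(meas, design)
      }
      do.call(rbind, tabs)
    } else {
      obs <- read_observations(config$input)
      if ("li" %in% names(obs)) {
        obs
      } else {
        covs <- unique(obs[, c("subject_id", "age_years", "sex", "cohort_id",
                               "handedness")])
        build_laterality_table(obs, covs)
      }
    }
  }, error = function(e) stage_error("observations", e))
  rownames(li_tab) <- NULL
  write_table_csv(li_tab, file.path(config$output_dir, "laterality_table.csv"))
  log_rec("observations", n = nrow(li_tab))

  combos <- unique(li_tab[, c("tract", "feature")])
  combos <- combos[order(combos$tract, combos$feature), , drop = FALSE]

  # stage 3-4: model selection and charts
  models <- list(); charts <- list()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$tract[i]; fe <- combos$feature[i]
    key <- paste(tr, fe, sep = "/")
    sub <- li_tab[li_tab$tract == tr & li_tab$feature == fe, , drop = FALSE]
    m <- tryCatch(
      select_model(sub, power_set = config$power_set,
                   max_order = config$max_order, strategy = config$strategy,
                   control = fit_control(
                     age_offset = config$age_offset,
                     seed = derive_seed(config$seed, paste0("fit/", key)))),
      error = function(e) stage_error(paste0("fit/", key), e))
    m$tract <- tr; m$feature <- fe
    models[[key]] <- m
    log_rec("fit", tract = tr, feature = fe, spec_mu = format(m$spec_mu),
            spec_sigma = format(m$spec_sigma), n = m$n, k = m$k,
            loglik = m$loglik, bic = m$bic, converged = m$converged)
    grid <- seq(m$age_range[1], m$age_range[2], length.out = config$grid_size)
    ch <- centile_curves(m, grid, levels = config$levels, sex = "average",
                         tract = tr, feature = fe)
    charts[[key]] <- ch
    write_chart(ch, file.path(config$output_dir, "charts",
                              paste(tr, fe, sep = "_")))
  }

  # stage 5: lifespan dynamics
  dyn <- tryCatch({
    reversals <- do.call(rbind, lapply(charts, detect_reversals,
                                       min_excursion = config$min_excursion))
    slopes <- do.call(rbind, lapply(charts, epoch_slopes,
                                    epochs = config$epochs))
    snaps <- snapshot_summary(models, ages = config$snapshot_ages)
    rownames(reversals) <- rownames(slopes) <- rownames(snaps) <- NULL
    write_table_csv(reversals,
                    file.path(config$output_dir, "reversals.csv"),
                    schema = "wmasym-reversals/1")
    write_table_csv(slopes, file.path(config$output_dir, "epoch_slopes.csv"),
                    schema = "wmasym-epoch-slopes/1")
    write_table_csv(snaps, file.path(config$output_dir, "snapshots.csv"),
                    schema = "wmasym-snapshots/1")
    list(reversals = reversals, slopes = slopes, snapshots = snaps)
  }, error = function(e) stage_error("dynamics", e))
  log_rec("dynamics", n_reversals = nrow(dyn$reversals))

  # stage 6: handedness contrasts
  contrasts <- NULL
  if (isTRUE(config$handedness)) {
    contrasts <- tryCatch({
      rows <- list()
      for (key in names(models)) {
        sub <- li_tab[paste(li_tab$tract, li_tab$feature, sep = "/") == key, ,
                      drop = FALSE]
        sf <- stratified_fits(sub, power_set = config$power_set,
                              max_order = config$max_order,
                              strategy = config$strategy,
                              control = fit_control(
                                age_offset = config$age_offset,
                                seed = derive_seed(config$seed,
                                                   paste0("hand/", key))))
        if (all(c("right", "left") %in% names(sf$models))) {
          prof <- cohen_d_profile(sf$models$right, sf$models$left)
          rows[[key]] <- data.frame(
            tract = models[[key]]$tract, feature = models[[key]]$feature,
            mean_d = prof$mean_d, abs_mean_d = prof$abs_mean_d,
            stringsAsFactors = FALSE)
        }
        log_rec("handedness", combo = key,
                fitted = names(sf$models), skipped = sf$skipped$stratum)
      }
      tab <- do.call(rbind, rows)
      if (!is.null(tab)) {
        rownames(tab) <- NULL
        write_table_csv(tab,
                        file.path(config$output_dir, "handedness_contrasts.csv"),
                        schema = "wmasym-handedness/1")
      }
      tab
    }, error = function(e) stage_error("handedness", e))
  }

  log_rec("done")
  invisible(list(laterality_table = li_tab, models = models, charts = charts,
                 reversals = dyn$reversals, epoch_slopes = dyn$slopes,
                 snapshots = dyn$snapshots, handedness = contrasts,
                 config_hash = hash))
}
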