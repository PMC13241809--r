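#!/usr/bin/env Rscript
# Step 5 -- lifespan dynamics from the fitted charts:
#   * reversals: ages where the population-median LI crosses zero;
#   * epoch slopes: mean rate of change of |median LI| in the six life
#     epochs (positive = strengthening asymmetry, negative = attenuation);
#   * snapshots: median LI and % right-lateralized at ages 3, 9, 17, 30,
#     50, 80.
# Writes the three summary tables under results/dynamics/.

suppressPackageStartupMessages(library(wmasym))

dir.create("results/dynamics", recursive = TRUE, showWarnings = FALSE)
model_files <- list.files("results/models", pattern = "^[^_]+_[^_]+\\.json$",
                          full.names = TRUE)
models <- lapply(model_files, read_model)
names(models) <- vapply(models, function(m) paste(m$tract, m$feature, sep = "/"),
                        character(1))
charts <- lapply(models, function(m)
  centile_curves(m, sex = "average", tract = m$tract, feature = m$feature))

reversals <- do.call(rbind, lapply(charts, detect_reversals))
rownames(reversals) <- NULL
if (nrow(reversals) > 0) {
  cat("lateralization reversals (median LI crosses zero):\n")
  for (i in seq_len(nrow(reversals))) {
    cat(sprintf("  %s/%s at %.1f years (%s)\n",
                reversals$tract[i], reversals$feature[i],
                reversals$age_years[i], reversals$direction[i]))
  }
} else cat("no lateralization reversals detected\n")

slopes <- do.call(rbind, lapply(charts, epoch_slopes))
rownames(slopes) <- NULL
strongest <- slopes[which.max(abs(slopes$slope)), ]
cat(sprintf("largest epoch slope of |median LI|: %s/%s in %s (%+.2e per year)\n",
            strongest$tract, strongest$feature, strongest$epoch,
            strongest$slope))

snaps <- snapshot_summary(models)
cat("snapshot median LI / % right-lateralized at the six representative ages:\n")
for (key in unique(paste(snaps$tract, snaps$feature, sep = "/"))) {
  s <- snaps[paste(snaps$tract, snaps$feature, sep = "/") == key, ]
  cat(sprintf("  %-11s %s\n", key,
              paste(sprintf("%g y: %+0.3f/%0.1f%%", s$age_years, s$median_li,
                            s$pct_right), collapse = "  ")))
}

write_table_csv(reversals, "results/dynamics/reversals.csv",
                schema = "wmasym-reversals/1")
write_table_csv(slopes, "results/dynamics/epoch_slopes.csv",
                schema = "wmasym-epoch-slopes/1")
write_table_csv(snaps, "results/dynamics/snapshots.csv",
                schema = "wmasym-snapshots/1")
cat("wrote reversal, epoch-slope and snapshot tables under results/dynamics/\n")
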