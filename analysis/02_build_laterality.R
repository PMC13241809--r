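#!/usr/bin/env Rscript
# Step 2 -- compute the lateralization index LI = (R - L) / (R + L) for every
# subject x tract x feature, dropping (and counting) degenerate rows.
# Reads results/data/observations.csv; writes results/data/laterality_table.csv.

suppressPackageStartupMessages(library(wmasym))

obs <- read_observations("results/data/observations.csv")
rep <- attr(obs, "ingest_report")
cat(sprintf("read %d bilateral rows (%d rejected at ingest)\n",
            rep$n_kept, rep$n_read - rep$n_kept))

covs <- unique(obs[, c("subject_id", "age_years", "sex", "cohort_id",
                       "handedness")])
li_tab <- build_laterality_table(obs, covs)
excl <- attr(li_tab, "exclusions")
cat(sprintf("laterality table: %d observations, %d excluded for non-positive values\n",
            nrow(li_tab), nrow(excl)))

for (key in unique(paste(li_tab$tract, li_tab$feature, sep = "/"))) {
  sub <- li_tab[paste(li_tab$tract, li_tab$feature, sep = "/") == key, ]
  cat(sprintf("  %-11s mean LI %+0.4f, SD %0.4f (n = %d)\n",
              key, mean(sub$li), sd(sub$li), nrow(sub)))
}

write_table_csv(li_tab, "results/data/laterality_table.csv")
cat("wrote results/data/laterality_table.csv\n")
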