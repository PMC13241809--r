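#!/usr/bin/env Rscript
# Step 4 -- build the normative asymmetry charts: centile curves (2.5th,
# 25th, 50th, 75th, 97.5th) on a 500-point age grid, per sex and
# sex-averaged, with cohort offsets at zero (population context). Each chart
# is written as an NPY array (age column + centile columns), a CSV mirror
# and a JSON sidecar under results/charts/.

suppressPackageStartupMessages(library(wmasym))

dir.create("results/charts", recursive = TRUE, showWarnings = FALSE)
model_files <- list.files("results/models", pattern = "^[^_]+_[^_]+\\.json$",
                          full.names = TRUE)

for (mf in model_files) {
  m <- read_model(mf)
  stub <- sub("\\.json$", "", basename(mf))
  for (sex in c("average", "female", "male")) {
    ch <- centile_curves(m, sex = sex, tract = m$tract, feature = m$feature)
    write_chart(ch, file.path("results/charts", paste0(stub, "_", sex)))
  }
  ch <- read_chart(file.path("results/charts", paste0(stub, "_average")))
  mid <- ch$values[round(length(ch$age_grid) / 2), ]
  cat(sprintf("%s: median LI at age %.0f = %+0.4f (2.5th %+0.4f, 97.5th %+0.4f)\n",
              stub, ch$age_grid[round(length(ch$age_grid) / 2)],
              mid["p50"], mid["p2.5"], mid["p97.5"]))
}
cat("wrote", 3 * length(model_files), "charts under results/charts/\n")
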