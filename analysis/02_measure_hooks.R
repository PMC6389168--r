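#!/usr/bin/env Rscript
# Step 2: run the measurement engine on the digitized outlines from step 1
# and check it against the brute-force ground truth.
#
# Reads results/hook_outlines.tps, measures all 14 variables per specimen,
# and reports the worst deviation from results/hook_truth.csv.

suppressPackageStartupMessages(library(hookmorph))

outlines <- read_landmarks_tps("results/hook_outlines.tps")
truth <- read_measurements_csv("results/hook_truth.csv")
species <- setNames(truth$species, truth$specimen_id)

measured <- measure_outlines(outlines, species = species)
write_measurements_csv(measured, "results/hook_measured.csv",
                       comments = "engine measurements of simulated outlines")

lv <- setdiff(hook_variables(), angle_variables())
worst_len <- 0; worst_ang <- 0
for (i in seq_len(nrow(measured))) {
  id <- measured$specimen_id[i]
  got <- unlist(measured[i, hook_variables()])
  ref <- unlist(truth[truth$specimen_id == id, hook_variables()])
  worst_len <- max(worst_len, abs(got - ref)[lv] / pmax(abs(ref[lv]), 1e-9))
  worst_ang <- max(worst_ang, abs(got - ref)[angle_variables()])
}
cat(sprintf("measured %d specimens; worst length deviation %.5f%%, worst angle deviation %.5f deg\n",
            nrow(measured), 100 * worst_len, worst_ang))
cat("engine output -> results/hook_measured.csv\n")
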