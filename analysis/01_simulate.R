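#!/usr/bin/env Rscript
# Step 1: build the synthetic inputs for the whole analysis.
#
# (a) A measurement table drawn from the published per-species summary
#     distributions (P. vaalense, D. paradoxum, P. ichthyoxanthon) at the
#     discriminant-analysis group sizes 8 / 4 / 5.
# (b) A set of parametric hook outlines (three shape "species", four
#     specimens each) with brute-force ground-truth measurements, written as
#     TPS landmark files for the geometry step.

suppressPackageStartupMessages(library(hookmorph))
dir.create("results", showWarnings = FALSE)
seed <- 20190225L
set.seed(seed)

# (a) measurement table from the published summaries
measurements <- generate_measurements(diplozoid_presets(), seed = seed)
write_measurements_csv(measurements, "results/measurements.csv",
                       comments = sprintf("synthetic measurement table, seed=%d", seed))
cat(sprintf("measurement table: %d specimens (%s)\n", nrow(measurements),
            paste(table(measurements$species), collapse = "/")))

# (b) parametric hook outlines with ground truth
species_shapes <- list(
  small = hook_shape_params(shaft_length = 9, blade_inner_radius = 3.5,
                            blade_arc_degrees = 150, handle_length = 32),
  medium = hook_shape_params(shaft_length = 12, blade_inner_radius = 5,
                             blade_arc_degrees = 160, handle_length = 41),
  large = hook_shape_params(shaft_length = 16, blade_inner_radius = 6.5,
                            blade_arc_degrees = 175, handle_length = 55))
jit <- function(x, by = 0.04) x * runif(1, 1 - by, 1 + by)

outlines <- list()
truth_rows <- list()
for (sp in names(species_shapes)) {
  base <- species_shapes[[sp]]
  for (i in 1:4) {
    id <- sprintf("%s_%d", sp, i)
    prm <- hook_shape_params(
      shaft_length = jit(base$shaft_length),
      shaft_width_proximal = jit(base$shaft_width_proximal),
      shaft_width_distal = jit(base$shaft_width_distal),
      blade_inner_radius = jit(base$blade_inner_radius),
      blade_arc_degrees = jit(base$blade_arc_degrees, 0.02),
      point_taper_fraction = jit(base$point_taper_fraction),
      handle_length = jit(base$handle_length),
      rotation = runif(1, 0, 360), translation = runif(2, -30, 30))
    f <- build_hook_outline(prm, id = id)
    outlines[[id]] <- f$outline
    truth_rows[[id]] <- data.frame(specimen_id = id, species = sp,
                                   t(f$truth), check.names = FALSE)
  }
}
write_landmarks_tps(outlines, "results/hook_outlines.tps")
write_outline_csv(outlines, "results/hook_outlines.csv")
truth <- do.call(rbind, truth_rows)
write_measurements_csv(truth, "results/hook_truth.csv",
                       comments = "brute-force ground-truth measurements")
cat(sprintf("outlines: %d specimens -> results/hook_outlines.{tps,csv}\n",
            length(outlines)))
cat("ground truth -> results/hook_truth.csv\n")
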