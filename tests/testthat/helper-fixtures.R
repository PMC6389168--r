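# shared fixture builders; everything is generated in code at test time

# random but valid shape parameters for oracle sweeps
random_shape_params <- function(posed = TRUE, resolution = 120) {
  hook_shape_params(
    shaft_length = runif(1, 8, 18),
    shaft_width_proximal = runif(1, 2, 4),
    shaft_width_distal = runif(1, 1.5, 2.5),
    blade_inner_radius = runif(1, 3, 7),
    blade_arc_degrees = runif(1, 120, 210),
    point_taper_fraction = runif(1, 0.2, 0.5),
    handle_length = runif(1, 30, 60),
    resolution = resolution,
    rotation = if (posed) runif(1, 0, 360) else 0,
    translation = if (posed) runif(2, -50, 50) else c(0, 0))
}

# three synthetic "species" of hook shapes for end-to-end runs
shape_species_params <- function(which = c("small", "medium", "large")) {
  which <- match.arg(which)
  switch(which,
    small = hook_shape_params(shaft_length = 9, blade_inner_radius = 3.5,
                              blade_arc_degrees = 150, handle_length = 32),
    medium = hook_shape_params(shaft_length = 12, blade_inner_radius = 5,
                               blade_arc_degrees = 160, handle_length = 41),
    large = hook_shape_params(shaft_length = 16, blade_inner_radius = 6.5,
                              blade_arc_degrees = 175, handle_length = 55))
}

# Monte-Carlo permutation p for the Kruskal-Wallis H: independent oracle for
# the in-package exact enumeration (label shuffling under the null)
mc_kw_p <- function(x, g, n_perm = 20000) {
  obs <- suppressWarnings(stats::kruskal.test(x, g)$statistic)
  hs <- replicate(n_perm, {
    suppressWarnings(stats::kruskal.test(x, sample(g))$statistic)
  })
  mean(hs >= obs - 1e-12)
}

# tiny separated two-cluster dataset for classification checks
two_cloud_data <- function(n = 6, gap = 50, seed = 7) {
  set.seed(seed)
  d <- rbind(
    data.frame(species = "A", v1 = rnorm(n), v2 = rnorm(n)),
    data.frame(species = "B", v1 = rnorm(n) + gap, v2 = rnorm(n) + gap))
  d$specimen_id <- sprintf("s%02d", seq_len(nrow(d)))
  d
}
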