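#' Measurement vocabulary for diplozoid hook morphometry
#'
#' The 14 point-to-point variables measured on the central hook and handle:
#' hook length (HL), handle length (HNL), aperture distance (AD), proximal
#' shaft width (PSW), point length (PL), distal shaft width (DSW), inner and
#' outer curve length (ICL, OCL), point curve angle (PCA), inner shaft length
#' (ISL), inner aperture angle (IAA), outer shaft length (OSL), outer aperture
#' angle (OAA) and distal point length (DPL). Lengths are in micrometres,
#' angles in degrees.
#'
#' @return Character vector of the 14 variable names, in canonical order.
#' @seealso [angle_variables()] for the subset reported in degrees.
#' @export
#' @examples
#' hook_variables()
hook_variables <- function() {
  c("HL", "HNL", "AD", "PSW", "PL", "DSW", "ICL", "OCL",
    "PCA", "ISL", "IAA", "OSL", "OAA", "DPL")
}

#' @rdname hook_variables
#' @export
angle_variables <- function() {
  c("PCA", "IAA", "OAA")
}

#' Per-variable simulation parameters
#'
#' Marginal summary for one morphometric variable of one species: mean,
#' standard deviation and observed range, in micrometres (or degrees for the
#' three angle variables).
#'
#' @param name One of [hook_variables()].
#' @param mean,sd Mean and standard deviation (sd >= 0).
#' @param range_low,range_high Observed extremes; must bracket the mean.
#' @return A `variable_params` list.
#' @export
variable_params <- function(name, mean, sd, range_low, range_high) {
  name <- match.arg(name, hook_variables())
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  if (!(range_low <= mean && mean <= range_high)) {
    stop(sprintf("variable %s: range [%g, %g] must bracket the mean %g",
                 name, range_low, range_high, mean), call. = FALSE)
  }
  structure(list(name = name, mean = unname(mean), sd = unname(sd),
                 range_low = unname(range_low),
                 range_high = unname(range_high)),
            class = "variable_params")
}

#' Per-species simulation parameters
#'
#' Bundles the marginal summaries of all 14 variables for one species together
#' with a default specimen count.
#'
#' @param species Species label.
#' @param n_default Default number of specimens to simulate.
#' @param variables A list of exactly 14 [variable_params()], one per
#'   measurement name, unique names.
#' @return A `species_params` list.
#' @export
species_params <- function(species, n_default, variables) {
  stopifnot(is.character(species), length(species) == 1,
            n_default >= 0, is.list(variables))
  nm <- vapply(variables, function(v) v$name, character(1))
  if (length(nm) != 14 || anyDuplicated(nm) ||
      !setequal(nm, hook_variables())) {
    stop("a species must carry exactly the 14 named variables", call. = FALSE)
  }
  names(variables) <- nm
  structure(list(species = species, n_default = as.integer(n_default),
                 variables = variables[hook_variables()]),
            class = "species_params")
}
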