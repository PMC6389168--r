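#' Simulate a measurement table from per-species summary distributions
#'
#' Draws synthetic specimens variable by variable from independent Gaussians
#' with the per-species means and standard deviations carried by `params`.
#' Variables are sampled independently because the published summaries are
#' marginal (no covariances are reported); see the methods vignette for the
#' consequences. With `truncate = TRUE`, out-of-range draws are redrawn until
#' they fall inside the published observed range (off by default: ranges are
#' observed extremes, not distribution bounds).
#'
#' @param params Named list of [species_params()], e.g. [diplozoid_presets()].
#' @param n Optional named integer vector of specimens per species; names must
#'   match `params`. Defaults to each species' `n_default`.
#' @param seed Integer seed; required, so tables are reproducible.
#' @param truncate Logical; redraw values outside the published range.
#' @return A data.frame with columns `specimen_id`, `species`, then the 14
#'   measurement variables (lengths in micrometres, angles in degrees).
#' @export
#' @examples
#' d <- generate_measurements(diplozoid_presets(), seed = 1)
#' table(d$species)
generate_measurements <- function(params, n = NULL, seed, truncate = FALSE) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible simulation", call. = FALSE)
  }
  stopifnot(is.list(params), length(params) >= 1)
  sp_names <- vapply(params, function(p) p$species, character(1))
  names(params) <- sp_names

  if (is.null(n)) {
    n <- vapply(params, function(p) p$n_default, integer(1))
  } else {
    if (is.null(names(n)) && length(n) == length(params)) names(n) <- sp_names
    unknown <- setdiff(names(n), sp_names)
    if (length(unknown)) {
      stop("unknown species name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    full <- vapply(params, function(p) p$n_default, integer(1))
    full[names(n)] <- as.integer(n)
    n <- full
  }
  if (any(n < 0)) stop("specimen counts must be >= 0", call. = FALSE)

  set.seed(as.integer(seed))
  vars <- hook_variables()
  blocks <- lapply(sp_names, function(sp) {
    ni <- n[[sp]]
    vals <- matrix(NA_real_, nrow = ni, ncol = length(vars),
                   dimnames = list(NULL, vars))
    for (v in vars) {
      vp <- params[[sp]]$variables[[v]]
      if (ni > 0) {
        x <- stats::rnorm(ni, vp$mean, vp$sd)
        if (truncate) {
          bad <- x < vp$range_low | x > vp$range_high
          while (any(bad)) {
            x[bad] <- stats::rnorm(sum(bad), vp$mean, vp$sd)
            bad <- x < vp$range_low | x > vp$range_high
          }
        }
        vals[, v] <- x
      }
    }
    abbrev <- gsub("[^A-Za-z]", "", abbreviate(sp, 4))
    ids <- if (ni > 0) sprintf("%s_%02d", abbrev, seq_len(ni)) else character(0)
    data.frame(specimen_id = ids,
               species = rep(sp, ni),
               vals, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
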