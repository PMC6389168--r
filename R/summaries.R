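#' Per-species, per-variable measurement summaries
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and observed
#' range for every species x variable cell, available-case per variable
#' (rows missing one variable still contribute to the others). Each cell is
#' also rendered as `"mean ± sd (lo–hi)"`, the conventional layout
#' of morphometric summary tables.
#'
#' @param data Measurement data.frame with a `species` column and measurement
#'   variables.
#' @param variables Variables to summarize; defaults to those of
#'   [hook_variables()] present in `data`.
#' @param digits Decimals used in the rendered label.
#' @return Long data.frame: species, variable, n, mean, sd, min, max, label.
#' @export
#' @examples
#' d <- generate_measurements(diplozoid_presets(), seed = 1)
#' head(summarize_measurements(d))
summarize_measurements <- function(data, variables = NULL, digits = 2) {
  stopifnot(is.data.frame(data), "species" %in% names(data))
  variables <- variables %||% intersect(hook_variables(), names(data))
  stopifnot(length(variables) >= 1, all(variables %in% names(data)))
  species <- unique(as.character(data$species))
  rows <- list()
  for (sp in species) {
    sub <- data[data$species == sp, , drop = FALSE]
    if (nrow(sub) == 0) stop("species with no rows: ", sp, call. = FALSE)
    for (v in variables) {
      x <- sub[[v]]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n == 0) stop(sprintf("no observations for %s / %s", sp, v),
                       call. = FALSE)
      s <- if (n == 1) {
        warning(sprintf("%s / %s: single observation, SD reported as 0",
                        sp, v))
        0
      } else stats::sd(x)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, variable = v, n = n, mean = mean(x), sd = s,
        min = min(x), max = max(x),
        label = format_summary(mean(x), s, min(x), max(x), digits),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname summarize_measurements
#' @param mean,sd,min,max Summary components of a single cell.
#' @export
format_summary <- function(mean, sd, min, max, digits = 2) {
  fmt <- sprintf("%%.%df", digits)
  sprintf(paste0(fmt, " ± ", fmt, " (", fmt, "–", fmt, ")"),
          mean, sd, min, max)
}
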