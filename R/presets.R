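#' Published per-species measurement summaries for three diplozoid species
#'
#' Marginal summary statistics (mean, standard deviation, observed range) of
#' the 14 hook and handle measurements reported for *Paradiplozoon vaalense*,
#' *Diplozoon paradoxum* and *Paradiplozoon ichthyoxanthon* studied by SEM
#' after enzymatic digestion. Lengths are in micrometres, the three aperture /
#' curve angles (PCA, IAA, OAA) in degrees. Default group sizes are 8, 4 and 5
#' specimens respectively: the listwise-complete group sizes used by the
#' published discriminant analysis (the *P. vaalense* univariate summaries
#' were based on 10 specimens, of which 8 were complete cases).
#'
#' @return Named list of three [species_params()] objects.
#' @seealso [generate_measurements()] to draw synthetic specimens from these
#'   distributions.
#' @export
#' @examples
#' p <- diplozoid_presets()
#' p[["D. paradoxum"]]$variables[["HL"]]$mean
diplozoid_presets <- function() {
  # columns: variable, mean, sd, range_low, range_high
  tab <- list(
    "P. vaalense" = list(
      n = 8L,
      rows = rbind(
        HL  = c(18.53, 0.39, 17.77, 19.35),
        HNL = c(41.45, 0.96, 39.23, 42.07),
        AD  = c(12.80, 0.33, 12.55, 13.41),
        PSW = c(3.72, 0.26, 3.26, 4.16),
        PL  = c(7.95, 0.30, 7.36, 8.44),
        DSW = c(2.81, 0.22, 2.61, 3.18),
        ICL = c(1.89, 0.18, 1.67, 2.10),
        OCL = c(3.06, 0.27, 2.80, 3.52),
        PCA = c(13.43, 2.81, 9.44, 17.81),
        ISL = c(12.08, 0.36, 11.31, 12.83),
        IAA = c(85.13, 5.45, 76.57, 92.98),
        OSL = c(15.94, 0.41, 15.05, 16.75),
        OAA = c(78.70, 3.44, 73.72, 84.57),
        DPL = c(7.46, 0.45, 6.70, 8.06))),
    "D. paradoxum" = list(
      n = 4L,
      rows = rbind(
        HL  = c(30.67, 0.65, 30.02, 31.37),
        HNL = c(67.70, 2.34, 63.95, 70.38),
        AD  = c(22.87, 0.69, 22.02, 23.71),
        PSW = c(3.66, 0.15, 3.42, 3.80),
        PL  = c(13.08, 0.31, 12.62, 13.49),
        DSW = c(3.38, 0.21, 3.16, 3.69),
        ICL = c(3.37, 0.20, 3.05, 3.60),
        OCL = c(4.85, 0.28, 4.42, 5.22),
        PCA = c(9.49, 2.28, 7.50, 13.15),
        ISL = c(22.81, 0.58, 22.22, 23.76),
        IAA = c(77.76, 3.44, 74.30, 83.17),
        OSL = c(25.34, 0.51, 24.75, 26.08),
        OAA = c(75.35, 3.00, 72.55, 80.39),
        DPL = c(12.77, 0.29, 12.39, 13.12))),
    "P. ichthyoxanthon" = list(
      n = 5L,
      rows = rbind(
        HL  = c(25.23, 0.57, 24.78, 26.29),
        HNL = c(55.25, 3.23, 51.91, 59.30),
        AD  = c(18.08, 0.67, 17.65, 19.40),
        PSW = c(4.10, 0.28, 3.66, 4.53),
        PL  = c(10.54, 0.11, 10.39, 10.71),
        DSW = c(3.85, 0.18, 3.59, 4.12),
        ICL = c(2.53, 0.16, 2.42, 2.85),
        OCL = c(4.34, 0.20, 4.00, 4.59),
        PCA = c(15.46, 3.95, 10.68, 21.54),
        ISL = c(16.59, 0.54, 15.63, 17.22),
        IAA = c(89.69, 4.72, 84.71, 96.61),
        OSL = c(21.03, 0.34, 20.55, 21.48),
        OAA = c(79.91, 3.29, 76.49, 85.84),
        DPL = c(10.03, 0.18, 9.86, 10.37))))

  out <- lapply(names(tab), function(sp) {
    rows <- tab[[sp]]$rows
    vars <- lapply(rownames(rows), function(v) {
      variable_params(v, rows[v, 1], rows[v, 2], rows[v, 3], rows[v, 4])
    })
    species_params(sp, tab[[sp]]$n, vars)
  })
  names(out) <- names(tab)
  out
}
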