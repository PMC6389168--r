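#' Control parameters for the hook measurement geometry
#'
#' @param step Densification step in micrometres for zenith searches; edges
#'   are resampled at this spacing before apex searches (default 0.01 um).
#' @param distal_window,proximal_window Projection windows, as fractions of
#'   an edge's projection span onto the aperture-distance (tip-to-base) line,
#'   in which the outer-edge zenith (distal: point-side apex defining PL) and
#'   the heel zenith (proximal) are searched. The published protocol separates
#'   the two apices only pictorially; a fixed 40% split is used by default.
#' @param min_curvature Minimum blade curve depth (outer curve length)
#'   relative to the aperture distance below which the outline is rejected as
#'   a degenerate, bladeless "hook".
#' @return A list of control parameters.
#' @export
geometry_control <- function(step = 0.01, distal_window = c(0.4, 1),
                             proximal_window = c(0, 0.4),
                             min_curvature = 1e-6) {
  stopifnot(step > 0, length(distal_window) == 2, length(proximal_window) == 2,
            min_curvature >= 0)
  list(step = step, distal_window = distal_window,
       proximal_window = proximal_window, min_curvature = min_curvature)
}

#' Fit the shaft axis of a hook
#'
#' Total-least-squares line through the flagged straight section of the inner
#' shaft edge (the principal axis of the flagged vertices' scatter), oriented
#' from the articulation base toward the tip. The hook length HL is measured
#' parallel to this axis.
#'
#' @param outline A [hook_outline()].
#' @return List with `point` (centroid) and `direction` (unit vector, base to
#'   tip).
#' @export
fit_shaft_axis <- function(outline) {
  stopifnot(inherits(outline, "hook_outline"))
  pts <- outline$inner_edge[outline$straight_range, , drop = FALSE]
  ctr <- colMeans(pts)
  dev <- sweep(pts, 2, ctr)
  if (max(abs(dev)) < .Machine$double.eps^0.5 * max(1, max(abs(ctr)))) {
    stop("degenerate straight section: all flagged vertices coincide",
         call. = FALSE)
  }
  S <- crossprod(dev)
  e <- eigen(S, symmetric = TRUE)
  dir <- e$vectors[, 1]
  # edges run tip -> base, so earlier flagged vertices are nearer the tip
  toward_tip <- pts[1, ] - pts[nrow(pts), ]
  if (sum(dir * toward_tip) < 0) dir <- -dir
  list(point = ctr, direction = dir)
}

#' Find the zenith of an edge relative to a reference line
#'
#' The zenith is the edge point at maximal perpendicular distance from the
#' reference line, among points whose projection onto the line falls in a
#' stated window. Candidates are the vertices of a densification of the edge
#' at a fixed arc-length step, plus the exact points where the edge crosses
#' the window boundaries (so window-limited zeniths do not depend on the
#' sampling grid). Projections are normalized to \[0, 1\] over the span of
#' the original vertices' projections. Ties are broken by smallest arc length
#' from the tip (the edge's first vertex).
#'
#' @param edge n x 2 polyline, ordered from the tip.
#' @param line_point,line_direction Reference line (point + direction).
#' @param region Length-2 window in \[0, 1\] of the normalized projection.
#' @param step Densification step (micrometres).
#' @return List with `point`, `distance` (perpendicular, >= 0), `arc_length`
#'   from the edge's first vertex, and `projection` (unnormalized).
#' @export
find_zenith <- function(edge, line_point, line_direction, region = c(0, 1),
                        step = 0.01) {
  edge <- as_coord_matrix(edge, "edge")
  if (length(region) != 2 || region[1] > region[2]) {
    stop("region must be an interval c(lo, hi) with lo <= hi", call. = FALSE)
  }
  a <- as.numeric(line_point)
  u <- unitize(as.numeric(line_direction))

  # window bounds in raw projection units, from the exact vertices
  t_vert <- proj_component(edge, a, u)
  span <- max(t_vert) - min(t_vert)
  if (span > 0) {
    lo <- min(t_vert) + region[1] * span
    hi <- min(t_vert) + region[2] * span
  } else {
    lo <- -Inf; hi <- Inf # edge perpendicular to u: whole edge qualifies
  }

  dens <- resample_polyline(edge, step = step)
  pts <- dens$points
  s <- dens$s
  # exact crossings of the window boundaries along the original polyline
  s_vert <- arc_lengths(edge)
  for (cut in c(lo, hi)) {
    if (!is.finite(cut)) next
    cr <- polyline_level_crossings(edge, t_vert, s_vert, cut)
    if (nrow(cr$points)) {
      pts <- rbind(pts, cr$points)
      s <- c(s, cr$s)
    }
  }
  t_raw <- proj_component(pts, a, u)
  eps <- 1e-9 * max(1, span)
  sel <- which(t_raw >= lo - eps & t_raw <= hi + eps)
  if (!length(sel)) stop("empty projection region", call. = FALSE)
  d <- abs(perp_component(pts[sel, , drop = FALSE], a, u))
  dmax <- max(d)
  tol <- 1e-9 * max(1, dmax)
  cand <- sel[d >= dmax - tol]
  best <- cand[which.min(s[cand])] # tie-break: nearest the tip
  list(point = pts[best, ],
       distance = abs(perp_component(pts[best, , drop = FALSE], a, u)),
       arc_length = s[best],
       projection = t_raw[best])
}

# exact points where a per-vertex linear quantity (values `v` at the
# vertices of polyline P, arc lengths s_vert) crosses `level`
polyline_level_crossings <- function(P, v, s_vert, level) {
  n <- nrow(P)
  a <- v[-n] - level
  b <- v[-1] - level
  hit <- which(a * b <= 0 & !(a == 0 & b == 0))
  if (!length(hit)) {
    return(list(points = matrix(numeric(0), 0, 2), s = numeric(0)))
  }
  t <- a[hit] / (a[hit] - b[hit])
  list(points = cbind(P[hit, 1] + t * (P[hit + 1, 1] - P[hit, 1]),
                      P[hit, 2] + t * (P[hit + 1, 2] - P[hit, 2])),
       s = s_vert[hit] + t * (s_vert[hit + 1] - s_vert[hit]))
}

# point on polyline P at arc length s0 (clamped to the polyline's length)
polyline_point_at <- function(P, s0) {
  s <- arc_lengths(P)
  s0 <- min(max(s0, 0), s[length(s)])
  i <- max(1L, findInterval(s0, s, rightmost.closed = TRUE))
  i <- min(i, nrow(P) - 1L)
  w <- (s0 - s[i]) / max(s[i + 1] - s[i], .Machine$double.xmin)
  P[i, ] + w * (P[i + 1, ] - P[i, ])
}

# all intersections of the infinite line (a, direction v) with a polyline;
# returns a matrix of intersection points (possibly 0 rows)
line_polyline_intersections <- function(P, a, v) {
  cp <- perp_component(P, a, unitize(v))
  n <- nrow(P)
  c1 <- cp[-n]
  c2 <- cp[-1]
  hit <- which((c1 <= 0 & c2 >= 0) | (c1 >= 0 & c2 <= 0))
  hit <- hit[!(c1[hit] == 0 & c2[hit] == 0)] # skip collinear segments
  if (!length(hit)) return(matrix(numeric(0), 0, 2))
  t <- c1[hit] / (c1[hit] - c2[hit])
  cbind(P[hit, 1] + t * (P[hit + 1, 1] - P[hit, 1]),
        P[hit, 2] + t * (P[hit + 1, 2] - P[hit, 2]))
}

#' Derive the construction landmarks of a hook outline
#'
#' Computes the auxiliary points from which the point-to-point measurements
#' are defined:
#' * the aperture-distance (AD) line from the tip T to the articulation base B;
#' * `Z_out`, the zenith of the outer edge relative to the AD line in the
#'   distal window (the apex through which the point length PL is measured);
#' * `F_AD`, the perpendicular foot of `Z_out` on the AD line, so the PL line
#'   runs through `F_AD` and `Z_out`;
#' * `P_in`, the intersection of the PL line with the inner edge nearest
#'   `F_AD` (the section at which the distal shaft width DSW is read);
#' * `H_heel`, the heel zenith of the outer edge in the proximal window;
#' * the blade chord from T to `Z_out`, and the inner/outer blade zeniths
#'   relative to that chord (`Z_inner_blade`, `Z_outer_blade`), which define
#'   the inner and outer curve lengths.
#'
#' @param outline A [hook_outline()].
#' @param control A [geometry_control()] list.
#' @return A `hook_landmarks` list.
#' @export
derive_landmarks <- function(outline, control = geometry_control()) {
  stopifnot(inherits(outline, "hook_outline"))
  T_ <- outline$tip
  B <- outline$articulation_base
  AD <- vnorm(T_ - B)
  if (AD < .Machine$double.eps^0.5) {
    stop("tip and articulation base coincide", call. = FALSE)
  }
  u_AD <- (T_ - B) / AD

  z_out <- find_zenith(outline$outer_edge, B, u_AD,
                       region = control$distal_window, step = control$step)
  if (z_out$distance < control$min_curvature * AD) {
    stop("degenerate hook: outer edge has no curvature in the distal window",
         call. = FALSE)
  }
  Z_out <- z_out$point
  F_AD <- B + sum((Z_out - B) * u_AD) * u_AD
  v_PL <- Z_out - F_AD
  if (vnorm(v_PL) < .Machine$double.eps^0.5) {
    stop("degenerate hook: outer zenith lies on the AD line", call. = FALSE)
  }

  inner_dense <- resample_polyline(outline$inner_edge, step = control$step)
  hits <- line_polyline_intersections(inner_dense$points, F_AD, v_PL)
  if (!nrow(hits)) {
    stop("geometry error: PL line does not intersect the inner edge",
         call. = FALSE)
  }
  dists <- sqrt((hits[, 1] - F_AD[1])^2 + (hits[, 2] - F_AD[2])^2)
  P_in <- hits[which.min(dists), ]

  h_heel <- find_zenith(outline$outer_edge, B, u_AD,
                        region = control$proximal_window, step = control$step)
  H_heel <- h_heel$point

  # blade chord: tip to outer zenith
  chord_len <- vnorm(Z_out - T_)
  if (chord_len < .Machine$double.eps^0.5) {
    stop("degenerate hook: outer zenith coincides with the tip", call. = FALSE)
  }
  u_ch <- (Z_out - T_) / chord_len

  # the blade spans the first s(Z_out) of arc from the tip on either edge;
  # the exact cutoff point is added so the window edge is grid-independent
  s_cut <- z_out$arc_length
  blade_zenith <- function(edge, dense, extra_pt, extra_s) {
    keep <- which(dense$s <= s_cut)
    pts <- rbind(dense$points[keep, , drop = FALSE], extra_pt)
    s <- c(dense$s[keep], extra_s)
    d <- abs(perp_component(pts, T_, u_ch))
    dmax <- max(d)
    tol <- 1e-9 * max(1, dmax)
    cand <- which(d >= dmax - tol)
    best <- cand[which.min(s[cand])]
    list(point = pts[best, ], distance = dmax)
  }
  zi <- blade_zenith(outline$inner_edge, inner_dense,
                     matrix(polyline_point_at(outline$inner_edge, s_cut), 1),
                     s_cut)
  Z_inner_blade <- zi$point
  outer_dense <- resample_polyline(outline$outer_edge, step = control$step)
  zo <- blade_zenith(outline$outer_edge, outer_dense, matrix(Z_out, 1), s_cut)
  if (zo$distance < control$min_curvature * AD) {
    stop("degenerate hook: no blade curvature between tip and outer zenith",
         call. = FALSE)
  }
  Z_outer_blade <- zo$point

  structure(list(tip = T_, base = B, ad_direction = u_AD,
                 Z_out = Z_out, F_AD = F_AD, P_in = P_in, H_heel = H_heel,
                 Z_inner_blade = Z_inner_blade, Z_outer_blade = Z_outer_blade,
                 chord_direction = u_ch, chord_length = chord_len,
                 shaft_axis = fit_shaft_axis(outline)),
            class = "hook_landmarks")
}

#' Measure the 13 hook variables from an outline
#'
#' Computes the hook measurements from the derived landmarks (see
#' [derive_landmarks()] for the constructions):
#' * `AD` = |T - B|, `PSW` = |B - H_heel|, `PL` = |F_AD - Z_out|,
#'   `DSW` = |P_in - Z_out|, `DPL` = |T - Z_out|, `ISL` = |P_in - B|,
#'   `OSL` = |Z_out - H_heel|;
#' * `ICL`, `OCL`: perpendicular depths of the inner/outer blade zeniths from
#'   the blade chord T-Z_out (blade = the first s(Z_out) of arc from the tip);
#' * `PCA`: the point curve angle, at vertex Z_out between the rays to F_AD
#'   (down the PL line) and to T (along the chord) -- the acute angle between
#'   the PL line and the blade chord, `acos(PL/DPL)`; `OAA`: angle at Z_out
#'   between the rays to H_heel and to T; `IAA`: angle at P_in between the
#'   rays to B and to T;
#' * `HL`: extent of the projections of all outline vertices onto the shaft
#'   axis (proximal to distal zenith of the entire hook, parallel to the
#'   straight inner edge of the shaft).
#'
#' Lengths in micrometres, angles in degrees. The handle length HNL is
#' measured separately by [measure_handle()].
#'
#' @param outline A [hook_outline()].
#' @param control A [geometry_control()] list.
#' @return Named numeric vector of the 13 hook variables.
#' @export
measure_hook <- function(outline, control = geometry_control()) {
  lm <- derive_landmarks(outline, control)
  T_ <- lm$tip; B <- lm$base
  AD <- vnorm(T_ - B)
  PSW <- vnorm(B - lm$H_heel)
  PL <- vnorm(lm$F_AD - lm$Z_out)
  DSW <- vnorm(lm$P_in - lm$Z_out)
  DPL <- vnorm(T_ - lm$Z_out)
  ISL <- vnorm(lm$P_in - B)
  OSL <- vnorm(lm$Z_out - lm$H_heel)
  ICL <- abs(perp_component(matrix(lm$Z_inner_blade, 1), T_,
                            lm$chord_direction))
  OCL <- abs(perp_component(matrix(lm$Z_outer_blade, 1), T_,
                            lm$chord_direction))
  PCA <- angle_between(lm$F_AD - lm$Z_out, T_ - lm$Z_out)
  OAA <- angle_between(lm$H_heel - lm$Z_out, T_ - lm$Z_out)
  IAA <- angle_between(B - lm$P_in, T_ - lm$P_in)
  proj <- proj_component(rbind(outline$inner_edge, outline$outer_edge),
                         lm$shaft_axis$point, lm$shaft_axis$direction)
  HL <- max(proj) - min(proj)
  c(HL = HL, AD = AD, PSW = PSW, PL = PL, DSW = DSW, ICL = ICL, OCL = OCL,
    PCA = PCA, ISL = ISL, IAA = IAA, OSL = OSL, OAA = OAA, DPL = DPL)
}

#' Measure the handle length
#'
#' HNL: Euclidean distance from the handle tip to the handle base.
#' Coincident points yield 0 with a warning.
#'
#' @param handle_tip,handle_base Length-2 points (micrometres).
#' @return Handle length in micrometres.
#' @export
measure_handle <- function(handle_tip, handle_base) {
  d <- vnorm(as.numeric(handle_tip) - as.numeric(handle_base))
  if (d == 0) warning("handle tip and base coincide; HNL = 0")
  d
}

#' Measure all 14 variables of one specimen
#'
#' Runs [measure_hook()] and, if the outline carries a handle,
#' [measure_handle()]; HNL is `NA` when no handle is digitized.
#'
#' @inheritParams measure_hook
#' @return Named numeric vector over [hook_variables()].
#' @export
measure_specimen <- function(outline, control = geometry_control()) {
  m <- measure_hook(outline, control)
  hnl <- if (is.null(outline$handle)) NA_real_ else {
    measure_handle(outline$handle[1, ], outline$handle[2, ])
  }
  out <- c(m, HNL = hnl)
  out[hook_variables()]
}

#' Measure a collection of outlines into a measurement table
#'
#' @param outlines List of [hook_outline()] objects.
#' @param species Optional character vector (or named map from specimen id)
#'   of species labels.
#' @param control A [geometry_control()] list.
#' @return A measurement data.frame (`specimen_id`, `species`, 14 variables).
#' @export
measure_outlines <- function(outlines, species = NULL,
                             control = geometry_control()) {
  stopifnot(is.list(outlines), length(outlines) >= 1)
  ids <- vapply(outlines, function(o) o$id, character(1))
  vals <- t(vapply(outlines, function(o) {
    tryCatch(measure_specimen(o, control), error = function(e) {
      stop(sprintf("specimen '%s': %s", o$id, conditionMessage(e)),
           call. = FALSE)
    })
  }, numeric(14)))
  colnames(vals) <- hook_variables()
  sp <- if (is.null(species)) rep(NA_character_, length(ids))
        else if (!is.null(names(species))) unname(species[ids])
        else as.character(species)
  data.frame(specimen_id = ids, species = sp, vals,
             stringsAsFactors = FALSE, row.names = NULL)
}
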