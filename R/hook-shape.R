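#' Parameters of the parametric hook shape grammar
#'
#' A synthetic central hook consistent with diplozoid hook anatomy: a straight
#' shaft (a tapering strip), a blade that is an arc of a circular annulus
#' tangent to the shaft, and a point that tapers the annulus thickness to a
#' single tip vertex over the final fraction of the arc. The handle is a
#' straight segment articulating at the shaft base. All lengths in
#' micrometres, the blade arc in degrees.
#'
#' @param shaft_length Length of the straight shaft.
#' @param shaft_width_proximal,shaft_width_distal Strip widths at the base and
#'   at the shaft-blade junction.
#' @param blade_inner_radius Radius of the inner (concave) blade arc.
#' @param blade_arc_degrees Angular sweep of the blade, in (0, 270).
#' @param point_taper_fraction Fraction of the arc, from the tip backwards,
#'   over which the blade thickness tapers linearly to zero; in (0, 1\].
#' @param handle_length Handle length.
#' @param resolution Vertices per edge (>= 50).
#' @param rotation,translation Rigid pose applied to the finished outline.
#' @return A `hook_shape_params` list.
#' @export
hook_shape_params <- function(shaft_length = 12, shaft_width_proximal = 3,
                              shaft_width_distal = 2.5,
                              blade_inner_radius = 5, blade_arc_degrees = 160,
                              point_taper_fraction = 0.35, handle_length = 40,
                              resolution = 100, rotation = 0,
                              translation = c(0, 0)) {
  p <- list(shaft_length = shaft_length,
            shaft_width_proximal = shaft_width_proximal,
            shaft_width_distal = shaft_width_distal,
            blade_inner_radius = blade_inner_radius,
            blade_arc_degrees = blade_arc_degrees,
            point_taper_fraction = point_taper_fraction,
            handle_length = handle_length,
            resolution = as.integer(resolution),
            rotation = rotation, translation = translation)
  lens <- c(p$shaft_length, p$shaft_width_proximal, p$shaft_width_distal,
            p$blade_inner_radius, p$handle_length)
  if (any(lens <= 0)) stop("all lengths must be > 0", call. = FALSE)
  if (!(p$blade_arc_degrees > 0 && p$blade_arc_degrees < 270)) {
    stop("blade_arc_degrees must be in (0, 270)", call. = FALSE)
  }
  if (!(p$point_taper_fraction > 0 && p$point_taper_fraction <= 1)) {
    stop("point_taper_fraction must be in (0, 1]", call. = FALSE)
  }
  if (p$resolution < 50) stop("resolution must be >= 50", call. = FALSE)
  structure(p, class = "hook_shape_params")
}

# build the inner and outer edge polylines (base -> tip order) in the
# canonical pose: shaft along +x from the base, blade curling counterclockwise
build_hook_edges <- function(p, resolution) {
  L <- p$shaft_length
  r <- p$blade_inner_radius
  R <- r + p$shaft_width_distal
  A <- deg2rad(p$blade_arc_degrees)
  C <- c(L, r)                      # annulus centre, above the shaft tip
  phi0 <- -pi / 2                   # blade starts tangent to the shaft
  phi1 <- phi0 + A
  phi_taper <- phi1 - A * p$point_taper_fraction

  arc_len_in <- r * A
  n_straight <- max(10L, round(resolution * L / (L + arc_len_in)))
  n_arc <- max(10L, resolution - n_straight)

  # inner edge: straight strip edge on y = 0, then the inner arc
  xs <- seq(0, L, length.out = n_straight)
  phi <- seq(phi0, phi1, length.out = n_arc + 1L)[-1L]
  inner <- rbind(cbind(xs, 0),
                 cbind(C[1] + r * cos(phi), C[2] + r * sin(phi)))

  # outer edge: straight strip edge, then the outer arc with the point taper
  ys <- seq(-p$shaft_width_proximal, -p$shaft_width_distal,
            length.out = n_straight)
  Rout <- ifelse(phi <= phi_taper, R,
                 R - (R - r) * (phi - phi_taper) / (phi1 - phi_taper))
  outer <- rbind(cbind(xs, ys),
                 cbind(C[1] + Rout * cos(phi), C[2] + Rout * sin(phi)))
  # force the exact shared tip vertex
  tipv <- C + r * c(cos(phi1), sin(phi1))
  inner[nrow(inner), ] <- tipv
  outer[nrow(outer), ] <- tipv
  list(inner = inner, outer = outer, n_straight = n_straight, tip = tipv)
}

#' Build a parametric hook outline with ground truth
#'
#' Constructs a [hook_outline()] from a [hook_shape_params()] shape (shaft
#' strip + annular blade + tapered point + straight handle), applies the
#' requested rigid pose, and computes ground-truth landmarks and measurements
#' with [measure_hook_reference()] -- an exhaustive search over a densely
#' resampled (40x) copy of the same outline -- so the production measurement
#' engine can be validated against it. Parameter combinations producing a
#' self-intersecting outline are rejected.
#'
#' @param params A [hook_shape_params()] object.
#' @param id Specimen identifier.
#' @param control A [geometry_control()] list (windows shared with the
#'   reference measurements).
#' @return List with elements `outline` (a `hook_outline`), `truth` (named
#'   vector over [hook_variables()]), and `params`.
#' @export
build_hook_outline <- function(params, id = "synthetic",
                               control = geometry_control()) {
  stopifnot(inherits(params, "hook_shape_params"))
  e <- build_hook_edges(params, params$resolution)

  # tip -> base ordering, as required by hook_outline
  inner <- e$inner[rev(seq_len(nrow(e$inner))), ]
  outer <- e$outer[rev(seq_len(nrow(e$outer))), ]
  B <- c(0, -params$shaft_width_proximal / 2)
  handle <- rbind(B, B - c(params$handle_length, 0)) # tip at B, base proximal
  n_in <- nrow(inner)
  straight <- (n_in - e$n_straight + 1L):n_in

  out <- hook_outline(inner, outer, B, handle = handle,
                      straight_range = straight, id = id)
  out <- transform_outline(out, rotation = params$rotation,
                           translation = params$translation)
  if (!ring_is_simple(outline_ring(out))) {
    stop("shape parameters produce a self-intersecting outline",
         call. = FALSE)
  }
  truth <- measure_hook_reference(out, factor = 40, control = control)
  truth["HNL"] <- params$handle_length
  list(outline = out, truth = truth[hook_variables()], params = params)
}

# --- reference (brute force) implementation -------------------------------

# dense arc-length resampling used only by the reference path; deliberately
# separate from resample_polyline so the two code paths stay independent.
# Original vertices are kept in the sample (polyline extrema live there).
.dense_resample <- function(P, n) {
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  si <- sort(unique(c(seq(0, s[length(s)], length.out = n), s)))
  idx <- findInterval(si, s, rightmost.closed = TRUE)
  idx[idx >= nrow(P)] <- nrow(P) - 1L
  w <- (si - s[idx]) / pmax(s[idx + 1L] - s[idx], .Machine$double.xmin)
  list(points = P[idx, , drop = FALSE] +
         w * (P[idx + 1L, , drop = FALSE] - P[idx, , drop = FALSE]),
       s = si)
}

.ref_perp <- function(pts, a, u) u[1] * (pts[, 2] - a[2]) - u[2] * (pts[, 1] - a[1])
.ref_proj <- function(pts, a, u) u[1] * (pts[, 1] - a[1]) + u[2] * (pts[, 2] - a[2])

.ref_angle <- function(v1, v2) {
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  180 / pi * acos(min(1, max(-1, ct)))
}

#' Reference hook measurements by exhaustive dense search
#'
#' Independent implementation of the 13 hook measurements used as ground
#' truth for synthetic fixtures: every zenith is found by exhaustive argmax
#' over the vertices of a densely resampled copy of each edge (`factor` times
#' the stored vertex count), and the PL-line/inner-edge intersection is an
#' exhaustive scan over all dense segments. Shares the measurement
#' definitions, but not the search code, with [measure_hook()].
#'
#' @param outline A [hook_outline()].
#' @param factor Densification factor (>= 10 recommended).
#' @param control A [geometry_control()] list (projection windows).
#' @return Named numeric vector of the 13 hook variables.
#' @export
measure_hook_reference <- function(outline, factor = 40,
                                   control = geometry_control()) {
  T_ <- outline$tip
  B <- outline$articulation_base
  din <- .dense_resample(outline$inner_edge, factor * nrow(outline$inner_edge))
  dout <- .dense_resample(outline$outer_edge, factor * nrow(outline$outer_edge))

  AD <- sqrt(sum((T_ - B)^2))
  u <- (T_ - B) / AD

  # window bounds from the exact outer-edge vertices; boundary crossings are
  # interpolated exactly and appended to the candidate set
  tv <- .ref_proj(outline$outer_edge, B, u)
  sv <- {
    seg <- sqrt(rowSums((outline$outer_edge[-1, , drop = FALSE] -
                           outline$outer_edge[-nrow(outline$outer_edge), ,
                                              drop = FALSE])^2))
    c(0, cumsum(seg))
  }
  span <- max(tv) - min(tv)
  cuts <- min(tv) + span * sort(unique(c(control$distal_window,
                                         control$proximal_window)))
  extra_pts <- matrix(numeric(0), 0, 2)
  extra_s <- numeric(0)
  nv <- nrow(outline$outer_edge)
  for (cut in cuts) {
    a <- tv[-nv] - cut
    b <- tv[-1] - cut
    hit <- which(a * b <= 0 & !(a == 0 & b == 0))
    if (length(hit)) {
      tt <- a[hit] / (a[hit] - b[hit])
      extra_pts <- rbind(extra_pts,
                         outline$outer_edge[hit, , drop = FALSE] +
                           tt * (outline$outer_edge[hit + 1, , drop = FALSE] -
                                   outline$outer_edge[hit, , drop = FALSE]))
      extra_s <- c(extra_s, sv[hit] + tt * (sv[hit + 1] - sv[hit]))
    }
  }
  cand_pts <- rbind(dout$points, extra_pts)
  cand_s <- c(dout$s, extra_s)
  cand_t <- .ref_proj(cand_pts, B, u)
  eps <- 1e-9 * max(1, span)
  window_argmax <- function(w) {
    lo <- min(tv) + w[1] * span
    hi <- min(tv) + w[2] * span
    sel <- which(cand_t >= lo - eps & cand_t <= hi + eps)
    d <- abs(.ref_perp(cand_pts[sel, , drop = FALSE], B, u))
    best <- sel[order(d, -cand_s[sel], decreasing = TRUE)[1]]
    list(point = cand_pts[best, ], s = cand_s[best])
  }
  zo <- window_argmax(control$distal_window)
  Z_out <- zo$point
  s_zout <- zo$s
  H_heel <- window_argmax(control$proximal_window)$point

  F_AD <- B + sum((Z_out - B) * u) * u
  v <- Z_out - F_AD
  uv <- v / sqrt(sum(v^2))
  cp <- .ref_perp(din$points, F_AD, uv)
  n <- length(cp)
  sign_change <- which(cp[-n] * cp[-1] <= 0 & !(cp[-n] == 0 & cp[-1] == 0))
  if (!length(sign_change)) {
    stop("reference: PL line does not cross the inner edge", call. = FALSE)
  }
  tpar <- cp[sign_change] / (cp[sign_change] - cp[sign_change + 1L])
  px <- din$points[sign_change, 1] +
    tpar * (din$points[sign_change + 1L, 1] - din$points[sign_change, 1])
  py <- din$points[sign_change, 2] +
    tpar * (din$points[sign_change + 1L, 2] - din$points[sign_change, 2])
  dd <- (px - F_AD[1])^2 + (py - F_AD[2])^2
  P_in <- c(px[which.min(dd)], py[which.min(dd)])

  chord <- Z_out - T_
  uc <- chord / sqrt(sum(chord^2))
  # blade = first s_zout of arc from the tip on either edge; the exact cutoff
  # points are appended so the window edge is grid-independent
  sel <- which(din$s <= s_zout)
  svi <- {
    seg <- sqrt(rowSums((outline$inner_edge[-1, , drop = FALSE] -
                           outline$inner_edge[-nrow(outline$inner_edge), ,
                                              drop = FALSE])^2))
    c(0, cumsum(seg))
  }
  cut_in <- if (s_zout < svi[length(svi)]) {
    i <- max(1L, findInterval(s_zout, svi, rightmost.closed = TRUE))
    i <- min(i, nrow(outline$inner_edge) - 1L)
    wgt <- (s_zout - svi[i]) / max(svi[i + 1] - svi[i], .Machine$double.xmin)
    matrix(outline$inner_edge[i, ] +
             wgt * (outline$inner_edge[i + 1, ] - outline$inner_edge[i, ]), 1)
  } else matrix(numeric(0), 0, 2)
  d <- abs(.ref_perp(rbind(din$points[sel, , drop = FALSE], cut_in), T_, uc))
  ICL <- max(d)
  sel <- which(dout$s <= s_zout)
  d <- abs(.ref_perp(rbind(dout$points[sel, , drop = FALSE],
                           matrix(Z_out, 1)), T_, uc))
  OCL <- max(d)

  flag <- outline$inner_edge[outline$straight_range, , drop = FALSE]
  ctr <- colMeans(flag)
  sv <- svd(sweep(flag, 2, ctr))
  axis <- sv$v[, 1]
  if (sum(axis * (flag[1, ] - flag[nrow(flag), ])) < 0) axis <- -axis
  proj <- .ref_proj(rbind(outline$inner_edge, outline$outer_edge), ctr, axis)
  HL <- max(proj) - min(proj)

  c(HL = HL,
    AD = AD,
    PSW = sqrt(sum((B - H_heel)^2)),
    PL = sqrt(sum((F_AD - Z_out)^2)),
    DSW = sqrt(sum((P_in - Z_out)^2)),
    ICL = ICL,
    OCL = OCL,
    PCA = .ref_angle(F_AD - Z_out, T_ - Z_out),
    ISL = sqrt(sum((P_in - B)^2)),
    IAA = .ref_angle(B - P_in, T_ - P_in),
    OSL = sqrt(sum((Z_out - H_heel)^2)),
    OAA = .ref_angle(H_heel - Z_out, T_ - Z_out),
    DPL = sqrt(sum((T_ - Z_out)^2)))
}
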