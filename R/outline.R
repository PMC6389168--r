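#' Labeled, ordered digitized outline of one hook
#'
#' Container for one digitized central-hook outline. The hook is bounded by an
#' inner (concave) and an outer (convex) edge, both ordered polylines running
#' from the point tip to the articulation base. Both edges share the tip as
#' their first vertex. The articulation base B -- the centre of the base of
#' the articulation between hook and handle -- is a supplied landmark, not
#' necessarily a polyline vertex. A straight proximal section of the inner
#' shaft edge is flagged (`straight_range`, vertex indices into `inner_edge`)
#' and anchors the shaft axis used for hook length; if unflagged, the proximal
#' 40% of the inner edge by arc length is used. Coordinates are multiplied by
#' `units_scale` on construction so that stored coordinates are micrometres.
#' No image-axis flipping is performed; digitizations in image coordinates
#' (y down) should be reflected by the caller.
#'
#' @param inner_edge,outer_edge n x 2 matrices, ordered tip to base.
#' @param articulation_base Length-2 point B.
#' @param handle Optional 2 x 2 matrix: handle tip then handle base.
#' @param straight_range Optional integer vector of inner-edge vertex indices
#'   marking the straight shaft section.
#' @param units_scale Micrometres per coordinate unit (> 0).
#' @param id Specimen identifier.
#' @return A `hook_outline` object.
#' @export
hook_outline <- function(inner_edge, outer_edge, articulation_base,
                         handle = NULL, straight_range = NULL,
                         units_scale = 1, id = "specimen") {
  stopifnot(is.numeric(units_scale), length(units_scale) == 1, units_scale > 0)
  inner <- as_coord_matrix(inner_edge, "inner_edge") * units_scale
  outer <- as_coord_matrix(outer_edge, "outer_edge") * units_scale
  base <- as.numeric(articulation_base) * units_scale
  if (length(base) != 2 || any(!is.finite(base))) {
    stop("articulation_base must be a finite length-2 point", call. = FALSE)
  }
  if (nrow(inner) < 2 || nrow(outer) < 2) {
    stop("edges need at least 2 vertices", call. = FALSE)
  }
  span <- max(vnorm(inner[nrow(inner), ] - inner[1, ]), 1)
  if (vnorm(inner[1, ] - outer[1, ]) > 1e-6 * span) {
    stop("inner and outer edges must share the tip as their first vertex",
         call. = FALSE)
  }
  if (!is.null(handle)) {
    handle <- as_coord_matrix(handle, "handle") * units_scale
    if (nrow(handle) != 2) {
      stop("handle must be two points: tip then base", call. = FALSE)
    }
  }
  if (is.null(straight_range)) {
    # proximal (base-end) 40% of the inner edge by arc length
    s <- arc_lengths(inner)
    straight_range <- which(s >= 0.6 * s[length(s)])
    if (length(straight_range) < 2) {
      straight_range <- (nrow(inner) - 1L):nrow(inner)
    }
  }
  straight_range <- as.integer(straight_range)
  if (length(straight_range) < 2 ||
      any(straight_range < 1 | straight_range > nrow(inner))) {
    stop("straight_range must index at least 2 inner-edge vertices",
         call. = FALSE)
  }
  structure(list(inner_edge = inner, outer_edge = outer,
                 tip = inner[1, ], articulation_base = base,
                 handle = handle, straight_range = straight_range,
                 units_scale = units_scale, id = as.character(id)),
            class = "hook_outline")
}

#' @export
print.hook_outline <- function(x, ...) {
  cat(sprintf("<hook_outline '%s'>\n", x$id))
  cat(sprintf("  inner edge: %d vertices; outer edge: %d vertices\n",
              nrow(x$inner_edge), nrow(x$outer_edge)))
  cat(sprintf("  tip (%.2f, %.2f) um; articulation base (%.2f, %.2f) um\n",
              x$tip[1], x$tip[2],
              x$articulation_base[1], x$articulation_base[2]))
  cat(sprintf("  handle: %s\n", if (is.null(x$handle)) "absent" else "present"))
  invisible(x)
}

#' Apply a similarity transform to a hook outline
#'
#' Rotates, reflects, scales and translates every coordinate of the outline
#' (edges, tip, articulation base, handle). Reflection (about the x axis) is
#' applied first, then scaling, rotation and translation.
#'
#' @param outline A [hook_outline()].
#' @param rotation Rotation angle in degrees, counterclockwise.
#' @param translation Length-2 offset in micrometres.
#' @param scale Uniform scale factor (> 0).
#' @param reflect Logical; mirror about the x axis before rotating.
#' @return The transformed `hook_outline`.
#' @export
transform_outline <- function(outline, rotation = 0, translation = c(0, 0),
                              scale = 1, reflect = FALSE) {
  stopifnot(inherits(outline, "hook_outline"), scale > 0)
  R <- rotmat(rotation)
  f <- function(p) {
    m <- matrix(p, ncol = 2)
    if (reflect) m[, 2] <- -m[, 2]
    m <- (scale * m) %*% t(R)
    m[, 1] <- m[, 1] + translation[1]
    m[, 2] <- m[, 2] + translation[2]
    if (length(p) == 2) as.numeric(m) else m
  }
  out <- outline
  out$inner_edge <- f(outline$inner_edge)
  out$outer_edge <- f(outline$outer_edge)
  out$tip <- f(outline$tip)
  out$articulation_base <- f(outline$articulation_base)
  if (!is.null(outline$handle)) out$handle <- f(outline$handle)
  out
}

# cumulative arc length along a polyline, starting at 0
arc_lengths <- function(P) {
  d <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
  c(0, cumsum(d))
}

# resample a polyline at (approximately) uniform arc-length spacing; the
# original vertices are kept in the sample (a polyline's extrema live at its
# vertices). Give either a step (spacing <= step) or a target count n.
# Returns list(points, s) with s the arc length of each sample, ordered.
resample_polyline <- function(P, step = NULL, n = NULL) {
  s <- arc_lengths(P)
  L <- s[length(s)]
  if (L == 0) return(list(points = P[1, , drop = FALSE], s = 0))
  if (is.null(n)) {
    stopifnot(!is.null(step), step > 0)
    n <- max(2L, ceiling(L / step) + 1L)
  }
  si <- sort(unique(c(seq(0, L, length.out = n), s)))
  list(points = cbind(stats::approx(s, P[, 1], xout = si, ties = "ordered")$y,
                      stats::approx(s, P[, 2], xout = si, ties = "ordered")$y),
       s = si)
}

# closed-ring simplicity check: TRUE if no two non-adjacent segments of the
# ring intersect. The ring is decimated to at most max_points vertices first;
# the check is a coarse guard against grossly self-intersecting shapes.
ring_is_simple <- function(ring, max_points = 250) {
  ring <- as_coord_matrix(ring, "ring")
  if (nrow(ring) > max_points) {
    keep <- unique(round(seq(1, nrow(ring), length.out = max_points)))
    ring <- ring[keep, , drop = FALSE]
  }
  m <- nrow(ring)
  a <- ring
  b <- ring[c(2:m, 1), , drop = FALSE]
  idx <- utils::combn(m, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adjacent <- (j - i == 1) | (i == 1 & j == m)
  i <- i[!adjacent]; j <- j[!adjacent]
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
  !any(hit)
}

# outline as one closed ring: inner edge tip->base, base gap, outer edge
# base->tip (the shared tip closes the ring)
outline_ring <- function(outline) {
  rbind(outline$inner_edge,
        outline$outer_edge[rev(seq_len(nrow(outline$outer_edge))[-1]), ,
                           drop = FALSE])
}
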