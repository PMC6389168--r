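# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps^0.5) {
    stop("cannot normalize a (near-)zero vector", call. = FALSE)
  }
  v / n
}

# 2x2 rotation matrix, angle in degrees
rotmat <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# signed perpendicular component of points relative to line (a, direction u);
# pts is an n x 2 matrix, a length-2, u unit length-2
perp_component <- function(pts, a, u) {
  dx <- pts[, 1] - a[1]
  dy <- pts[, 2] - a[2]
  u[1] * dy - u[2] * dx
}

# projection parameter of points onto line (a, u), in coordinate units
proj_component <- function(pts, a, u) {
  (pts[, 1] - a[1]) * u[1] + (pts[, 2] - a[2]) * u[2]
}

# interior angle (degrees) between two direction vectors, in (0, 180]
angle_between <- function(v1, v2) {
  n1 <- vnorm(v1)
  n2 <- vnorm(v2)
  if (n1 < .Machine$double.eps^0.5 || n2 < .Machine$double.eps^0.5) {
    stop("degenerate angle: coincident points give a zero-length ray",
         call. = FALSE)
  }
  ct <- sum(v1 * v2) / (n1 * n2)
  rad2deg(acos(min(1, max(-1, ct))))
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits;
# used to fingerprint run configurations in output headers
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

as_coord_matrix <- function(x, what = "coordinates") {
  m <- as.matrix(x)
  if (!is.numeric(m) || ncol(m) != 2) {
    stop(sprintf("%s must be an n x 2 numeric matrix", what), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop(sprintf("%s contain non-finite values", what), call. = FALSE)
  }
  unname(m)
}
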