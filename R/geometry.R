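# Small 3D vector / transform helpers shared by the cylinder and nucleotide
# models.  Vectors are plain numeric length-3; point sets are n x 3 matrices.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @noRd
# Deterministic orthonormal frame with `y` as the given axis: picks the
# reference vector least aligned with the axis so the frame never degenerates.
frame_from_axis <- function(axis) {
  y <- vunit(axis)
  ref <- if (abs(y[1L]) <= abs(y[2L]) && abs(y[1L]) <= abs(y[3L])) {
    c(1, 0, 0)
  } else if (abs(y[2L]) <= abs(y[3L])) {
    c(0, 1, 0)
  } else {
    c(0, 0, 1)
  }
  x <- vunit(vcross(ref, y))
  z <- vcross(x, y)
  cbind(x = x, y = y, z = z)
}

# 4x4 homogeneous transform from a 3x3 rotation (columns = local axes in world
# coordinates) and an origin.
make_transform <- function(rotation, origin) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4L] <- origin
  m
}

# Apply a 4x4 transform to an n x 3 matrix of points (w = 1) or directions
# (w = 0).
apply_transform <- function(transform, pts, w = 1) {
  pts <- matrix(pts, ncol = 3L)
  out <- pts %*% t(transform[1:3, 1:3])
  if (w != 0) out <- sweep(out, 2L, transform[1:3, 4L], `+`)
  out
}

# Spherical linear interpolation between two vectors about the origin.
# Interpolates direction along the great circle and magnitude linearly.
# Near-parallel or near-antiparallel inputs fall back to linear interpolation
# (the antiparallel arc is undefined).
slerp_vec <- function(a, b, t) {
  na <- vnorm(a)
  nb <- vnorm(b)
  if (na < 1e-9 || nb < 1e-9) return(a + t * (b - a))
  ua <- a / na
  ub <- b / nb
  d <- max(-1, min(1, sum(ua * ub)))
  omega <- acos(d)
  if (omega < 1e-6 || omega > pi - 1e-6) return(a + t * (b - a))
  dir <- (sin((1 - t) * omega) * ua + sin(t * omega) * ub) / sin(omega)
  ((1 - t) * na + t * nb) * dir
}
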