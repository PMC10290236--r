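# Internal geometry and RNG helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Signed dihedral angle (radians) defined by four points, IUPAC convention.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -atan2(y, x)  # sign matches the standard convention (IUPAC, bio3d)
}

# All pairwise Euclidean distances between the rows of two coordinate matrices.
cross_dist <- function(xa, xb) {
  xa <- matrix(xa, ncol = 3L)
  xb <- matrix(xb, ncol = 3L)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Uniform random rotation matrix (3x3) from a quaternion draw; uses the
# current RNG stream, callers wrap in with_seed() for determinism.
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / vec_norm(q)
  quat_to_rotmat(q)
}

quat_to_rotmat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# Quaternion (w, x, y, z) of a rotation matrix, scalar part canonicalized >= 0.
rotmat_to_quat <- function(R) {
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3L, 2L] - R[2L, 3L]) / s,
           (R[1L, 3L] - R[3L, 1L]) / s,
           (R[2L, 1L] - R[1L, 2L]) / s)
  } else if (R[1L, 1L] > R[2L, 2L] && R[1L, 1L] > R[3L, 3L]) {
    s <- sqrt(1 + R[1L, 1L] - R[2L, 2L] - R[3L, 3L]) * 2
    q <- c((R[3L, 2L] - R[2L, 3L]) / s, 0.25 * s,
           (R[1L, 2L] + R[2L, 1L]) / s,
           (R[1L, 3L] + R[3L, 1L]) / s)
  } else if (R[2L, 2L] > R[3L, 3L]) {
    s <- sqrt(1 + R[2L, 2L] - R[1L, 1L] - R[3L, 3L]) * 2
    q <- c((R[1L, 3L] - R[3L, 1L]) / s,
           (R[1L, 2L] + R[2L, 1L]) / s, 0.25 * s,
           (R[2L, 3L] + R[3L, 2L]) / s)
  } else {
    s <- sqrt(1 + R[3L, 3L] - R[1L, 1L] - R[2L, 2L]) * 2
    q <- c((R[2L, 1L] - R[1L, 2L]) / s,
           (R[1L, 3L] + R[3L, 1L]) / s,
           (R[2L, 3L] + R[3L, 2L]) / s, 0.25 * s)
  }
  q <- q / vec_norm(q)
  # canonical sign: scalar part >= 0. Near 180-degree rotations the scalar
  # part sits at numerical zero and its sign is noise, so there the flip is
  # decided by the largest-magnitude vector component instead (stable under
  # perturbations of the input rotation).
  if (abs(q[1L]) > 1e-6) {
    if (q[1L] < 0) q <- -q
  } else {
    lead <- which.max(abs(q[2:4])) + 1L
    if (q[lead] < 0) q <- -q
  }
  q
}
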