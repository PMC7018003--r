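# Small geometric helpers shared across the package. All vectors are plain
# numeric length-3; all angles are radians unless a *_deg suffix says
# otherwise.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

clamp_cos <- function(x) pmin(1, pmax(-1, x))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation formula. The returned matrix rotates column vectors
#' counterclockwise by `angle` radians about `axis` (right-hand rule).
#'
#' @param axis numeric length-3, need not be normalized.
#' @param angle rotation angle in radians.
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @keywords internal
#' @noRd
rotation_about_axis <- function(axis, angle) {
  a <- unit(axis)
  co <- cos(angle)
  si <- sin(angle)
  K <- matrix(c(0, a[3L], -a[2L],
                -a[3L], 0, a[1L],
                a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) * co + si * K + (1 - co) * tcrossprod(a)
}

# Signed dihedral of the four points p1-p2-p3-p4 in (-pi, pi], computed with
# the atan2 construction (numerically stable near 0 and pi). Sign follows the
# standard convention used by the common structural-biology toolkits.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  phi <- -atan2(sum(m1 * n2), sum(n1 * n2))
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
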