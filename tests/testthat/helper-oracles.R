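# Independent oracles used to cross-check the package's computational paths.
# Each one is deliberately implemented with a different construction than the
# code it checks.

# Signed dihedral via plane normals + sign of the triple product (the package
# uses the atan2 construction instead).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(min(1, max(-1, cosv)))
  s <- sum(cr(n1, n2) * b2)
  if (s < 0) -ang else ang
}

# Planar angle as arccos of the normalized dot product.
oracle_angle <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

# Brute-force cumulative-bin score: explicit double loop, no vectorization.
oracle_bin_score <- function(values, bounds, n) {
  k <- length(bounds)
  total <- 0
  for (i in seq_len(k)) {
    cnt <- 0
    for (v in values) if (v <= bounds[i]) cnt <- cnt + 1
    total <- total + (k - i + 1) * (cnt / n)
  }
  2 * total / (k * (k + 1))
}

# Brute-force GDT-HA style mean over thresholds from a single distance set.
oracle_gdtha <- function(dists, n, thresholds = c(0.5, 1, 2, 4)) {
  mean(vapply(thresholds, function(t) sum(dists <= t) / n, 0))
}

# Dense hierarchical rotation-grid search for the optimal-superposition RMSD.
# ZYZ Euler angles, coarse scan then two zoom passes; independent of SVD.
oracle_kabsch_grid_rmsd <- function(a, b) {
  a <- sweep(as.matrix(a), 2, colMeans(a))
  b <- sweep(as.matrix(b), 2, colMeans(b))
  euler_zyz <- function(al, be, ga) {
    cz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    cy <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
    cz(al) %*% cy(be) %*% cz(ga)
  }
  rmsd_of <- function(al, be, ga) {
    R <- euler_zyz(al, be, ga)
    sqrt(mean(rowSums((a %*% t(R) - b)^2)))
  }
  best <- c(0, 0, 0); best_val <- rmsd_of(0, 0, 0)
  scan <- function(center, half_width, step) {
    for (al in seq(center[1] - half_width, center[1] + half_width, by = step))
      for (be in seq(center[2] - half_width, center[2] + half_width, by = step))
        for (ga in seq(center[3] - half_width, center[3] + half_width, by = step)) {
          v <- rmsd_of(al, be, ga)
          if (v < best_val) { best_val <<- v; best <<- c(al, be, ga) }
        }
  }
  scan(c(pi, pi / 2, pi), pi, 12 * pi / 180)  # full sphere, 12 deg
  scan(best, 12 * pi / 180, 1.5 * pi / 180)
  scan(best, 1.5 * pi / 180, 0.15 * pi / 180)
  scan(best, 0.15 * pi / 180, 0.02 * pi / 180)
  best_val
}

# Uniform-ish random proper rotation from the QR decomposition.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_rigid_transform <- function(max_shift = 20) {
  rigid_transform(random_rotation(), stats::runif(3, -max_shift, max_shift))
}

# Apply a rigid motion to every atom of a structure.
transform_structure <- function(s, tr) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  s$atoms[, c("x", "y", "z")] <- apply_transform(tr, xyz)
  s
}

# Convenience: a united residue straight from coordinates.
ur <- function(ca, sc = NULL) {
  if (is.null(sc)) {
    structure(list(ca = ca, sc = ca, has_distinct_sc = FALSE, res_name = "GLY"),
              class = "ur_residue")
  } else {
    structure(list(ca = ca, sc = sc, has_distinct_sc = TRUE, res_name = "XXX"),
              class = "ur_residue")
  }
}

identity_transform <- function() rigid_transform()

# straight alpha-carbon trace with the canonical 3.8 A spacing
.ca_trace_for_test <- function(n) cbind(3.8 * seq_len(n), 0, 0)
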