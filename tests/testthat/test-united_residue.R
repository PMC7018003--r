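# United-residue conversion and the five-parameter pair geometry.

res_from_atoms <- function(resname, names, coords) {
  xyz <- do.call(rbind, coords)
  structure(list(chain_id = "A", seq_num = 1L, icode = "", res_name = resname,
                 atoms = data.frame(chain = "A", resno = 1L, icode = "",
                                    resname = resname, atom = names,
                                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                    occ = 1, element = substr(names, 1, 1),
                                    stringsAsFactors = FALSE)),
            class = "pdb_residue")
}

test_that("to_united_residue computes the side-chain heavy-atom centroid", {
  r <- res_from_atoms("ALA", c("N", "CA", "CB"),
                      list(c(0, 1, 0), c(0, 0, 0), c(1, 1, 1)))
  u <- to_united_residue(r)
  expect_equal(u$sc, c(1, 1, 1))
  expect_true(u$has_distinct_sc)

  r2 <- res_from_atoms("SER", c("CA", "CB", "OG"),
                       list(c(5, 5, 5), c(0, 0, 0), c(2, 0, 0)))
  expect_equal(to_united_residue(r2)$sc, c(1, 0, 0))

  gly <- res_from_atoms("GLY", c("N", "CA", "C", "O"),
                        list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  ug <- to_united_residue(gly)
  expect_false(ug$has_distinct_sc)
  expect_equal(ug$sc, ug$ca)

  noca <- res_from_atoms("ALA", c("N", "CB"), list(c(0, 1, 0), c(1, 1, 1)))
  expect_error(to_united_residue(noca), "no CA atom")
})

test_that("to_united_residue is permutation-invariant in atom order", {
  set.seed(42)
  nms <- c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2")
  coords <- lapply(seq_along(nms), function(i) rnorm(3))
  r1 <- res_from_atoms("ASP", nms, coords)
  perm <- sample(seq_along(nms))
  r2 <- res_from_atoms("ASP", nms[perm], coords[perm])
  u1 <- to_united_residue(r1); u2 <- to_united_residue(r2)
  expect_equal(u1$sc, u2$sc)
  expect_equal(u1$ca, u2$ca)
})

test_that("pair_geometry reproduces the right-angle worked example", {
  g <- pair_geometry(ur(c(0, 0, 0), c(1, 0, 0)), ur(c(0, 0, 0), c(0, 1, 0)),
                     identity_transform())
  expect_equal(g$r, sqrt(2))
  expect_equal(g$theta1, 3 * pi / 4)
  expect_equal(g$theta2, pi / 4)
  expect_equal(g$phi, 0)
  expect_true(g$angles_defined)

  # cross-check the two planar angles against the generic angle oracle
  rvec <- c(0, 1, 0) - c(1, 0, 0)
  expect_equal(g$theta1, oracle_angle(c(1, 0, 0), rvec))
  expect_equal(g$theta2, oracle_angle(c(0, 1, 0), rvec))
})

test_that("pair_geometry degeneracy rules", {
  # identical residues: distances 0, angles undefined and zeroed
  g <- pair_geometry(ur(c(1, 2, 3), c(2, 2, 3)), ur(c(1, 2, 3), c(2, 2, 3)),
                     identity_transform())
  expect_equal(g$d, 0)
  expect_equal(g$r, 0)
  expect_false(g$angles_defined)
  expect_equal(c(g$theta1, g$theta2, g$phi), c(0, 0, 0))

  # glycine on either side disables the angles
  g2 <- pair_geometry(ur(c(0, 0, 0)), ur(c(0, 0, 0), c(1, 0, 0)),
                      identity_transform())
  expect_false(g2$angles_defined)

  # 3-4-5 triangle for the CA distance
  g3 <- pair_geometry(ur(c(0, 0, 0), c(1, 0, 0)), ur(c(3, 4, 0), c(4, 4, 0)),
                      identity_transform())
  expect_equal(g3$d, 5)

  # collinear bonds: torsion degenerates to the inter-bond angle
  g4 <- pair_geometry(ur(c(0, 0, 0), c(1, 0, 0)), ur(c(3, 0, 0), c(4, 0, 0)),
                      identity_transform())
  expect_equal(g4$phi, 0)
  g5 <- pair_geometry(ur(c(0, 0, 0), c(1, 0, 0)), ur(c(5, 0, 0), c(4, 0, 0)),
                      identity_transform())
  expect_equal(g5$phi, pi)
})

test_that("planar angles match the angle oracle to 1e-9 on random inputs", {
  set.seed(101)
  for (i in 1:200) {
    m <- ur(rnorm(3), rnorm(3, sd = 2))
    n <- ur(rnorm(3), rnorm(3, sd = 2))
    g <- pair_geometry(m, n, identity_transform())
    if (!g$angles_defined) next
    rvec <- n$sc - m$sc
    expect_equal(g$theta1, oracle_angle(m$sc - m$ca, rvec), tolerance = 1e-9)
    expect_equal(g$theta2, oracle_angle(n$sc - n$ca, rvec), tolerance = 1e-9)
  }
})

test_that("the closed-form torsion cosine matches the dihedral magnitude", {
  # cos(phi) = (u1.u2 - cos t1 cos t2) / (sin t1 sin t2) should equal the
  # cosine of min(phi, 2*pi - phi) whenever the angles are defined
  set.seed(77)
  checked <- 0
  for (i in 1:300) {
    m <- ur(rnorm(3), rnorm(3, sd = 2))
    n <- ur(rnorm(3), rnorm(3, sd = 2))
    g <- pair_geometry(m, n, identity_transform())
    if (!g$angles_defined || sin(g$theta1) * sin(g$theta2) < 1e-3) next
    u1 <- (m$sc - m$ca) / sqrt(sum((m$sc - m$ca)^2))
    u2 <- (n$sc - n$ca) / sqrt(sum((n$sc - n$ca)^2))
    closed <- acos(min(1, max(-1, (sum(u1 * u2) - cos(g$theta1) * cos(g$theta2)) /
                                (sin(g$theta1) * sin(g$theta2)))))
    expect_equal(closed, min(g$phi, 2 * pi - g$phi), tolerance = 1e-7)
    checked <- checked + 1
  }
  expect_gt(checked, 200)
})

test_that("pair geometry is invariant under a common rigid motion", {
  set.seed(55)
  for (i in 1:20) {
    m <- ur(rnorm(3), rnorm(3, sd = 2))
    n <- ur(rnorm(3), rnorm(3, sd = 2))
    g0 <- pair_geometry(m, n, identity_transform())
    tr <- random_rigid_transform()
    mv <- function(u) {
      u$ca <- drop(apply_transform(tr, matrix(u$ca, 1)))
      u$sc <- drop(apply_transform(tr, matrix(u$sc, 1)))
      u
    }
    g1 <- pair_geometry(mv(m), mv(n), identity_transform())
    expect_equal(g1$d, g0$d, tolerance = 1e-9)
    expect_equal(g1$r, g0$r, tolerance = 1e-9)
    if (g0$angles_defined) {
      expect_equal(g1$theta1, g0$theta1, tolerance = 1e-9)
      expect_equal(g1$theta2, g0$theta2, tolerance = 1e-9)
      expect_equal(g1$phi, g0$phi, tolerance = 1e-9)
    }
  }
})

test_that("pair_geometry rejects a non-orthonormal transform", {
  bad <- structure(list(rotation = diag(3) * 1.1, translation = c(0, 0, 0)),
                   class = "rigid_transform")
  expect_error(pair_geometry(ur(c(0, 0, 0), c(1, 0, 0)),
                             ur(c(0, 0, 0), c(0, 1, 0)), bad),
               "orthonormal")
})
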