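# Component scores, the weighted total, and the end-to-end evaluation.

test_that("score_dca matches brute-force threshold counting", {
  d <- c(0.4, 1.5, 3.0, 9.0)
  counts <- vapply(c(0.5, 1, 2, 4), function(t) sum(d <= t), 0L)
  res <- score_dca(counts, n_native = 4)
  expect_equal(res$profile, c(0.25, 0.25, 0.5, 0.75))
  expect_equal(res$score, 0.4375)
  expect_equal(res$score, oracle_gdtha(d, 4))

  expect_equal(score_dca(c(4L, 4L, 4L, 4L), 4)$score, 1)
  expect_equal(score_dca(c(0L, 0L, 0L, 0L), 4)$score, 0)
  expect_error(score_dca(c(1L, 1L, 1L, 1L), 0), "n_native")
})

test_that("score_rsc matches the worked example and edge cases", {
  res <- score_rsc(c(0.3, 1.2, 4.8, 6.0), n_sc = 4)
  expect_equal(res$score, 23 / 55)
  expect_equal(res$score, oracle_bin_score(c(0.3, 1.2, 4.8, 6.0), 0.5 * (1:10), 4))

  expect_equal(score_rsc(rep(0.2, 7), 7)$score, 1)
  expect_equal(score_rsc(rep(5.5, 7), 7)$score, 0)
  expect_true(is.na(score_rsc(numeric(0), 0)$score))
})

test_that("score_planar matches the worked example", {
  th <- c(20, 95) * pi / 180
  res <- score_planar(th, n_sc = 2)
  expect_equal(res$profile, c(0.5, 0.5, 0.5, 1.0))
  expect_equal(res$score, 0.55)
  expect_equal(score_planar(rep(0.1, 3), 3)$score, 1)
  expect_equal(score_planar(rep(2.5, 3), 3)$score, 0)
})

test_that("score_dihedral matches the worked example and the bin-7 option", {
  ph <- c(10, 190, 310) * pi / 180
  expect_equal(score_dihedral(ph, n_sc = 3)$score, (65 / 3) / 55)
  expect_equal(score_dihedral(rep(0.2, 5), 5)$score, 1)
  expect_equal(score_dihedral(rep(5.5, 5), 5)$score, 0)

  # the printed 201-degree bound is exposed as a configuration choice:
  # an angle of 205 degrees sits inside bin 7 at 210 but outside at 201
  cfg201 <- specs_config(dihedral_bin7 = 201)
  a205 <- 205 * pi / 180
  expect_gt(score_dihedral(a205, 1)$score, score_dihedral(a205, 1, cfg201)$score)
})

test_that("component scorers agree with the brute-force oracle on random inputs", {
  set.seed(12)
  cfg <- specs_config()
  for (i in 1:300) {
    n <- sample(1:40, 1)
    r <- runif(n, 0, 7)
    th <- runif(n, 0, pi)
    ph <- runif(n, 0, 2 * pi)
    expect_equal(score_rsc(r, n, cfg)$score, oracle_bin_score(r, cfg$sc_bins, n),
                 tolerance = 1e-12)
    expect_equal(score_planar(th, n, cfg)$score,
                 oracle_bin_score(th, cfg$planar_bins, n), tolerance = 1e-12)
    expect_equal(score_dihedral(ph, n, cfg)$score,
                 oracle_bin_score(ph, cfg$dihedral_bins, n), tolerance = 1e-12)
  }
})

test_that("cumulative bin profiles are non-decreasing and scores monotone", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    r <- runif(n, 0, 6)
    res <- score_rsc(r, n)
    expect_true(all(diff(res$profile) >= 0))
    # element-wise upscaling never increases the distance score
    expect_lte(score_rsc(r * runif(1, 1, 3), n)$score, res$score)
  }
  # a uniform positive offset to CA distances never increases dca
  for (i in 1:20) {
    d <- runif(10, 0, 5)
    t4 <- c(0.5, 1, 2, 4)
    c1 <- vapply(t4, function(t) sum(d <= t), 0L)
    c2 <- vapply(t4, function(t) sum(d + runif(1, 0, 2) <= t), 0L)
    expect_lte(score_dca(c2, 10)$score, score_dca(c1, 10)$score)
  }
})

test_that("specs_total applies the 4:1:1:1:1 weighting exactly", {
  expect_equal(specs_total(1, 1, 1, 1, 1), 1)
  expect_equal(specs_total(0, 0, 0, 0, 0), 0)
  comp <- c(0.4375, 23 / 55, 0.55, 0.55, (65 / 3) / 55)
  expect_equal(specs_total(comp[1], comp[2], comp[3], comp[4], comp[5]),
               (4 * comp[1] + comp[2] + comp[3] + comp[4] + comp[5]) / 8)
  expect_error(specs_total(1.2, 0, 0, 0, 0), "\\[0, 1\\]")
  expect_error(specs_total(0.5, -0.1, 0.5, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("self-comparison scores exactly one", {
  nat <- make_native(fixture_spec(n_residues = 18, glycine_fraction = 0.15, seed = 8))
  res <- specs_score(nat, nat)
  expect_identical(res$total, 1)
  expect_identical(unlist(res$components, use.names = FALSE), rep(1, 5))
})

test_that("a whole-body rigid motion of the model leaves all components at one", {
  nat <- make_native(fixture_spec(n_residues = 14, seed = 17))
  set.seed(17)
  moved <- transform_structure(nat, random_rigid_transform())
  res <- specs_score(moved, nat)
  expect_equal(res$total, 1, tolerance = 1e-9)
})

test_that("dCA under a single transform equals the high-accuracy GDT formula", {
  nat <- make_native(fixture_spec(n_residues = 20, seed = 23))
  dec <- make_decoy(nat, fixture_spec(n_residues = 20, ca_noise_sigma = 1.5, seed = 23))
  res <- specs_score(dec, nat)
  d <- res$reference$ca_distances
  counts <- res$reference$counts_under
  expect_equal(score_dca(counts, res$n_native)$score, oracle_gdtha(d, res$n_native))
})

test_that("perfect-CA models with rotated side chains are distinguished", {
  nat <- make_native(fixture_spec(n_residues = 20, seed = 31))
  dec <- make_decoy(nat, fixture_spec(n_residues = 20, sc_rotation_deg = 160, seed = 31))
  res <- specs_score(dec, nat)
  expect_equal(res$components$dca, 1)
  expect_lt(res$total, 1)
})

test_that("incomplete model side chains are penalized, not excluded", {
  nat <- make_native(fixture_spec(n_residues = 10, glycine_fraction = 0, seed = 41))
  stripped <- nat
  # remove all side-chain atoms of residue 4 in the model
  drop <- stripped$atoms$resno == 4 &
    !(stripped$atoms$atom %in% c("N", "CA", "C", "O", "OXT"))
  stripped$atoms <- stripped$atoms[!drop, ]
  res <- specs_score(stripped, nat)
  expect_equal(res$n_native_sc, 10)
  expect_equal(res$components$dca, 1)
  # residue 4 contributes to no side-chain bin: each profile tops out at 9/10
  expect_equal(max(res$profiles$rsc), 0.9)
  expect_lt(res$total, 1)
})

test_that("polyglycine natives fall back to the CA component", {
  nat <- make_native(fixture_spec(n_residues = 8, glycine_fraction = 0, seed = 51))
  nat$atoms <- nat$atoms[nat$atoms$atom %in% c("N", "CA", "C", "O"), ]
  nat$atoms$resname <- "GLY"
  res <- specs_score(nat, nat)
  expect_false(res$sc_defined)
  expect_true(is.na(res$components$rsc))
  expect_identical(res$total, res$components$dca)
  expect_identical(res$total, 1)
})

test_that("evaluation requires at least three shared residues", {
  nat <- make_native(fixture_spec(n_residues = 10, seed = 61))
  tiny <- nat
  tiny$atoms <- tiny$atoms[tiny$atoms$resno <= 2, ]
  expect_error(specs_score(tiny, nat), "at least 3")
})
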