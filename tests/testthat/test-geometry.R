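test_that("rmsd matches identity, translation, and a brute-force oracle", {
  set.seed(11)
  a <- matrix(rnorm(18 * 3), 18, 3)
  expect_identical(rmsd(a, a), 0)
  b <- sweep(a, 2, c(3, 0, 0), "+")
  expect_equal(rmsd(a, b), 3.0, tolerance = 1e-12)
  # independent per-atom summation oracle
  b2 <- a + matrix(rnorm(18 * 3), 18, 3)
  acc <- 0
  for (i in 1:18) {
    acc <- acc + (a[i, 1] - b2[i, 1])^2 + (a[i, 2] - b2[i, 2])^2 +
      (a[i, 3] - b2[i, 3])^2
  }
  expect_equal(rmsd(a, b2), sqrt(acc / 18), tolerance = 1e-10)
  expect_error(rmsd(a[0, , drop = FALSE], b[0, , drop = FALSE]), "empty")
  expect_error(rmsd(a, b[1:5, ]), "mismatch")
})

test_that("rmsd_matrix equals elementwise rmsd and respects pose order", {
  tmpl <- build_ideal_helix("LYELLH", start_resno = 16)
  set.seed(3)
  coords <- replicate(5, {
    X <- as.matrix(tmpl[, c("x", "y", "z")])
    sweep(X, 2, rnorm(3, sd = 2), "+")
  }, simplify = FALSE)
  ens <- mk_ensemble(tmpl, coords)
  D <- rmsd_matrix(ens)
  ca <- which(tmpl$name == "CA")
  for (i in 1:5) for (j in 1:5) {
    expect_equal(D[i, j], rmsd(coords[[i]][ca, ], coords[[j]][ca, ]),
                 tolerance = 1e-10)
  }
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
  expect_true(all(diag(D) == 0))
  # identical poses give the zero matrix
  ens0 <- mk_ensemble(tmpl, coords[c(1, 1, 1)])
  expect_true(all(rmsd_matrix(ens0) < 1e-12))
  # permuting pose order permutes rows/cols consistently
  perm <- c(3, 1, 5, 2, 4)
  ensp <- mk_ensemble(tmpl, coords[perm],
                      ids = sprintf("p%02d", seq_len(5)))
  Dp <- rmsd_matrix(ensp)
  expect_equal(unclass(Dp), unclass(D)[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("pairwise RMSD is invariant under a joint rigid motion", {
  tmpl <- build_ideal_helix("LYELLH", start_resno = 16)
  set.seed(5)
  coords <- replicate(4, as.matrix(tmpl[, c("x", "y", "z")]) +
                        matrix(rnorm(nrow(tmpl) * 3), ncol = 3),
                      simplify = FALSE)
  ens <- mk_ensemble(tmpl, coords)
  R <- rot_about(c(1, 2, 3), 77)
  moved <- move_ensemble(ens, R, c(5, -4, 2))
  expect_equal(unclass(rmsd_matrix(moved)), unclass(rmsd_matrix(ens)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the membrane frame reproduces a constructed plane", {
  fix <- analytic_receptor()
  fr <- build_membrane_frame(fix$structure, fix$bw_map)
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$origin, c(1 / 3, 1 / 3, 0), tolerance = 1e-12)
  # reference residue along +x from the origin fixes the azimuth zero
  expect_equal(fr$x_axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-12)
})

test_that("degenerate zero-planes and references are rejected", {
  fix <- analytic_receptor()
  collinear <- fix$structure
  collinear$y[3] <- 0; collinear$x[3] <- 2  # third point on the x-axis
  expect_error(build_membrane_frame(collinear, fix$bw_map), "collinear")
  overhead <- fix$structure
  overhead$x[5] <- 1 / 3; overhead$y[5] <- 1 / 3; overhead$z[5] <- 30
  expect_error(build_membrane_frame(overhead, fix$bw_map), "azimuth")
})

test_that("depth is the signed z of the anchor and is rigid-motion invariant", {
  fix <- analytic_receptor()
  fr <- build_membrane_frame(fix$structure, fix$bw_map)
  tmpl <- mk_atoms(rbind(c(0, 0, 0), c(0, 0, 1)), resno = c(33, 32))
  at_origin <- matrix(c(1 / 3, 1 / 3, 0, 0, 0, 1), 2, 3, byrow = TRUE)
  above <- at_origin; above[1, ] <- fr$origin + 5 * fr$z_axis
  ens <- mk_ensemble(tmpl, list(at_origin, above),
                     receptor = fix$structure, peptide_range = c(32, 33))
  d <- binding_depth(ens, fr, anchor_resno = 33)
  expect_equal(d$depth, c(0, 5), tolerance = 1e-9)

  # the same rigid motion on receptor and poses leaves depth unchanged
  R <- rot_about(c(2, -1, 1), 33)
  moved <- move_ensemble(ens, R, c(-3, 7, 1))
  fr2 <- build_membrane_frame(moved$receptor, fix$bw_map)
  expect_equal(binding_depth(moved, fr2, anchor_resno = 33)$depth,
               d$depth, tolerance = 1e-9)
  expect_error(binding_depth(ens, fr, anchor_resno = 99), "not found")
})

test_that("azimuth measures the in-plane tail-to-head angle", {
  fix <- analytic_receptor()
  fr <- build_membrane_frame(fix$structure, fix$bw_map)
  tmpl <- mk_atoms(rbind(c(0, 0, 0), c(0, 0, 0)), resno = c(26, 28))
  # head - tail along +x -> 0 degrees
  along_x <- rbind(c(2, 0, 0), c(0, 0, 0))
  # head - tail along +y -> 90 degrees (counterclockwise from extracellular)
  along_y <- rbind(c(0, 2, 0), c(0, 0, 0))
  ens <- mk_ensemble(tmpl, list(along_x, along_y),
                     receptor = fix$structure, peptide_range = c(26, 28))
  az <- azimuth(ens, fr)
  expect_equal(az$azimuth, c(0, 90), tolerance = 1e-9)
  expect_equal(az$inplane, c(2, 2), tolerance = 1e-12)

  # vector along z has no in-plane component: undefined azimuth
  vertical <- rbind(c(0, 0, 5), c(0, 0, 0))
  ens_v <- mk_ensemble(tmpl, list(vertical), receptor = fix$structure,
                       peptide_range = c(26, 28))
  expect_error(azimuth(ens_v, fr), "undefined azimuth")
  expect_true(is.na(azimuth(ens_v, fr, on_degenerate = "na")$azimuth))
})

test_that("rotating a pose about the membrane normal shifts azimuth equally", {
  fix <- toy_fixture()
  sim <- generate_ensemble(generator_config(seed = 2, n_poses = 5,
                                            decoy_fraction = 0),
                           receptor = fix$receptor)
  az0 <- azimuth(sim$ensemble, sim$frame)
  rotated <- sim$ensemble
  Rz <- rot_about(sim$frame$z_axis, 30)
  for (i in seq_len(n_poses(rotated))) {
    X <- matrix(rotated$xyz[i, ], ncol = 3, byrow = TRUE) %*% t(Rz)
    rotated$xyz[i, ] <- as.vector(t(X))
  }
  az1 <- azimuth(rotated, sim$frame)
  shift <- poseatlas:::ang_diff(az1$azimuth, az0$azimuth)
  expect_equal(shift, rep(30, 5), tolerance = 1e-6)
})

test_that("depth and azimuth are invariant under joint rigid motion", {
  fix <- toy_fixture()
  sim <- generate_ensemble(generator_config(seed = 9, n_poses = 10,
                                            decoy_fraction = 0),
                           receptor = fix$receptor)
  d0 <- binding_depth(sim$ensemble, sim$frame)
  a0 <- azimuth(sim$ensemble, sim$frame)
  R <- rot_about(c(1, 1, 1), 121)
  moved <- move_ensemble(sim$ensemble, R, c(11, -2, 4))
  fr2 <- build_membrane_frame(moved$receptor, fix$receptor$bw_map)
  expect_equal(binding_depth(moved, fr2)$depth, d0$depth, tolerance = 1e-9)
  expect_equal(azimuth(moved, fr2)$azimuth, a0$azimuth, tolerance = 1e-6)
})
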