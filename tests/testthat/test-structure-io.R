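test_that("hand-written PDB records parse to the printed fields", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   LEU P  16       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  LEU P  16       1.500  -2.250   0.000  1.00  0.00           C",
    "ATOM      3  CA  TYR P  17      -4.125   0.001  99.000  1.00  0.00           C"
  ), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 3)
  expect_equal(s$x, c(1.0, 1.5, -4.125))
  expect_equal(s$y, c(2.0, -2.25, 0.001))
  expect_equal(s$z, c(3.0, 0.0, 99.0))
  expect_equal(s$name, c("N", "CA", "CA"))
  expect_equal(s$resno, c(16L, 16L, 17L))
  expect_equal(s$chain, rep("P", 3))
})

test_that("malformed and empty files give informative parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       1.0x0   2.000   3.000  1.00  0.00           C"
  ), f)
  expect_error(read_structure(f), "line 2")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("", empty)
  expect_error(read_structure(empty), "empty")
})

test_that("duplicated atom records warn but are kept", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C"
  ), f)
  expect_warning(s <- read_structure(f), "duplicated")
  expect_equal(nrow(s), 2)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C"
  ), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 9.0)
})

test_that("write-then-read round-trips atoms to PDB precision", {
  helix <- build_ideal_helix("LYELLHGAGNHAAGILTL", start_resno = 16)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(helix, f)
  back <- read_structure(f)
  expect_equal(nrow(back), nrow(helix))
  expect_equal(back$name, helix$name)
  expect_equal(back$resno, helix$resno)
  expect_equal(back$resname, helix$resname)
  expect_equal(back$x, helix$x, tolerance = 1e-3)
  expect_equal(back$y, helix$y, tolerance = 1e-3)
  expect_equal(back$z, helix$z, tolerance = 1e-3)
})

test_that("parser agrees with an established PDB reader on a fixture", {
  skip_if_not_installed("bio3d")
  helix <- build_ideal_helix("LYELL", start_resno = 16)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(helix, f)
  ours <- read_structure(f)
  ref <- bio3d::read.pdb(f, verbose = FALSE)
  expect_equal(ours$x, ref$atom$x, tolerance = 1e-9)
  expect_equal(ours$y, ref$atom$y, tolerance = 1e-9)
  expect_equal(ours$z, ref$atom$z, tolerance = 1e-9)
  expect_equal(ours$name, ref$atom$elety)
  expect_equal(ours$resno, ref$atom$resno)
})

test_that("multi-model ensembles round-trip with pairwise RMSD preserved", {
  tmpl <- build_ideal_helix("LYELL", start_resno = 16, chain = "P")
  X <- as.matrix(tmpl[, c("x", "y", "z")])
  ens <- mk_ensemble(tmpl, list(X, X, X))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(ens, f)
  back <- read_pose_ensemble(f, ens$receptor)
  expect_equal(n_poses(back), 3)
  D <- rmsd_matrix(back, resno = c(16, 20))
  expect_true(all(D < 1e-9))
})

test_that("a directory of pose files loads in lexicographic order", {
  tmpl <- build_ideal_helix("LYELL", start_resno = 16)
  d <- withr::local_tempdir()
  write_structure(tmpl, file.path(d, "b_pose.pdb"))
  write_structure(dplyr::mutate(tmpl, x = x + 1), file.path(d, "a_pose.pdb"))
  ens <- read_pose_ensemble(d, mk_atoms(c(50, 50, 50)))
  expect_equal(ens$poses$pose_id, c("a_pose", "b_pose"))
})

test_that("a model with a missing atom is rejected by name and count", {
  tmpl <- build_ideal_helix("LYELL", start_resno = 16)
  f <- withr::local_tempfile(fileext = ".pdb")
  lines1 <- poseatlas:::format_pdb_atom(tmpl)
  lines2 <- lines1[-3]
  writeLines(c("MODEL        1", lines1, "ENDMDL",
               "MODEL        2", lines2, "ENDMDL", "END"), f)
  expect_error(read_pose_ensemble(f, mk_atoms(c(50, 50, 50))),
               sprintf("model 2: %d atoms, expected %d",
                       length(lines2), length(lines1)))
})

test_that("score attachment joins by id and reports strays", {
  tmpl <- build_ideal_helix("LYELL", start_resno = 16)
  X <- as.matrix(tmpl[, c("x", "y", "z")])
  ens <- mk_ensemble(tmpl, list(X, X), ids = c("a", "b"))

  out <- attach_scores(ens, tibble::tibble(pose_id = "a", score = -10))
  expect_equal(out$poses$score, c(-10, NA))
  expect_length(attr(out, "unmatched"), 0)

  expect_message(
    out2 <- attach_scores(ens, tibble::tibble(pose_id = "c", score = -1)),
    "match no pose")
  expect_true(all(is.na(out2$poses$score)))
  expect_equal(attr(out2, "unmatched"), "c")

  expect_error(
    attach_scores(ens, tibble::tibble(pose_id = c("a", "a"),
                                      score = c(-10, -9))),
    "duplicate")
})

test_that("BW labels resolve against the structure, structure wins on names", {
  fix <- analytic_receptor()
  res <- resolve_bw(fix$bw_map, fix$structure, "6.48")
  expect_equal(res$resno, 2L)
  bad_map <- fix$bw_map
  bad_map$resname[2] <- "TYR"
  expect_warning(res2 <- resolve_bw(bad_map, fix$structure, "6.48"),
                 "structure wins")
  expect_equal(res2$resname, "ALA")
  expect_error(resolve_bw(fix$bw_map, fix$structure, "9.99"), "known labels")
})
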