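# Shared fixtures and independent oracles, all built in code.

# minimal atom tibble; coordinates in Angstrom
mk_atoms <- function(xyz, name = "CA", elem = "C", resname = "ALA",
                     chain = "A", resno = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  tibble::tibble(
    serial = seq_len(n),
    name = rep_len(name, n),
    resname = rep_len(resname, n),
    chain = rep_len(chain, n),
    resno = resno %||% seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    elem = rep_len(elem, n)
  )
}

`%||%` <- rlang::`%||%`

# ensemble from a template atom tibble and a list of n_atoms x 3 matrices
mk_ensemble <- function(template, coords, receptor = NULL, ids = NULL,
                        peptide_range = NULL) {
  ids <- ids %||% sprintf("p%02d", seq_along(coords))
  xyz <- do.call(rbind, lapply(coords, function(m) as.vector(t(m))))
  receptor <- receptor %||% mk_atoms(c(50, 50, 50))
  poseatlas:::new_pose_ensemble(
    receptor, poseatlas:::new_atoms(template), xyz,
    tibble::tibble(pose_id = ids, score = NA_real_),
    peptide_range %||% range(template$resno))
}

template_xyz <- function(ensemble) {
  as.matrix(ensemble$template[, c("x", "y", "z")])
}

# apply one rigid motion (rotation R, translation t) to an atom tibble
move_atoms <- function(atoms, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]
  atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}

# the same rigid motion on every pose of an ensemble (and its receptor)
move_ensemble <- function(ensemble, R = diag(3), t = c(0, 0, 0)) {
  ensemble$receptor <- move_atoms(ensemble$receptor, R, t)
  n_atoms <- nrow(ensemble$template)
  for (i in seq_len(nrow(ensemble$xyz))) {
    X <- matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE) %*% t(R)
    X <- sweep(X, 2, t, "+")
    ensemble$xyz[i, ] <- as.vector(t(X))
  }
  ensemble
}

rot_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# --- independent clustering oracle ------------------------------------------
# Re-implements the greedy neighbour-count extraction from scratch each round
# using explicit per-pose neighbour lists; written independently of
# daura_cluster() for cross-validation.
daura_oracle <- function(D, cutoff) {
  n <- nrow(D)
  remaining <- seq_len(n)
  out <- list()
  while (length(remaining) > 0) {
    best <- NULL
    best_n <- -1
    for (i in remaining) {
      nb <- remaining[remaining != i & D[i, remaining] < cutoff]
      if (length(nb) > best_n) {
        best <- i
        best_n <- length(nb)
        best_nb <- nb
      }
    }
    members <- sort(c(best, best_nb))
    out[[length(out) + 1]] <- members
    remaining <- setdiff(remaining, members)
  }
  out
}

# membership vector (pose index -> cluster number) from a cluster list
membership_vec <- function(clusters, n) {
  v <- integer(n)
  for (k in seq_along(clusters)) v[clusters[[k]]] <- k
  v
}

# toy receptor + frame, shared across files (cheap to build)
toy_fixture <- function() {
  toy <- build_toy_receptor()
  frame <- build_membrane_frame(toy$structure, toy$bw_map)
  list(receptor = toy, frame = frame)
}

# tiny constructed receptor for analytic frame tests: zero-plane CAs at
# z = 0 spanning the unit triangle, a body CA below, a reference CA along +x
analytic_receptor <- function() {
  at <- mk_atoms(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                       c(1 / 3, 1 / 3, -10), c(10, 1 / 3, 0)),
                 chain = "A", resno = 1:5)
  bw <- tibble::tibble(
    bw_label = c("5.46", "6.48", "7.43", "body", "4.50"),
    chain = "A", resnum = 1:5, resname = "ALA")
  list(structure = at, bw_map = bw)
}
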