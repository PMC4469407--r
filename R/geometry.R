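# Geometric measurements on pose ensembles: no-superposition Calpha RMSD,
# the membrane frame (zero-plane + membrane normal), binding depth and
# rotational azimuth.
#
# RMSD is computed WITHOUT superposition throughout: rigid-body docking poses
# share the receptor frame, and least-squares fitting would erase exactly the
# placement differences the analysis is about.

#' Select atoms of a pose template
#'
#' @param template Atom tibble (ensemble template or any structure).
#' @param atom_names Atom names to keep (`NULL` = all).
#' @param resno Length-2 residue-number range to keep (`NULL` = all).
#' @param heavy_only Drop hydrogens?
#' @return Integer row indices into `template`.
#' @export
atom_indices <- function(template, atom_names = NULL, resno = NULL,
                         heavy_only = FALSE) {
  keep <- rep(TRUE, nrow(template))
  if (!is.null(atom_names)) keep <- keep & template$name %in% atom_names
  if (!is.null(resno)) {
    keep <- keep & template$resno >= resno[1] & template$resno <= resno[2]
  }
  if (heavy_only) keep <- keep & template$elem != "H"
  which(keep)
}

# default selection: peptide Calpha trace
ca_indices <- function(ensemble) {
  atom_indices(ensemble$template, atom_names = "CA",
               resno = ensemble$peptide_range)
}

# column indices into the flat xyz block for a set of atom rows
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain per-atom RMSD with no superposition; both inputs must list the same
#' atoms in the same order.
#'
#' @param a,b n x 3 coordinate matrices (Angstrom), or atom tibbles.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as_xyz(a); b <- as_xyz(b)
  if (nrow(a) == 0) abort("rmsd(): empty atom selection")
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("rmsd(): atom mismatch (%d vs %d atoms)", nrow(a), nrow(b)))
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' All-pairs RMSD matrix over a pose ensemble
#'
#' Computes the symmetric matrix of pairwise no-superposition RMSDs over a
#' fixed atom selection (default: peptide Calpha atoms), once per unordered
#' pair.
#'
#' @param ensemble A `pose_ensemble` with at least 2 poses.
#' @param atom_names,resno Selection passed to [atom_indices()]; defaults to
#'   the Calpha trace of the peptide residue range.
#' @return An `rmsd_matrix`: a symmetric numeric matrix with pose ids as
#'   dimnames and the selection stored in attributes.
#' @export
rmsd_matrix <- function(ensemble, atom_names = "CA", resno = NULL) {
  if (n_poses(ensemble) < 2) abort("rmsd_matrix(): need at least 2 poses")
  resno <- resno %||% ensemble$peptide_range
  idx <- atom_indices(ensemble$template, atom_names = atom_names, resno = resno)
  if (length(idx) == 0) abort("rmsd_matrix(): empty atom selection")
  X <- ensemble$xyz[, xyz_cols(idx), drop = FALSE]
  D <- as.matrix(dist(X)) / sqrt(length(idx))
  dimnames(D) <- list(ensemble$poses$pose_id, ensemble$poses$pose_id)
  structure(D, class = c("rmsd_matrix", "matrix", "array"),
            selection = list(atom_names = atom_names, resno = resno,
                             n_atoms = length(idx)))
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  sel <- attr(x, "selection")
  cat(sprintf("<rmsd_matrix> %d poses | %d atoms per pose | mean %.2f A\n",
              nrow(x), sel$n_atoms, mean(x[upper.tri(x)])))
  invisible(x)
}

# ---- membrane frame ---------------------------------------------------------

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the membrane frame of a receptor
#'
#' Defines the coordinate frame used for binding depth and azimuth. The
#' zero-plane passes through the Calpha atoms of three deep binding-pocket
#' residues (defaults 5.46, 6.48, 7.43); its unit normal is the membrane
#' z-axis, with the sign chosen so that the centroid of all receptor Calpha
#' atoms lies on the negative (intracellular) side — depth therefore increases
#' toward the extracellular mouth. The in-plane x-axis (azimuth zero) points
#' toward a reference residue, by default the TM4 anchor 4.50.
#'
#' With `zero_mode = "single"`, depth is measured from a single residue's
#' Calpha (the plane normal still comes from the three zero-plane residues).
#'
#' @param receptor Structure tibble.
#' @param bw_map BW annotation tibble for the receptor.
#' @param zero_labels Three BW labels whose Calphas span the zero-plane.
#' @param tm_reference BW label anchoring azimuth 0 degrees.
#' @param zero_mode `"plane"` (default; origin = centroid of the three
#'   Calphas) or `"single"` (origin = Calpha of `single_label`).
#' @param single_label Residue used when `zero_mode = "single"`.
#' @param axis_center Optional 3-vector: a point on the bundle axis, used for
#'   radial (in-plane) distances. Default: centroid of all receptor Calphas.
#' @return A `membrane_frame` with fields `origin`, `x_axis`, `y_axis`,
#'   `z_axis`, `axis_center`.
#' @export
build_membrane_frame <- function(receptor, bw_map,
                                 zero_labels = c("5.46", "6.48", "7.43"),
                                 tm_reference = "4.50",
                                 zero_mode = c("plane", "single"),
                                 single_label = "6.48",
                                 axis_center = NULL) {
  zero_mode <- match.arg(zero_mode)
  stopifnot(length(zero_labels) == 3)
  p <- lapply(zero_labels, function(l) bw_ca(bw_map, receptor, l))
  v1 <- p[[2]] - p[[1]]
  v2 <- p[[3]] - p[[1]]
  nrm <- cross3(v1, v2)
  if (sqrt(sum(nrm^2)) < 1e-8 * sqrt(sum(v1^2)) * sqrt(sum(v2^2))) {
    abort("zero-plane residues are collinear; cannot define a plane")
  }
  z_axis <- unit_vec(nrm)
  origin <- (p[[1]] + p[[2]] + p[[3]]) / 3
  ca <- receptor[receptor$name == "CA", ]
  centroid <- c(mean(ca$x), mean(ca$y), mean(ca$z))
  # receptor body sits on the intracellular (negative-z) side of the pocket
  if (sum((centroid - origin) * z_axis) > 0) z_axis <- -z_axis
  if (zero_mode == "single") origin <- bw_ca(bw_map, receptor, single_label)
  ref <- bw_ca(bw_map, receptor, tm_reference)
  v <- ref - origin
  x_axis <- v - sum(v * z_axis) * z_axis
  if (sqrt(sum(x_axis^2)) < 1e-6) {
    abort(sprintf("reference residue %s projects onto the frame origin; %s",
                  tm_reference, "cannot anchor the azimuth"))
  }
  x_axis <- unit_vec(x_axis)
  y_axis <- cross3(z_axis, x_axis)
  structure(
    list(origin = origin, x_axis = x_axis, y_axis = y_axis, z_axis = z_axis,
         axis_center = axis_center %||% centroid,
         zero_labels = zero_labels, tm_reference = tm_reference,
         zero_mode = zero_mode),
    class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> zero-plane %s | azimuth 0 at %s | z = (%.3f, %.3f, %.3f)\n",
              paste(x$zero_labels, collapse = "/"), x$tm_reference,
              x$z_axis[1], x$z_axis[2], x$z_axis[3]))
  invisible(x)
}

#' Express coordinates in a membrane frame
#'
#' @param frame A `membrane_frame`.
#' @param xyz n x 3 world coordinates.
#' @param anchor Origin used for x/y: `"origin"` (zero-plane centroid) or
#'   `"axis_center"` (bundle axis); z is always relative to the zero-plane
#'   origin.
#' @return n x 3 matrix of frame coordinates.
#' @export
frame_coords <- function(frame, xyz, anchor = c("origin", "axis_center")) {
  anchor <- match.arg(anchor)
  xyz <- as_xyz(xyz)
  R <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  o_xy <- if (anchor == "axis_center") frame$axis_center else frame$origin
  loc <- xyz %*% t(R)
  off_xy <- c(sum(o_xy * frame$x_axis), sum(o_xy * frame$y_axis))
  off_z <- sum(frame$origin * frame$z_axis)
  loc[, 1] <- loc[, 1] - off_xy[1]
  loc[, 2] <- loc[, 2] - off_xy[2]
  loc[, 3] <- loc[, 3] - off_z
  colnames(loc) <- c("x", "y", "z")
  loc
}

# inverse of frame_coords(anchor = "axis_center" for xy, zero-plane for z)
frame_to_world <- function(frame, loc) {
  loc <- as_xyz(loc)
  R <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  off <- c(sum(frame$axis_center * frame$x_axis),
           sum(frame$axis_center * frame$y_axis),
           sum(frame$origin * frame$z_axis))
  sweep(loc, 2, -off) %*% R
}

#' Binding depth of each pose
#'
#' Depth is the signed z-coordinate (Angstrom) of an anchor atom — by default
#' the Calpha of the C-terminal residue, e.g. Leu33 of orexin-A(16-33) — in
#' the membrane frame. Positive values lie on the extracellular side of the
#' zero-plane.
#'
#' @param ensemble A `pose_ensemble`.
#' @param frame A `membrane_frame`.
#' @param anchor_resno Residue number of the anchor (default: last peptide
#'   residue).
#' @param anchor_atom Atom name of the anchor (default `"CA"`).
#' @return Tibble with columns `pose_id`, `depth`.
#' @export
binding_depth <- function(ensemble, frame, anchor_resno = NULL,
                          anchor_atom = "CA") {
  anchor_resno <- anchor_resno %||% ensemble$peptide_range[2]
  idx <- which(ensemble$template$resno == anchor_resno &
               ensemble$template$name == anchor_atom)
  if (length(idx) == 0) {
    abort(sprintf("anchor atom %s of residue %d not found in pose template",
                  anchor_atom, anchor_resno))
  }
  idx <- idx[1]
  P <- ensemble$xyz[, xyz_cols(idx), drop = FALSE]
  depth <- as.vector((P %*% frame$z_axis) - sum(frame$origin * frame$z_axis))
  tibble(pose_id = ensemble$poses$pose_id, depth = depth)
}

#' Rotational azimuth of each pose
#'
#' Projects the tail-to-head Calpha vector (default Ala28 -> His26) into the
#' membrane plane and measures its angle from the frame x-axis,
#' counterclockwise as seen from the extracellular side. The in-plane length
#' of the projection is returned too: short projections indicate tilted
#' peptides whose rotational state is poorly defined.
#'
#' @param ensemble A `pose_ensemble`.
#' @param frame A `membrane_frame`.
#' @param tail_resno,head_resno Residue numbers of the vector tail and head.
#' @param atom Atom name used at both ends (default `"CA"`).
#' @param on_degenerate `"error"` (default) to fail when the in-plane length
#'   is below 1e-6 Angstrom, or `"na"` to return `NA` azimuth for such poses.
#' @return Tibble with columns `pose_id`, `azimuth` (degrees in \[0, 360)),
#'   `inplane` (Angstrom).
#' @export
azimuth <- function(ensemble, frame, tail_resno = 28, head_resno = 26,
                    atom = "CA", on_degenerate = c("error", "na")) {
  on_degenerate <- match.arg(on_degenerate)
  pick <- function(resno) {
    idx <- which(ensemble$template$resno == resno &
                 ensemble$template$name == atom)
    if (length(idx) == 0) {
      abort(sprintf("atom %s of residue %d not found in pose template",
                    atom, resno))
    }
    idx[1]
  }
  Ph <- ensemble$xyz[, xyz_cols(pick(head_resno)), drop = FALSE]
  Pt <- ensemble$xyz[, xyz_cols(pick(tail_resno)), drop = FALSE]
  v <- Ph - Pt
  vx <- as.vector(v %*% frame$x_axis)
  vy <- as.vector(v %*% frame$y_axis)
  inplane <- sqrt(vx^2 + vy^2)
  az <- wrap_deg(rad2deg(atan2(vy, vx)))
  degen <- inplane < 1e-6
  if (any(degen)) {
    if (on_degenerate == "error") {
      abort(sprintf("undefined azimuth: pose(s) %s project to < 1e-6 A in-plane",
                    paste(ensemble$poses$pose_id[degen], collapse = ", ")))
    }
    az[degen] <- NA_real_
  }
  tibble(pose_id = ensemble$poses$pose_id, azimuth = az, inplane = inplane)
}

#' Azimuth of a receptor residue around the bundle axis
#'
#' The in-plane angle of the residue's Calpha, seen from the bundle axis,
#' measured from the frame x-axis. Used to derive binding-mode sector centers
#' from the receptor structure itself.
#'
#' @param receptor Structure tibble.
#' @param frame A `membrane_frame`.
#' @param bw_map BW annotation tibble.
#' @param label BW label of the residue.
#' @return Angle in degrees in \[0, 360).
#' @export
residue_azimuth <- function(receptor, frame, bw_map, label) {
  ca <- bw_ca(bw_map, receptor, label)
  loc <- frame_coords(frame, matrix(ca, 1, 3), anchor = "axis_center")
  if (sqrt(loc[1]^2 + loc[2]^2) < 1e-6) {
    abort(sprintf("residue %s lies on the bundle axis", label))
  }
  wrap_deg(rad2deg(atan2(loc[2], loc[1])))
}

#' Summarize binding depths
#'
#' @param depths Tibble from [binding_depth()] (or any data frame with a
#'   `depth` column).
#' @return One-row tibble with `median`, `min`, `max`, `n`.
#' @export
summarize_depths <- function(depths) {
  d <- depths$depth
  d <- d[!is.na(d)]
  if (length(d) == 0) abort("summarize_depths(): no depths")
  tibble(median = median(d), min = min(d), max = max(d), n = length(d))
}
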