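# Receptor-ligand contact mapping: binary contacts per pose and contact
# frequencies over pose groups at a distance cutoff (default 4 Angstrom,
# strict <, any atom type — no side-chain/main-chain distinction).

resolve_residue_set <- function(receptor, residues, bw_map = NULL) {
  if (is.character(residues)) {
    if (is.null(bw_map)) {
      abort("BW-label residue set needs a bw_map")
    }
    res <- bind_rows(lapply(residues, function(l) {
      hit <- bw_map[bw_map$bw_label == l, ]
      if (nrow(hit) == 0) {
        abort(sprintf("unknown BW label '%s'; known labels: %s", l,
                      paste(bw_map$bw_label, collapse = ", ")))
      }
      tibble(chain = hit$chain, resno = hit$resnum, label = l)
    }))
  } else {
    res <- as_tibble(residues)
    if (!all(c("chain", "resno") %in% names(res))) {
      abort("residue set must have chain and resno columns (or be BW labels)")
    }
    if (!"label" %in% names(res)) {
      res$label <- paste0(res$chain, res$resno)
      if (!is.null(bw_map)) {
        m <- match(paste(res$chain, res$resno),
                   paste(bw_map$chain, bw_map$resnum))
        res$label[!is.na(m)] <- bw_map$bw_label[m[!is.na(m)]]
      }
    }
  }
  if (nrow(res) == 0) abort("empty receptor residue set")
  res
}

contact_grid <- function(ensemble, residue_set) {
  rec <- ensemble$receptor
  rec_idx <- lapply(seq_len(nrow(residue_set)), function(i) {
    which(rec$chain == residue_set$chain[i] &
          rec$resno == residue_set$resno[i])
  })
  if (any(lengths(rec_idx) == 0)) {
    bad <- which(lengths(rec_idx) == 0)[1]
    abort(sprintf("receptor residue %s/%d has no atoms",
                  residue_set$chain[bad], residue_set$resno[bad]))
  }
  lig_res <- sort(unique(ensemble$template$resno))
  lig_idx <- lapply(lig_res, function(r) which(ensemble$template$resno == r))
  list(rec_idx = rec_idx, lig_res = lig_res, lig_idx = lig_idx,
       rec_xyz = as_xyz(rec))
}

# binary contact matrix (receptor residues x ligand residues) for one pose
contacts_one_pose <- function(grid, L, cutoff) {
  nr <- length(grid$rec_idx); nl <- length(grid$lig_idx)
  out <- matrix(FALSE, nr, nl)
  for (i in seq_len(nr)) {
    R <- grid$rec_xyz[grid$rec_idx[[i]], , drop = FALSE]
    for (j in seq_len(nl)) {
      Lj <- L[grid$lig_idx[[j]], , drop = FALSE]
      out[i, j] <- min_cross_dist2(Lj, R) < cutoff^2
    }
  }
  out
}

contact_tibble <- function(mat, residue_set, lig_res, cutoff, type, n_poses) {
  out <- tibble(
    receptor_label = rep(residue_set$label, times = length(lig_res)),
    receptor_chain = rep(residue_set$chain, times = length(lig_res)),
    receptor_resno = rep(residue_set$resno, times = length(lig_res)),
    ligand_resno = rep(lig_res, each = nrow(residue_set)),
    value = as.vector(mat)
  )
  class(out) <- c("contact_map", class(out))
  attr(out, "cutoff") <- cutoff
  attr(out, "type") <- type
  attr(out, "n_poses") <- n_poses
  out
}

#' Binary receptor-ligand contact map of one pose
#'
#' A receptor residue and a ligand residue are in contact when any pair of
#' their atoms (any atom type, hydrogens included if present) lies strictly
#' closer than `cutoff`.
#'
#' @param ensemble A `pose_ensemble`.
#' @param pose_id Pose to map.
#' @param residues Receptor residue set: either a character vector of BW
#'   labels (then `bw_map` is required) or a data frame with `chain`/`resno`
#'   (and optionally `label`) columns.
#' @param cutoff Contact distance in Angstrom (strict `<`).
#' @param bw_map Optional BW annotation tibble used to label residues.
#' @param heavy_only Restrict to heavy atoms (default `FALSE`: all atoms).
#' @return A `contact_map` tibble in long form: `receptor_label`,
#'   `receptor_chain`, `receptor_resno`, `ligand_resno`, `value` (0/1).
#' @export
contact_map <- function(ensemble, pose_id, residues, cutoff = 4.0,
                        bw_map = NULL, heavy_only = FALSE) {
  res <- resolve_residue_set(ensemble$receptor, residues, bw_map)
  ens <- ensemble
  if (heavy_only) {
    keep <- atom_indices(ens$template, heavy_only = TRUE)
    ens$template <- ens$template[keep, ]
    ens$xyz <- ens$xyz[, xyz_cols(keep), drop = FALSE]
    ens$receptor <- ens$receptor |> filter(.data$elem != "H")
  }
  if (nrow(ens$template) == 0) abort("contact_map(): empty ligand")
  grid <- contact_grid(ens, res)
  L <- pose_coords(ens, pose_id)
  mat <- contacts_one_pose(grid, L, cutoff)
  contact_tibble(mat * 1, res, grid$lig_res, cutoff, "binary", 1L)
}

#' Contact frequencies over a group of poses
#'
#' For every (receptor residue, ligand residue) pair, the fraction of poses
#' in the group in which the pair is in contact. The frequency map of a
#' singleton group equals its binary map.
#'
#' @inheritParams contact_map
#' @return A `contact_map` tibble with `value` = frequency in \[0, 1\].
#' @export
contact_frequency <- function(ensemble, residues, cutoff = 4.0,
                              bw_map = NULL, heavy_only = FALSE) {
  if (n_poses(ensemble) == 0) abort("contact_frequency(): empty pose group")
  res <- resolve_residue_set(ensemble$receptor, residues, bw_map)
  ens <- ensemble
  if (heavy_only) {
    keep <- atom_indices(ens$template, heavy_only = TRUE)
    ens$template <- ens$template[keep, ]
    ens$xyz <- ens$xyz[, xyz_cols(keep), drop = FALSE]
    ens$receptor <- ens$receptor |> filter(.data$elem != "H")
  }
  grid <- contact_grid(ens, res)
  acc <- matrix(0, length(grid$rec_idx), length(grid$lig_idx))
  for (i in seq_len(n_poses(ens))) {
    L <- matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
    acc <- acc + contacts_one_pose(grid, L, cutoff)
  }
  contact_tibble(acc / n_poses(ens), res, grid$lig_res, cutoff,
                 "frequency", n_poses(ens))
}

#' Cast a contact map to a matrix
#'
#' @param map A `contact_map`.
#' @return Numeric matrix, receptor residues (labels) x ligand residues.
#' @export
contact_matrix <- function(map) {
  labs <- unique(map$receptor_label)
  lres <- sort(unique(map$ligand_resno))
  m <- matrix(0, length(labs), length(lres),
              dimnames = list(labs, as.character(lres)))
  m[cbind(match(map$receptor_label, labs),
          match(map$ligand_resno, lres))] <- map$value
  m
}

#' Write a contact map as TSV (wide, BW-labelled rows)
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  m <- contact_matrix(map)
  df <- data.frame(receptor_residue = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
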