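# Reading and writing structures and docked-pose ensembles.
#
# Structures are plain tibbles of atom records (one row per atom) so they can
# be filtered and joined with the usual dplyr verbs. Coordinates are Angstrom.
# Pose ensembles keep a single atom template plus an n_poses x 3*n_atoms
# coordinate block, because poses from rigid-body docking share atoms and
# ordering by construction.

ATOM_COLS <- c("serial", "name", "resname", "chain", "resno",
               "x", "y", "z", "elem")

one_to_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

new_atoms <- function(df) {
  df <- as_tibble(df)[, ATOM_COLS]
  class(df) <- c("poseatlas_atoms", class(df))
  df
}

guess_element <- function(name) {
  # strip digits/primes, take the leading letter; two-letter elements are not
  # expected in peptides and receptors handled here
  e <- sub("^[0-9']*", "", name)
  toupper(substr(e, 1, 1))
}

parse_pdb_lines <- function(lines, source = "<text>") {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | grepl("^(ATOM|HETATM)", rec)
  idx <- which(is_atom)
  if (length(idx) == 0) {
    abort(sprintf("no ATOM/HETATM records found in %s", source))
  }
  al <- lines[idx]
  num_field <- function(chars, lo, hi, what) {
    raw <- substr(chars, lo, hi)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & trimws(raw) != "")
    bad <- union(bad, which(trimws(raw) == ""))
    if (length(bad) > 0) {
      abort(sprintf("%s: malformed %s field at line %d: '%s'",
                    source, what, idx[bad[1]], raw[bad[1]]))
    }
    val
  }
  elem_raw <- trimws(substr(al, 77, 78))
  name <- trimws(substr(al, 13, 16))
  tibble(
    serial  = as.integer(num_field(al, 7, 11, "serial")),
    name    = name,
    altloc  = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain   = substr(al, 22, 22),
    resno   = as.integer(num_field(al, 23, 26, "residue number")),
    x       = num_field(al, 31, 38, "x coordinate"),
    y       = num_field(al, 39, 46, "y coordinate"),
    z       = num_field(al, 47, 54, "z coordinate"),
    occ     = suppressWarnings(as.numeric(substr(al, 55, 60))) %|NA|% 1,
    elem    = ifelse(elem_raw == "", guess_element(name), elem_raw),
    line    = idx
  )
}

# altLoc policy: keep the highest-occupancy conformer per (chain, resno, name);
# ties broken by file order
resolve_altloc <- function(at) {
  if (all(at$altloc %in% c(" ", ""))) return(at)
  at |>
    group_by(.data$chain, .data$resno, .data$name) |>
    arrange(desc(.data$occ), .data$line, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$line)
}

#' Read a structure from a PDB file
#'
#' Parses fixed-width `ATOM`/`HETATM` records into a tibble of atom records
#' (columns `serial`, `name`, `resname`, `chain`, `resno`, `x`, `y`, `z`,
#' `elem`). A single leading `MODEL`/`ENDMDL` pair is tolerated; if the file
#' holds several models only the first is read, with a warning (use
#' [read_pose_ensemble()] for multi-model ensembles). Alternate-location
#' conformers are reduced to the highest-occupancy one (ties: first in file).
#' Duplicated (chain, residue, atom name) records trigger a warning but both
#' atoms are kept.
#'
#' @param path Path to a PDB file.
#' @return A tibble of atom records; coordinates in Angstrom.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(trimws(lines) == "")) {
    abort(sprintf("empty PDB file: %s", path))
  }
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    warn(sprintf("%s contains %d models; reading the first only",
                 path, length(model_starts)))
    end1 <- grep("^ENDMDL", lines)[1]
    lines <- lines[seq_len(end1)]
  }
  at <- parse_pdb_lines(lines, source = path)
  at <- resolve_altloc(at)
  dup <- at |> count(.data$chain, .data$resno, .data$name) |> filter(n > 1)
  if (nrow(dup) > 0) {
    warn(sprintf("%d duplicated (chain, resno, atom name) records kept in %s",
                 nrow(dup), path))
  }
  new_atoms(at)
}

format_pdb_atom <- function(at) {
  nm <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          at$serial %% 100000, nm, at$resname, at$chain, at$resno,
          at$x, at$y, at$z, 1.0, 0.0, at$elem)
}

#' Write a structure to a PDB file
#'
#' @param atoms A tibble of atom records as returned by [read_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  writeLines(c(format_pdb_atom(atoms), "END"), path)
  invisible(path)
}

# ---- pose ensembles ---------------------------------------------------------

new_pose_ensemble <- function(receptor, template, xyz, poses, peptide_range) {
  stopifnot(nrow(xyz) == nrow(poses), ncol(xyz) == 3 * nrow(template))
  rownames(xyz) <- poses$pose_id
  structure(
    list(receptor = receptor, template = template, xyz = xyz,
         poses = poses, peptide_range = peptide_range),
    class = "pose_ensemble"
  )
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf(
    "<pose_ensemble> %d poses | %d ligand atoms (residues %d-%d) | %d scored\n",
    n_poses(x), nrow(x$template), x$peptide_range[1], x$peptide_range[2],
    sum(!is.na(x$poses$score))))
  invisible(x)
}

#' Number of poses in an ensemble
#' @param ensemble A `pose_ensemble`.
#' @return Integer count.
#' @export
n_poses <- function(ensemble) nrow(ensemble$poses)

#' Pose metadata as a tibble
#'
#' @param x A `pose_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per pose (`pose_id`, `score`, any tags).
#' @method as_tibble pose_ensemble
#' @export
as_tibble.pose_ensemble <- function(x, ...) x$poses

#' Coordinates of one pose
#'
#' @param ensemble A `pose_ensemble`.
#' @param pose_id A pose id present in the ensemble.
#' @return An n_atoms x 3 matrix of coordinates (Angstrom), rows in template
#'   atom order.
#' @export
pose_coords <- function(ensemble, pose_id) {
  i <- match(pose_id, ensemble$poses$pose_id)
  if (is.na(i)) abort(sprintf("unknown pose id: %s", pose_id))
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Subset an ensemble by pose ids
#'
#' Keeps ensemble order; the atom template is untouched, so all remaining
#' poses still share atom ordering.
#'
#' @param ensemble A `pose_ensemble`.
#' @param pose_ids Character vector of ids to keep.
#' @return A `pose_ensemble`.
#' @export
subset_poses <- function(ensemble, pose_ids) {
  keep <- ensemble$poses$pose_id %in% pose_ids
  if (!all(pose_ids %in% ensemble$poses$pose_id)) {
    abort("subset_poses(): some requested ids are not in the ensemble")
  }
  new_pose_ensemble(ensemble$receptor, ensemble$template,
                    ensemble$xyz[keep, , drop = FALSE],
                    ensemble$poses[keep, , drop = FALSE],
                    ensemble$peptide_range)
}

template_from_atoms <- function(atoms) {
  new_atoms(atoms)
}

ensemble_from_models <- function(receptor, models, ids, peptide_range = NULL) {
  template <- models[[1]]
  n_atoms <- nrow(template)
  key <- function(a) paste(a$chain, a$resno, a$name)
  for (m in seq_along(models)) {
    if (nrow(models[[m]]) != n_atoms) {
      abort(sprintf("model %s: %d atoms, expected %d",
                    ids[m], nrow(models[[m]]), n_atoms))
    }
    if (!identical(key(models[[m]]), key(template))) {
      abort(sprintf("model %s: atom ordering differs from the first model",
                    ids[m]))
    }
  }
  xyz <- do.call(rbind, lapply(models, function(a) {
    as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  }))
  if (is.null(peptide_range)) peptide_range <- range(template$resno)
  new_pose_ensemble(
    receptor, template_from_atoms(template), xyz,
    tibble(pose_id = ids, score = NA_real_),
    peptide_range
  )
}

#' Read a docked-pose ensemble
#'
#' Reads either a multi-model PDB (one pose per `MODEL` block) or a directory
#' of single-model PDB files (one pose per file, ordered lexicographically by
#' filename). All poses must share atom count and ordering; poses are taken as
#' already expressed in the receptor's coordinate frame and are never
#' re-superposed.
#'
#' @param path Multi-model PDB file or directory of PDB files.
#' @param receptor Receptor structure tibble (from [read_structure()]).
#' @param peptide_range Optional length-2 integer vector giving the first and
#'   last peptide residue numbers; defaults to the full residue range of the
#'   pose template.
#' @return A `pose_ensemble`.
#' @export
read_pose_ensemble <- function(path, receptor, peptide_range = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0) abort(sprintf("no .pdb files in %s", path))
    models <- lapply(files, function(f) suppressWarnings(read_structure(f)))
    ids <- sub("\\.pdb$", "", basename(files))
    return(ensemble_from_models(receptor, models, ids, peptide_range))
  }
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    # single-model file: an ensemble of one
    at <- resolve_altloc(parse_pdb_lines(lines, source = path))
    return(ensemble_from_models(receptor, list(at), "1", peptide_range))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) {
    abort(sprintf("%s: %d MODEL but %d ENDMDL records",
                  path, length(starts), length(ends)))
  }
  ids <- trimws(substr(lines[starts], 7, 20))
  models <- map2(starts, ends, function(s, e) {
    resolve_altloc(parse_pdb_lines(lines[s:e], source = path))
  })
  # a REMARK 999 POSE_ID line inside a model overrides the MODEL number,
  # so string pose ids survive the PDB round-trip
  for (m in seq_along(starts)) {
    block <- lines[starts[m]:ends[m]]
    tag <- grep("^REMARK 999 POSE_ID ", block, value = TRUE)
    if (length(tag) > 0) ids[m] <- trimws(sub("^REMARK 999 POSE_ID ", "", tag[1]))
  }
  ensemble_from_models(receptor, models, ids, peptide_range)
}

#' Write a pose ensemble as a multi-model PDB
#'
#' @param ensemble A `pose_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_ensemble <- function(ensemble, path) {
  out <- character(0)
  tmpl <- ensemble$template
  for (i in seq_len(n_poses(ensemble))) {
    at <- tmpl
    xyz <- matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    out <- c(out, sprintf("MODEL %8d", i),
             sprintf("REMARK 999 POSE_ID %s", ensemble$poses$pose_id[i]),
             format_pdb_atom(at), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---- score tables -----------------------------------------------------------

#' Read a per-pose score table
#'
#' Two-column TSV/CSV with header `pose_id` and `score` (refinement score,
#' lower is better).
#'
#' @param path Path to the table.
#' @return Tibble with columns `pose_id` (character) and `score` (double).
#' @export
read_score_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (!all(c("pose_id", "score") %in% names(df))) {
    abort(sprintf("%s: expected columns pose_id and score", path))
  }
  tibble(pose_id = as.character(df$pose_id), score = as.numeric(df$score))
}

#' Attach refinement scores to a pose ensemble
#'
#' Joins scores by pose id. Poses absent from the table keep a missing score;
#' table rows that match no pose are reported via a message and returned in
#' the `unmatched` attribute.
#'
#' @param ensemble A `pose_ensemble`.
#' @param table Data frame with columns `pose_id` and `score`.
#' @return The ensemble with scores filled in.
#' @export
attach_scores <- function(ensemble, table) {
  table <- as_tibble(table)
  if (anyDuplicated(table$pose_id)) {
    abort(sprintf("duplicate pose id(s) in score table: %s",
                  paste(unique(table$pose_id[duplicated(table$pose_id)]),
                        collapse = ", ")))
  }
  if (any(is.infinite(table$score))) abort("non-finite score in table")
  m <- match(ensemble$poses$pose_id, table$pose_id)
  ensemble$poses$score <- table$score[m]
  unmatched <- setdiff(table$pose_id, ensemble$poses$pose_id)
  if (length(unmatched) > 0) {
    inform(sprintf("attach_scores(): %d table row(s) match no pose",
                   length(unmatched)))
  }
  attr(ensemble, "unmatched") <- unmatched
  ensemble
}

# ---- Ballesteros-Weinstein maps --------------------------------------------

#' Read a Ballesteros-Weinstein annotation table
#'
#' TSV with header `bw_label`, `chain`, `resnum`, `resname` mapping BW labels
#' (e.g. `"6.48"`, or ECL2 labels like `"xl2.50"`) to residues of a specific
#' receptor structure.
#'
#' @param path Path to the TSV.
#' @return Tibble with those four columns.
#' @export
read_bw_map <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", colClasses = "character")
  need <- c("bw_label", "chain", "resnum", "resname")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  out <- tibble(bw_label = as.character(df$bw_label),
                chain = as.character(df$chain),
                resnum = as.integer(df$resnum),
                resname = as.character(df$resname))
  if (anyDuplicated(out$bw_label)) abort("duplicate BW labels in map")
  out
}

#' Write a Ballesteros-Weinstein annotation table
#' @param bw_map Tibble as returned by [read_bw_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bw_map <- function(bw_map, path) {
  write.table(bw_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve a Ballesteros-Weinstein label to residue atoms
#'
#' @param bw_map BW annotation tibble.
#' @param structure Structure tibble the map refers to.
#' @param label A single BW label, e.g. `"6.48"`.
#' @return Tibble of the residue's atom records.
#' @export
resolve_bw <- function(bw_map, structure, label) {
  hit <- bw_map[bw_map$bw_label == label, ]
  if (nrow(hit) == 0) {
    abort(sprintf("unknown BW label '%s'; known labels: %s", label,
                  paste(bw_map$bw_label, collapse = ", ")))
  }
  res <- structure[structure$chain == hit$chain &
                   structure$resno == hit$resnum, , drop = FALSE]
  if (nrow(res) == 0) {
    abort(sprintf("BW label %s maps to %s/%d, absent from the structure",
                  label, hit$chain, hit$resnum))
  }
  if (!all(res$resname == hit$resname)) {
    warn(sprintf(
      "BW label %s: map says %s but structure has %s at %s/%d (structure wins)",
      label, hit$resname, res$resname[1], hit$chain, hit$resnum))
  }
  res
}

# Calpha coordinate of a BW-labelled residue
bw_ca <- function(bw_map, structure, label) {
  res <- resolve_bw(bw_map, structure, label)
  ca <- res[res$name == "CA", ]
  if (nrow(ca) == 0) abort(sprintf("BW label %s: residue has no CA atom", label))
  c(ca$x[1], ca$y[1], ca$z[1])
}
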