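# Pose admissibility filters and score-based selections.
#
# Two geometric admissibility rules emulate the screening applied to raw
# rigid-body docking output before refinement:
#   * interface rule — the functionally critical C-terminal residues of the
#     peptide must touch the receptor;
#   * membrane rule — the peptide must not thread between the TM helices into
#     the membrane slab.
# Score selections pick "top-ranking" poses from refinement scores
# (lower = better).

new_filter_report <- function(rule, params, verdicts, ensemble) {
  structure(
    list(rule = rule, params = params, verdicts = verdicts,
         ensemble = ensemble),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> rule '%s': %d pass / %d fail of %d\n",
              x$rule, sum(x$verdicts$pass), sum(!x$verdicts$pass),
              nrow(x$verdicts)))
  invisible(x)
}

#' Surviving poses of a filter report
#' @param report A `filter_report`.
#' @return The surviving `pose_ensemble`.
#' @export
passing_poses <- function(report) report$ensemble

#' Interface filter: C-terminal residues must contact the receptor
#'
#' A pose passes if at least one heavy atom of the named peptide residues lies
#' within `cutoff` of any receptor heavy atom.
#'
#' @param ensemble A `pose_ensemble`.
#' @param c_term_range Length-2 residue-number range (default: the last four
#'   peptide residues, e.g. 30-33 for orexin-A(16-33)).
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @return A `filter_report` (per-pose verdicts plus the surviving ensemble).
#' @export
interface_filter <- function(ensemble, c_term_range = NULL, cutoff = 5.0) {
  c_term_range <- c_term_range %||%
    c(ensemble$peptide_range[2] - 3, ensemble$peptide_range[2])
  if (c_term_range[1] > c_term_range[2]) {
    abort("interface_filter(): empty C-terminal residue range")
  }
  idx <- atom_indices(ensemble$template, resno = c_term_range,
                      heavy_only = TRUE)
  if (length(idx) == 0) {
    abort("interface_filter(): no heavy atoms in the C-terminal range")
  }
  rec <- ensemble$receptor |> filter(.data$elem != "H")
  R <- as_xyz(rec)
  cols <- xyz_cols(idx)
  pass <- vapply(seq_len(n_poses(ensemble)), function(i) {
    L <- matrix(ensemble$xyz[i, cols], ncol = 3, byrow = TRUE)
    min_cross_dist2(L, R) <= cutoff^2 && cutoff > 0
  }, logical(1))
  verdicts <- tibble(pose_id = ensemble$poses$pose_id, pass = pass,
                     failed_rules = ifelse(pass, "", "interface"))
  new_filter_report("interface",
                    list(c_term_range = c_term_range, cutoff = cutoff),
                    verdicts,
                    subset_poses(ensemble, verdicts$pose_id[pass]))
}

# squared minimum distance between two coordinate sets (small blocks)
min_cross_dist2 <- function(A, B) {
  # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  m <- outer(a2, b2, "+") - 2 * A %*% t(B)
  max(min(m), 0)
}

#' Membrane filter: no peptide atoms among or beyond the TM helices
#'
#' A pose fails if any peptide heavy atom sits inside the membrane slab
#' (frame z within `slab`) while lying farther than `cavity_radius` from the
#' bundle axis — i.e. between or beyond the helices, in membrane-occupied
#' space, rather than in the interhelical cavity.
#'
#' @param ensemble A `pose_ensemble`.
#' @param frame A `membrane_frame` (its `axis_center` defines the bundle axis).
#' @param slab Length-2 z-range of the membrane slab, Angstrom relative to
#'   the zero-plane.
#' @param cavity_radius In-plane radius of the interhelical cavity, Angstrom.
#' @return A `filter_report`.
#' @export
membrane_filter <- function(ensemble, frame, slab = c(-15, 15),
                            cavity_radius = 13) {
  if (!all(is.finite(slab)) || slab[1] >= slab[2]) {
    abort("membrane_filter(): slab must be finite with z_min < z_max")
  }
  idx <- atom_indices(ensemble$template, heavy_only = TRUE)
  cols <- xyz_cols(idx)
  n <- n_poses(ensemble)
  # all atoms of all poses at once
  X <- matrix(t(ensemble$xyz[, cols, drop = FALSE]), ncol = 3, byrow = TRUE)
  loc <- frame_coords(frame, X, anchor = "axis_center")
  # depth (z) is measured from the zero-plane regardless of anchor
  in_slab <- loc[, 3] >= slab[1] & loc[, 3] <= slab[2]
  outside <- sqrt(loc[, 1]^2 + loc[, 2]^2) > cavity_radius
  bad_atom <- in_slab & outside
  fail <- rowSums(matrix(bad_atom, nrow = n, byrow = TRUE)) > 0
  verdicts <- tibble(pose_id = ensemble$poses$pose_id, pass = !fail,
                     failed_rules = ifelse(fail, "membrane", ""))
  new_filter_report("membrane",
                    list(slab = slab, cavity_radius = cavity_radius),
                    verdicts,
                    subset_poses(ensemble, verdicts$pose_id[!fail]))
}

#' Combine filter reports by intersection
#'
#' @param ... `filter_report` objects over the same input ensemble.
#' @param ensemble The input `pose_ensemble`.
#' @return A combined `filter_report`; a pose passes iff it passes every rule,
#'   and `failed_rules` joins the names of all rules that rejected it.
#' @export
combine_filters <- function(..., ensemble) {
  reports <- list(...)
  verdicts <- tibble(pose_id = ensemble$poses$pose_id, pass = TRUE,
                     failed_rules = "")
  for (r in reports) {
    v <- r$verdicts[match(verdicts$pose_id, r$verdicts$pose_id), ]
    verdicts$pass <- verdicts$pass & v$pass
    verdicts$failed_rules <- trimws(paste(verdicts$failed_rules,
                                          v$failed_rules))
  }
  new_filter_report(paste(vapply(reports, function(r) r$rule, ""),
                          collapse = "+"),
                    lapply(reports, function(r) r$params),
                    verdicts,
                    subset_poses(ensemble, verdicts$pose_id[verdicts$pass]))
}

#' Keep poses at or below a score threshold
#'
#' Emulates "refinement score of t or lower": the comparison is `<=`.
#' Unscored poses are dropped with a warning.
#'
#' @param ensemble A scored `pose_ensemble`.
#' @param threshold Score threshold (lower scores are better).
#' @return A `pose_ensemble` of the retained poses.
#' @export
score_filter <- function(ensemble, threshold) {
  s <- ensemble$poses$score
  if (all(is.na(s))) abort("score_filter(): no scored poses")
  if (any(is.na(s))) {
    warn(sprintf("score_filter(): dropping %d unscored pose(s)",
                 sum(is.na(s))))
  }
  keep <- !is.na(s) & s <= threshold
  subset_poses(ensemble, ensemble$poses$pose_id[keep])
}

#' Keep the best-scoring fraction of poses
#'
#' Selects the best `ceiling(fraction * N)` scored poses by ascending score;
#' ties at the boundary are broken by pose id (lexicographic).
#'
#' @param ensemble A scored `pose_ensemble`.
#' @param fraction Fraction in (0, 1].
#' @return A `pose_ensemble` of the selected poses, in ensemble order.
#' @export
top_fraction <- function(ensemble, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("top_fraction(): fraction must be in (0, 1]")
  }
  p <- ensemble$poses
  if (all(is.na(p$score))) abort("top_fraction(): no scored poses")
  if (any(is.na(p$score))) {
    warn(sprintf("top_fraction(): dropping %d unscored pose(s)",
                 sum(is.na(p$score))))
    p <- p[!is.na(p$score), ]
  }
  k <- ceiling(fraction * nrow(p))
  ord <- order(p$score, p$pose_id)
  subset_poses(ensemble, p$pose_id[ord[seq_len(k)]])
}

#' Write a filter report as TSV
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  out <- report$verdicts |>
    mutate(verdict = ifelse(.data$pass, "pass", "fail")) |>
    select("pose_id", "verdict", "failed_rules")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
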