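# Binding-mode classification from the rotational azimuth.
#
# High-scoring poses fall into two alternative rotational states roughly 100
# degrees apart: the bulky residues near the peptide C-terminus face either
# TM5 or TM7. Sector boundaries default to +/- 50 degrees around the azimuths
# of per-receptor reference residues (5.39 for TM5, 7.35 for TM7) so the
# classification is anchored to the structure, not to absolute angles.

#' Default binding-mode sectors from the receptor structure
#'
#' @param receptor Structure tibble.
#' @param frame A `membrane_frame`.
#' @param bw_map BW annotation tibble.
#' @param tm5_label,tm7_label Reference residues for the two modes.
#' @param half_width Sector half-width in degrees.
#' @return Named list `list(TM5 = c(lo, hi), TM7 = c(lo, hi))` of azimuth
#'   sectors in degrees (sectors may wrap across 0/360).
#' @export
default_mode_sectors <- function(receptor, frame, bw_map,
                                 tm5_label = "5.39", tm7_label = "7.35",
                                 half_width = 50) {
  c5 <- residue_azimuth(receptor, frame, bw_map, tm5_label)
  c7 <- residue_azimuth(receptor, frame, bw_map, tm7_label)
  if (abs(ang_diff(c5, c7)) < 2 * half_width) {
    abort(sprintf(
      "mode sectors overlap: reference azimuths %.1f and %.1f with half-width %.1f",
      c5, c7, half_width))
  }
  list(TM5 = wrap_deg(c(c5 - half_width, c5 + half_width)),
       TM7 = wrap_deg(c(c7 - half_width, c7 + half_width)))
}

in_sector <- function(az, sector) {
  lo <- sector[1]; hi <- sector[2]
  if (lo <= hi) az >= lo & az <= hi else az >= lo | az <= hi
}

sectors_disjoint <- function(sectors) {
  grid <- seq(0, 359.75, by = 0.25)
  hits <- rowSums(vapply(sectors, function(s) in_sector(grid, s),
                         logical(length(grid))))
  all(hits <= 1)
}

#' Classify poses into rotational binding modes
#'
#' Computes each pose's azimuth (tail-to-head Calpha vector in the membrane
#' plane, see [azimuth()]) and assigns the sector it falls in — provided its
#' in-plane projection is long enough for the rotational state to be
#' meaningful. Everything else, including poses with an undefined azimuth
#' (near-vertical projection), is labelled `"outlier"` with the reason
#' recorded.
#'
#' @param ensemble A `pose_ensemble`.
#' @param frame A `membrane_frame`.
#' @param sectors Named list of azimuth sectors (`c(lo, hi)` degrees, may
#'   wrap); defaults should come from [default_mode_sectors()].
#' @param min_inplane Minimum in-plane projection length (Angstrom) for a
#'   mode label.
#' @param tail_resno,head_resno Azimuth vector residues (default Ala28 ->
#'   His26).
#' @return A `mode_assignment` tibble: `pose_id`, `azimuth`, `inplane`,
#'   `mode`, `reason`.
#' @export
assign_modes <- function(ensemble, frame, sectors, min_inplane = 1.0,
                         tail_resno = 28, head_resno = 26) {
  if (is.null(names(sectors)) || any(names(sectors) == "")) {
    abort("assign_modes(): sectors must be a named list")
  }
  if (!sectors_disjoint(sectors)) abort("assign_modes(): sectors overlap")
  az <- azimuth(ensemble, frame, tail_resno = tail_resno,
                head_resno = head_resno, on_degenerate = "na")
  mode <- rep("outlier", nrow(az))
  reason <- rep("", nrow(az))
  reason[is.na(az$azimuth)] <- "undefined_azimuth"
  tilted <- !is.na(az$azimuth) & az$inplane < min_inplane
  reason[tilted] <- "tilted"
  eligible <- !is.na(az$azimuth) & !tilted
  for (nm in names(sectors)) {
    hit <- eligible & in_sector(az$azimuth, sectors[[nm]])
    mode[hit] <- nm
  }
  reason[eligible & mode == "outlier"] <- "outside_sectors"
  out <- az |> mutate(mode = mode, reason = reason)
  class(out) <- c("mode_assignment", class(out))
  attr(out, "sectors") <- sectors
  attr(out, "min_inplane") <- min_inplane
  out
}

#' Summarize binding-mode counts
#'
#' @param assignments A `mode_assignment` tibble.
#' @param by Optional data frame with `pose_id` plus a grouping column (e.g.
#'   a receptor-model tag) to stratify the counts.
#' @return Tibble of `mode`, `n`, `fraction` (fractions sum to 1 within each
#'   stratum).
#' @export
mode_summary <- function(assignments, by = NULL) {
  if (nrow(assignments) == 0) abort("mode_summary(): empty assignment table")
  tbl <- as_tibble(assignments)
  if (!is.null(by)) {
    tbl <- left_join(tbl, as_tibble(by), by = "pose_id")
    extra <- setdiff(names(as_tibble(by)), "pose_id")
    tbl |>
      count(across(all_of(extra)), .data$mode, name = "n") |>
      group_by(across(all_of(extra))) |>
      mutate(fraction = n / sum(n)) |>
      ungroup()
  } else {
    tbl |>
      count(.data$mode, name = "n") |>
      mutate(fraction = n / sum(n))
  }
}

#' Write mode assignments as TSV
#' @param assignments A `mode_assignment` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- as.data.frame(
    assignments[, c("pose_id", "azimuth", "inplane", "mode", "reason")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
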