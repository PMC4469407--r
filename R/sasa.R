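# Shrake-Rupley solvent-accessible surface area.
#
# Each atom is expanded by the probe radius and sampled with a deterministic
# golden-spiral point set; the accessible fraction is the share of points not
# buried inside any neighbour's expanded sphere. Deterministic by design: no
# random number generation is involved.

# Naccess-like van der Waals radii (Angstrom)
SASA_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.00)
SASA_FALLBACK_RADIUS <- 1.80

#' Quasi-uniform points on the unit sphere (golden spiral)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

element_radius <- function(elem, fallback = SASA_FALLBACK_RADIUS) {
  r <- unname(SASA_RADII[elem])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (is.na(fallback)) {
      abort(sprintf("no van der Waals radius for element(s): %s",
                    paste(unique(elem[unknown]), collapse = ", ")))
    }
    r[unknown] <- fallback
  }
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param atoms Atom tibble with columns `x`, `y`, `z`, `elem` (plus residue
#'   columns for the per-residue summary).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere points per atom; more points, better accuracy.
#' @param fallback_radius Radius used for elements missing from the internal
#'   table; set to `NA` to make unknown elements an error.
#' @return A `sasa_result`: list with `atoms` (per-atom areas), `residues`
#'   (per-residue totals), `total` (Angstrom^2), `probe`, `n_points`.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960,
                 fallback_radius = SASA_FALLBACK_RADIUS) {
  xyz <- as_xyz(atoms)
  n <- nrow(xyz)
  if (n == 0) abort("sasa(): no atoms")
  r <- element_radius(atoms$elem, fallback_radius) + probe
  pts <- sphere_points(n_points)
  d2 <- as.matrix(dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
            (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj > r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  per_atom <- as_tibble(atoms) |>
    mutate(area = area)
  residues <- per_atom |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(area = sum(.data$area), .groups = "drop")
  structure(
    list(atoms = per_atom, residues = residues, total = sum(area),
         probe = probe, n_points = n_points),
    class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms | total %.1f A^2 | probe %.2f A | %d points\n",
              nrow(x$atoms), x$total, x$probe, x$n_points))
  invisible(x)
}

#' Write a per-atom SASA report as TSV
#' @param result A `sasa_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sasa <- function(result, path) {
  out <- result$atoms |>
    select("serial", "name", "resname", "chain", "resno", "area")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
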