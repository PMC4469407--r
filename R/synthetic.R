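# Synthetic fixtures with the statistical structure the analysis assumes:
# an ideal alpha-helical peptide, a toy 7-helix transmembrane bundle with
# Ballesteros-Weinstein annotations, and rigid pose ensembles with planted
# clusters, two rotational modes, a depth continuum, membrane-violating
# decoys, and a noisy score that favours mode-consistent deep poses.
#
# Side chains are truncated at Cbeta: the pipeline needs Calpha geometry
# (RMSD, depth, azimuth) and any-atom contacts, not rotamers.

#' Build an ideal alpha-helix Calpha/Cbeta trace
#'
#' Places Calpha atoms on an ideal alpha-helix (radius 2.3 A, rise 1.5
#' A/residue, twist 100 degrees/residue) with the helix axis along z starting
#' at z = 0, plus a radially displaced Cbeta placeholder for non-glycine
#' residues.
#'
#' @param sequence One-letter amino-acid string (length >= 4) or vector of
#'   one-letter codes.
#' @param start_resno Residue number of the first residue.
#' @param rise Axial rise per residue, Angstrom.
#' @param twist Helical twist per residue, degrees.
#' @param radius Calpha helix radius, Angstrom.
#' @param chain Chain identifier.
#' @return A structure tibble.
#' @export
build_ideal_helix <- function(sequence, start_resno = 1, rise = 1.5,
                              twist = 100, radius = 2.3, chain = "P") {
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  n <- length(sequence)
  if (n == 0) abort("build_ideal_helix(): empty sequence")
  if (n < 4) abort("build_ideal_helix(): need at least 4 residues")
  resname <- unname(one_to_three[toupper(sequence)])
  if (any(is.na(resname))) {
    abort(sprintf("unknown residue code(s): %s",
                  paste(sequence[is.na(resname)], collapse = ", ")))
  }
  i <- seq_len(n) - 1
  theta <- deg2rad(i * twist)
  resno <- start_resno + i
  ca <- tibble(name = "CA", elem = "C", resname = resname, chain = chain,
               resno = resno,
               x = radius * cos(theta), y = radius * sin(theta), z = i * rise)
  cb <- ca |>
    filter(.data$resname != "GLY") |>
    mutate(name = "CB",
           x = (radius + 1.53) * cos(theta[.data$resno - start_resno + 1]),
           y = (radius + 1.53) * sin(theta[.data$resno - start_resno + 1]))
  at <- bind_rows(ca, cb) |>
    arrange(.data$resno, match(.data$name, c("CA", "CB"))) |>
    mutate(serial = row_number())
  new_atoms(at)
}

#' Default 18-mer peptide fragment
#'
#' The C-terminal fragment of orexin-A (residues 16-33,
#' `LYELLHGAGNHAAGILTL`) built as a straight ideal helix — the active
#' fragment whose C-terminus reaches deep into the receptor cavity.
#'
#' @return A structure tibble with residues numbered 16..33.
#' @export
default_peptide <- function() {
  build_ideal_helix("LYELLHGAGNHAAGILTL", start_resno = 16)
}

#' Build a toy 7-helix transmembrane bundle with BW annotations
#'
#' Ideal poly-alanine helices stand vertically on a circle of radius
#' `bundle_radius` around the z-axis. Residues are numbered so that
#' Ballesteros-Weinstein label `x.yy` maps to residue `yy - 30` of chain
#' `LETTERS[x]`; each helix is shifted vertically so that its zero-plane
#' anchor residue (5.46, 6.48 or 7.43 for helices 5-7, the generic
#' mid-membrane residue otherwise) sits at z = 0, placing the zero-plane at
#' z = 0 by construction with the extracellular mouth toward +z. The
#' ground-truth bundle axis and center are stored in attributes `axis` and
#' `center`.
#'
#' @param n_helices Number of helices (>= 3).
#' @param bundle_radius Circle radius, Angstrom.
#' @param helix_length Residues per helix.
#' @return List with `structure` (atom tibble) and `bw_map` (annotation
#'   tibble).
#' @export
build_toy_receptor <- function(n_helices = 7, bundle_radius = 12,
                               helix_length = 30) {
  if (n_helices < 3) abort("build_toy_receptor(): need >= 3 helices")
  if (bundle_radius < 6) abort("build_toy_receptor(): degenerate bundle radius")
  bw_to_resno <- function(yy) yy - 30
  anchors <- rep(bw_to_resno(48), n_helices)     # generic mid-membrane anchor
  inward <- anchors                              # residue facing the cavity
  if (n_helices >= 7) {
    anchors[5] <- bw_to_resno(46)
    anchors[6] <- bw_to_resno(48)
    anchors[7] <- bw_to_resno(43)
    inward[5] <- bw_to_resno(39)                 # TM5 mode reference 5.39
    inward[7] <- bw_to_resno(35)                 # TM7 mode reference 7.35
  }
  helices <- lapply(seq_len(n_helices), function(h) {
    ang <- 2 * pi * (h - 1) / n_helices
    hx <- build_ideal_helix(strrep("A", helix_length), start_resno = 1,
                            chain = LETTERS[h])
    # phase the helix about its own axis so the pocket-facing residue points
    # at the bundle center, as binding-site residues do in a real bundle
    phase <- rad2deg(ang) + 180 - 100 * (inward[h] - 1)
    xy <- as.matrix(hx[, c("x", "y")]) %*% t(rot_z(phase)[1:2, 1:2])
    hx$x <- xy[, 1]; hx$y <- xy[, 2]
    # helices alternate direction through the membrane (odd TMs run
    # extracellular -> intracellular), and the anchor residue sits at z = 0
    dir <- if (h %% 2 == 1) -1 else 1
    hx |>
      mutate(x = .data$x + bundle_radius * cos(ang),
             y = .data$y + bundle_radius * sin(ang),
             z = dir * (.data$resno - anchors[h]) * 1.5)
  })
  at <- bind_rows(helices) |> mutate(serial = row_number())
  labels <- c(paste0(seq_len(min(n_helices, 7)), ".50"),
              if (n_helices >= 7) c("5.46", "6.48", "7.43", "5.39", "7.35"))
  bw_map <- tibble(bw_label = labels) |>
    mutate(helix = as.integer(sub("\\..*", "", .data$bw_label)),
           pos = as.integer(sub(".*\\.", "", .data$bw_label)),
           chain = LETTERS[.data$helix],
           resnum = bw_to_resno(.data$pos),
           resname = "ALA") |>
    select("bw_label", "chain", "resnum", "resname")
  out <- list(structure = new_atoms(at), bw_map = bw_map)
  attr(out, "axis") <- c(0, 0, 1)
  attr(out, "center") <- c(0, 0, 0)
  out
}

#' Configuration for the synthetic pose-ensemble generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' roughly a thousand rigid poses of an 18-residue helical peptide inside a
#' 7-helix cavity, organised in a handful of positional clusters, with two
#' rotational modes about 100 degrees apart (the mode azimuths default to the
#' receptor's own TM5/TM7 reference directions), a continuum of binding
#' depths around 6 A, a tenth of membrane-violating decoys, and a noisy
#' score (lower = better) favouring mode-consistent poses at target depth.
#'
#' @param seed Integer seed; identical configs generate bit-identical
#'   ensembles.
#' @param n_poses Number of poses.
#' @param cluster_centers Optional tibble with columns `dx`, `dy` (in-plane
#'   offset from the bundle axis, A), optional `depth` and `azimuth`
#'   (degrees; `NA` entries are sampled per pose) and optional `weight`.
#'   Default: five centers on a pentagon of radius 4 A with sampled depth and
#'   azimuth.
#' @param cluster_spread Root-mean-square positional jitter magnitude, A.
#' @param mode_azimuths Length-2 named vector of mode centers (degrees);
#'   `NULL` (default) derives them from the receptor's TM5/TM7 reference
#'   residues.
#' @param mode_weights Mixture weights of the two modes (sum to 1).
#' @param angular_sd Wrapped-normal angular noise sd, degrees.
#' @param depth_mean,depth_sd Depth distribution of the C-terminal anchor, A.
#' @param decoy_fraction Fraction of membrane-violating decoy poses.
#' @param score_base_mean,score_base_sd Gaussian score noise.
#' @param score_bonus Score improvement (subtracted) for mode-consistent
#'   poses with depth inside `depth_band`.
#' @param depth_band Depth band rewarded by the score bonus, A.
#' @param tilt_sd Sd of random tilt away from the membrane normal, degrees.
#' @param cavity_radius,slab Cavity geometry used to place decoys just
#'   outside the cavity within the membrane slab.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 42, n_poses = 1000,
                             cluster_centers = NULL, cluster_spread = 1.0,
                             mode_azimuths = NULL,
                             mode_weights = c(0.6, 0.4), angular_sd = 15,
                             depth_mean = 6, depth_sd = 2,
                             decoy_fraction = 0.1,
                             score_base_mean = -4, score_base_sd = 3,
                             score_bonus = 6, depth_band = c(4, 9),
                             tilt_sd = 0, cavity_radius = 13,
                             slab = c(-15, 15)) {
  if (abs(sum(mode_weights) - 1) > 1e-8) {
    abort("generator_config(): mode_weights must sum to 1")
  }
  if (cluster_spread < 0) abort("generator_config(): cluster_spread < 0")
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    abort("generator_config(): decoy_fraction must be in [0, 1)")
  }
  if (is.null(cluster_centers)) {
    ang <- 2 * pi * (0:4) / 5
    cluster_centers <- tibble(dx = 4 * cos(ang), dy = 4 * sin(ang),
                              depth = NA_real_, azimuth = NA_real_,
                              weight = 0.2)
  }
  cluster_centers <- as_tibble(cluster_centers)
  if (!all(c("dx", "dy") %in% names(cluster_centers))) {
    abort("cluster_centers needs dx and dy columns")
  }
  if (!"depth" %in% names(cluster_centers)) cluster_centers$depth <- NA_real_
  if (!"azimuth" %in% names(cluster_centers)) {
    cluster_centers$azimuth <- NA_real_
  }
  if (!"weight" %in% names(cluster_centers)) {
    cluster_centers$weight <- 1 / nrow(cluster_centers)
  }
  if (abs(sum(cluster_centers$weight) - 1) > 1e-8) {
    abort("generator_config(): cluster weights must sum to 1")
  }
  structure(
    list(seed = seed, n_poses = n_poses, cluster_centers = cluster_centers,
         cluster_spread = cluster_spread, mode_azimuths = mode_azimuths,
         mode_weights = mode_weights, angular_sd = angular_sd,
         depth_mean = depth_mean, depth_sd = depth_sd,
         decoy_fraction = decoy_fraction,
         score_base_mean = score_base_mean, score_base_sd = score_base_sd,
         score_bonus = score_bonus, depth_band = depth_band,
         tilt_sd = tilt_sd, cavity_radius = cavity_radius, slab = slab),
    class = "generator_config")
}

# rotate row coords about an in-plane axis by tilt degrees (tilt away from z)
tilt_matrix <- function(tilt_deg, axis_angle_deg) {
  t <- deg2rad(tilt_deg); a <- deg2rad(axis_angle_deg)
  u <- c(cos(a), sin(a), 0)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

#' Generate a synthetic docked-pose ensemble
#'
#' Places rigid copies of the peptide helix in the receptor cavity according
#' to `config`: cluster center (or decoy placement outside the cavity), plus
#' isotropic positional jitter, a mode azimuth from the two-component
#' wrapped-normal mixture, a sampled binding depth, and an optional small
#' tilt. Scores are Gaussian noise minus a bonus for mode-consistent poses at
#' target depth. The planted cluster, mode, azimuth, depth and decoy flag of
#' every pose are returned as ground truth.
#'
#' @param config A `generator_config`.
#' @param receptor Output of [build_toy_receptor()] (or a list with
#'   `structure` and `bw_map`); built fresh when `NULL`.
#' @param peptide Peptide structure tibble; [default_peptide()] when `NULL`.
#' @return List with `ensemble` (scored `pose_ensemble`), `scores` tibble,
#'   `ground_truth` tibble, `frame` (the receptor's `membrane_frame`),
#'   `receptor`, and `config`.
#' @export
generate_ensemble <- function(config, receptor = NULL, peptide = NULL) {
  stopifnot(inherits(config, "generator_config"))
  receptor <- receptor %||% build_toy_receptor()
  peptide <- peptide %||% default_peptide()
  frame <- build_membrane_frame(receptor$structure, receptor$bw_map)
  mode_az <- config$mode_azimuths %||% c(
    TM5 = residue_azimuth(receptor$structure, frame, receptor$bw_map, "5.39"),
    TM7 = residue_azimuth(receptor$structure, frame, receptor$bw_map, "7.35"))
  if (is.null(names(mode_az))) names(mode_az) <- c("TM5", "TM7")

  # template in frame coordinates: C-terminus at the bottom (z = 0), helix
  # axis along +z, so the anchor Calpha depth equals the translation depth
  tmpl <- peptide
  T0 <- as_xyz(tmpl)
  T0[, 3] <- max(T0[, 3]) - T0[, 3]          # flip: last residue lowest
  T0[, 2] <- -T0[, 2]                        # keep handedness under the flip
  ca_last <- which(tmpl$resno == max(tmpl$resno) & tmpl$name == "CA")[1]
  T0 <- sweep(T0, 2, c(T0[ca_last, 1], T0[ca_last, 2], 0))  # anchor at origin
  # reference azimuth of the template's Ala28 -> His26 vector (frame xy)
  i_head <- which(tmpl$resno == 26 & tmpl$name == "CA")[1]
  i_tail <- which(tmpl$resno == 28 & tmpl$name == "CA")[1]
  az_ref <- if (!is.na(i_head) && !is.na(i_tail)) {
    v <- T0[i_head, ] - T0[i_tail, ]
    wrap_deg(rad2deg(atan2(v[2], v[1])))
  } else 0

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_poses
  width <- max(4, nchar(n))
  ids <- sprintf(paste0("pose_%0", width, "d"), seq_len(n))
  n_decoy <- round(config$decoy_fraction * n)
  decoy <- rep(FALSE, n)
  if (n_decoy > 0) decoy[sample.int(n, n_decoy)] <- TRUE

  cc <- config$cluster_centers
  k <- sample.int(nrow(cc), n, replace = TRUE, prob = cc$weight)
  mode_idx <- sample.int(2, n, replace = TRUE, prob = config$mode_weights)
  mode_lab <- names(mode_az)[mode_idx]
  az_noise <- rnorm(n, 0, config$angular_sd)
  az <- wrap_deg(unname(mode_az[mode_idx]) + az_noise)
  fixed_az <- !is.na(cc$azimuth[k])
  az[fixed_az] <- wrap_deg(cc$azimuth[k][fixed_az] +
                             az_noise[fixed_az] * (config$angular_sd > 0))
  mode_lab[fixed_az] <- NA_character_
  depth <- rnorm(n, config$depth_mean, config$depth_sd)
  fixed_d <- !is.na(cc$depth[k])
  depth[fixed_d] <- cc$depth[k][fixed_d]
  jit <- matrix(rnorm(3 * n, 0, config$cluster_spread / sqrt(3)), n, 3)
  px <- cc$dx[k] + jit[, 1]
  py <- cc$dy[k] + jit[, 2]
  pz_extra <- jit[, 3]
  tilt <- if (config$tilt_sd > 0) abs(rnorm(n, 0, config$tilt_sd)) else
    rep(0, n)
  tilt_dir <- runif(n, 0, 360)

  # decoys: outside the cavity, inside the membrane slab
  dec_r <- config$cavity_radius + runif(n, 2, 6)
  dec_ang <- runif(n, 0, 2 * pi)
  dec_z <- runif(n, config$slab[1] + 3, config$slab[2] - 10)
  px[decoy] <- (dec_r * cos(dec_ang))[decoy]
  py[decoy] <- (dec_r * sin(dec_ang))[decoy]
  depth[decoy] <- dec_z[decoy]
  pz_extra[decoy] <- 0
  mode_lab[decoy] <- NA_character_
  az[decoy] <- runif(n, 0, 360)[decoy]
  k_out <- ifelse(decoy, NA_integer_, k)

  n_atoms <- nrow(tmpl)
  xyz <- matrix(0, n, 3 * n_atoms)
  for (i in seq_len(n)) {
    X <- T0 %*% t(rot_z(az[i] - az_ref))
    if (tilt[i] > 0) X <- X %*% t(tilt_matrix(tilt[i], tilt_dir[i]))
    X <- sweep(X, 2, c(px[i], py[i], depth[i] + pz_extra[i]), "+")
    xyz[i, ] <- as.vector(t(frame_to_world(frame, X)))
  }

  # realized depth after jitter/tilt (anchor Calpha z in the frame)
  depth_real <- depth + pz_extra
  consistent <- !decoy & !is.na(mode_lab) &
    abs(ang_diff(az, unname(mode_az[mode_idx]))) <= 30 &
    depth_real >= config$depth_band[1] & depth_real <= config$depth_band[2]
  score <- rnorm(n, config$score_base_mean, config$score_base_sd) -
    config$score_bonus * consistent

  ensemble <- new_pose_ensemble(
    receptor$structure, template_from_atoms(tmpl), xyz,
    tibble(pose_id = ids, score = score),
    range(tmpl$resno))
  scores <- tibble(pose_id = ids, score = score)
  ground_truth <- tibble(
    pose_id = ids, decoy = decoy, cluster = k_out, mode = mode_lab,
    azimuth_planted = az, depth_planted = depth_real,
    tilt_planted = tilt, score = score)
  list(ensemble = ensemble, scores = scores, ground_truth = ground_truth,
       frame = frame, receptor = receptor, config = config)
}
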