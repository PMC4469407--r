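# Full-analysis orchestration: filter -> RMSD -> cluster -> score -> MDS ->
# depth/azimuth -> modes -> contacts, with TSV artifacts and a run report.
# Stage order is fixed; stages can be toggled off. Artifacts carry
# '#'-prefixed header lines recording the package version and the parameters
# used (no timestamps, so reruns are byte-identical).

#' Pipeline configuration
#'
#' Collects input locations (paths, or in-memory objects from
#' [generate_ensemble()]) and every stage parameter. Parameters not supplied
#' keep the pipeline defaults.
#'
#' @param receptor Path to a receptor PDB, or a structure tibble.
#' @param poses Path to a multi-model PDB / pose directory, or a
#'   `pose_ensemble`.
#' @param scores Path to a score TSV, or a data frame (`NULL` if the
#'   ensemble is already scored).
#' @param bw_map Path to a BW-annotation TSV, or a tibble.
#' @param outdir Output directory for artifacts.
#' @param interface_cutoff,c_term_range Interface-filter parameters.
#' @param slab,cavity_radius Membrane-filter parameters.
#' @param score_threshold Threshold for the top-ranking selection (`<=`).
#' @param top_fractions Fractions for cluster-occupancy tables.
#' @param cluster_cutoff Neighbour cutoff of the clustering, Angstrom.
#' @param mds_seed,mds_max_iter Embedding parameters.
#' @param sector_half_width,min_inplane Mode-classification parameters.
#' @param contact_cutoff Contact distance, Angstrom.
#' @param contact_residues Receptor residue set for contact maps (BW labels
#'   or data frame); `NULL` skips contact mapping.
#' @param stages Character vector of stages to run, a subset of the default.
#' @return A `run_config` list.
#' @export
poseatlas_config <- function(receptor, poses, scores = NULL, bw_map = NULL,
                             outdir = tempfile("poseatlas_run_"),
                             interface_cutoff = 5.0, c_term_range = NULL,
                             slab = c(-15, 15), cavity_radius = 13,
                             score_threshold = -8, top_fractions = c(0.05, 0.1),
                             cluster_cutoff = 3.0,
                             mds_seed = 1337, mds_max_iter = 500,
                             sector_half_width = 50, min_inplane = 1.0,
                             contact_cutoff = 4.0, contact_residues = NULL,
                             stages = c("filter", "cluster", "embed",
                                        "geometry", "modes", "contacts")) {
  structure(
    list(receptor = receptor, poses = poses, scores = scores,
         bw_map = bw_map, outdir = outdir,
         interface_cutoff = interface_cutoff, c_term_range = c_term_range,
         slab = slab, cavity_radius = cavity_radius,
         score_threshold = score_threshold, top_fractions = top_fractions,
         cluster_cutoff = cluster_cutoff, mds_seed = mds_seed,
         mds_max_iter = mds_max_iter,
         sector_half_width = sector_half_width, min_inplane = min_inplane,
         contact_cutoff = contact_cutoff, contact_residues = contact_residues,
         stages = stages),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [poseatlas_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(poseatlas_config, cfg)
}

load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

artifact_header <- function(stage, params) {
  flat <- unlist(params)
  c(sprintf("# poseatlas %s | stage: %s",
            as.character(utils::packageVersion("poseatlas")), stage),
    sprintf("# %s", paste(names(flat), flat, sep = "=", collapse = " ")))
}

write_artifact <- function(writer, obj, path, stage, params) {
  tmp <- tempfile()
  writer(obj, tmp)
  writeLines(c(artifact_header(stage, params), readLines(tmp)), path)
  unlink(tmp)
  invisible(path)
}

#' Run the full pose-analysis pipeline
#'
#' Executes the enabled stages in fixed order on one pose ensemble:
#' admissibility filters, RMSD matrix + clustering + cluster scoring +
#' score-ANOVA + top-fraction occupancy, 2D embedding, depth/azimuth
#' geometry, binding-mode classification, and contact-frequency mapping of
#' the top-ranking poses. Artifacts (`filters.tsv`, `clusters.tsv`,
#' `embedding.tsv`, `assignments.tsv`, `contact_freq_top.tsv`,
#' `report.json`) are written under `config$outdir`; reruns on the same
#' inputs are byte-identical.
#'
#' @param config A `run_config` from [poseatlas_config()].
#' @return A `run_report` list: per-stage counts and parameters plus a
#'   summary block, invisibly also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  receptor <- load_input(config$receptor, read_structure)
  bw_map <- load_input(config$bw_map, read_bw_map)
  ensemble <- if (inherits(config$poses, "pose_ensemble")) config$poses
    else read_pose_ensemble(config$poses, receptor)
  if (!is.null(config$scores)) {
    ensemble <- attach_scores(ensemble, load_input(config$scores,
                                                   read_score_table))
  }
  frame <- build_membrane_frame(receptor, bw_map)
  report <- list(parameters = config[!(names(config) %in%
                                         c("receptor", "poses", "scores",
                                           "bw_map", "outdir"))],
                 stages = list())
  n_in <- n_poses(ensemble)
  working <- ensemble

  if ("filter" %in% config$stages) {
    fi <- interface_filter(working, c_term_range = config$c_term_range,
                           cutoff = config$interface_cutoff)
    fm <- membrane_filter(working, frame, slab = config$slab,
                          cavity_radius = config$cavity_radius)
    combined <- combine_filters(fi, fm, ensemble = working)
    write_artifact(write_filter_report, combined,
                   file.path(config$outdir, "filters.tsv"), "filter",
                   list(interface_cutoff = config$interface_cutoff,
                        slab = config$slab,
                        cavity_radius = config$cavity_radius))
    report$stages$filter <- list(
      n_in = n_in, n_pass = sum(combined$verdicts$pass),
      n_fail = sum(!combined$verdicts$pass),
      fail_interface = sum(!fi$verdicts$pass),
      fail_membrane = sum(!fm$verdicts$pass))
    working <- passing_poses(combined)
  }

  clusters <- NULL
  if ("cluster" %in% config$stages) {
    D <- rmsd_matrix(working)
    clusters <- daura_cluster(D, cutoff = config$cluster_cutoff)
    clusters <- cluster_scores(clusters, working)
    anova_tbl <- tryCatch(cluster_score_anova(clusters, working),
                          error = function(e) NULL)
    occ <- lapply(config$top_fractions, function(f) {
      cluster_occupancy(clusters, top_fraction(working, f))
    })
    write_artifact(write_clusters, clusters,
                   file.path(config$outdir, "clusters.tsv"), "cluster",
                   list(cutoff = config$cluster_cutoff))
    report$stages$cluster <- list(
      n_poses = n_poses(working), n_clusters = nrow(clusters$clusters),
      best_median = min(clusters$clusters$median_score, na.rm = TRUE),
      anova_F = if (!is.null(anova_tbl)) anova_tbl$statistic else NA,
      anova_p = if (!is.null(anova_tbl)) anova_tbl$p.value else NA,
      top_fraction_occupancy = setNames(
        lapply(occ, function(o) o$count), config$top_fractions))
  }

  if ("embed" %in% config$stages) {
    D <- rmsd_matrix(working)
    emb <- mds_embed(D, seed = config$mds_seed,
                     max_iter = config$mds_max_iter)
    write_artifact(write_embedding, emb,
                   file.path(config$outdir, "embedding.tsv"), "embed",
                   list(seed = config$mds_seed))
    report$stages$embed <- list(stress = attr(emb, "stress"),
                                iterations = attr(emb, "iterations"))
  }

  geo <- NULL
  if ("geometry" %in% config$stages || "modes" %in% config$stages) {
    depths <- binding_depth(working, frame)
    report$stages$geometry <- c(list(n_poses = nrow(depths)),
                                as.list(summarize_depths(depths)))
    geo <- depths
  }

  assignments <- NULL
  if ("modes" %in% config$stages) {
    sectors <- default_mode_sectors(receptor, frame, bw_map,
                                    half_width = config$sector_half_width)
    assignments <- assign_modes(working, frame, sectors,
                                min_inplane = config$min_inplane)
    assignments <- left_join(assignments, geo, by = "pose_id")
    write_artifact(write_assignments, assignments,
                   file.path(config$outdir, "assignments.tsv"), "modes",
                   list(half_width = config$sector_half_width,
                        min_inplane = config$min_inplane))
    ms <- mode_summary(assignments)
    report$stages$modes <- setNames(as.list(ms$n), ms$mode)
  }

  if ("contacts" %in% config$stages && !is.null(config$contact_residues)) {
    top <- score_filter(working, config$score_threshold)
    freq <- contact_frequency(top, config$contact_residues,
                              cutoff = config$contact_cutoff,
                              bw_map = bw_map)
    write_artifact(write_contact_map, freq,
                   file.path(config$outdir, "contact_freq_top.tsv"),
                   "contacts",
                   list(cutoff = config$contact_cutoff,
                        score_threshold = config$score_threshold))
    report$stages$contacts <- list(n_top = n_poses(top),
                                   n_pairs = nrow(freq),
                                   max_frequency = max(freq$value))
  }

  report$summary <- list(
    n_poses_in = n_in,
    n_poses_analyzed = n_poses(working),
    n_clusters = if (!is.null(clusters)) nrow(clusters$clusters) else NA,
    best_median_score = if (!is.null(clusters))
      min(clusters$clusters$median_score, na.rm = TRUE) else NA,
    depth_median = if (!is.null(geo)) median(geo$depth) else NA,
    mode_counts = report$stages$modes %||% NA)
  class(report) <- "run_report"
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(report),
                         file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<run_report> %d poses in, %d analyzed | %s clusters | depth median %s A\n",
    s$n_poses_in, s$n_poses_analyzed, s$n_clusters,
    if (is.na(s$depth_median)) "NA" else sprintf("%.1f", s$depth_median)))
  invisible(x)
}
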