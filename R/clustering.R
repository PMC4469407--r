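# Greedy neighbour-count (Daura) clustering of docking poses, cluster scoring
# by median refinement score, and across-cluster score statistics.

new_cluster_set <- function(clusters, membership, cutoff) {
  structure(list(clusters = clusters, membership = membership,
                 cutoff = cutoff),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d poses | cutoff %.2f A\n",
              nrow(x$clusters), nrow(x$membership), x$cutoff))
  invisible(x)
}

#' Greedy neighbour-count clustering of an RMSD matrix
#'
#' Iteratively extracts clusters from the pool of poses: the pose with the
#' most remaining neighbours (pairwise RMSD strictly below `cutoff`) becomes
#' the next cluster's seed, the seed and its neighbours form the cluster and
#' leave the pool, and neighbour counts are recomputed over the remaining
#' pool. The process repeats until the pool is empty, so every pose is
#' assigned and singletons are allowed. Ties in neighbour count are broken by
#' the lowest pose index (input order), deterministically.
#'
#' @param matrix An `rmsd_matrix` (or any symmetric distance matrix with
#'   dimnames).
#' @param cutoff Neighbour cutoff in Angstrom (strict `<`).
#' @return A `cluster_set`: `clusters` tibble (`cluster_id`, `seed_id`,
#'   `size`, `members` list-column), `membership` tibble (`pose_id`,
#'   `cluster_id`), and the cutoff used.
#' @export
daura_cluster <- function(matrix, cutoff = 3.0) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    abort("daura_cluster(): cutoff must be > 0")
  }
  D <- unclass(matrix)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    abort("daura_cluster(): matrix must be symmetric")
  }
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  A <- D < cutoff
  diag(A) <- FALSE
  pool <- seq_len(nrow(D))
  clusters <- list()
  while (length(pool) > 0) {
    counts <- rowSums(A[pool, pool, drop = FALSE])
    seed_local <- which.max(counts)      # first maximum = lowest index
    seed <- pool[seed_local]
    members <- pool[c(seed_local, which(A[seed, pool]))]
    members <- sort(unique(members))
    clusters[[length(clusters) + 1]] <-
      list(seed = seed, members = members)
    pool <- setdiff(pool, members)
  }
  cl_tbl <- tibble(
    cluster_id = seq_along(clusters),
    seed_id = map_chr(clusters, function(c) ids[c$seed]),
    size = map_int(clusters, function(c) length(c$members)),
    median_score = NA_real_,
    members = map(clusters, function(c) ids[c$members])
  )
  membership <- cl_tbl |>
    select("cluster_id", "members") |>
    unnest("members") |>
    rename(pose_id = "members") |>
    select("pose_id", "cluster_id")
  new_cluster_set(cl_tbl, membership, cutoff)
}

#' Score clusters by median pose score
#'
#' Attaches the median refinement score of each cluster's members (even
#' sizes: mean of the two central values) and ranks clusters ascending, best
#' (lowest) median first. Unscored members are excluded from the median with
#' a warning; clusters with no scored member get a missing median and rank
#' last.
#'
#' @param clusters A `cluster_set`.
#' @param ensemble The scored `pose_ensemble` the clusters came from.
#' @return The `cluster_set` with `median_score` and `rank` filled in,
#'   clusters ordered best-first.
#' @export
cluster_scores <- function(clusters, ensemble) {
  scores <- setNames(ensemble$poses$score, ensemble$poses$pose_id)
  n_unscored <- 0
  med <- map_dbl(clusters$clusters$members, function(m) {
    s <- scores[m]
    n_unscored <<- n_unscored + sum(is.na(s))
    if (all(is.na(s))) NA_real_ else median(s, na.rm = TRUE)
  })
  if (n_unscored > 0) {
    warn(sprintf("cluster_scores(): %d unscored member(s) excluded from medians",
                 n_unscored))
  }
  cl <- clusters$clusters
  cl$median_score <- med
  cl <- cl[order(cl$median_score, cl$cluster_id, na.last = TRUE), ]
  cl$rank <- seq_len(nrow(cl))
  clusters$clusters <- cl
  clusters
}

#' One-way ANOVA of pose scores across clusters
#'
#' Tests whether mean refinement scores differ between clusters, using the
#' classical one-way F statistic over per-pose scores grouped by cluster.
#' Clusters with fewer than `min_size` scored members are excluded.
#'
#' @param clusters A `cluster_set`.
#' @param ensemble The scored `pose_ensemble`.
#' @param min_size Minimum scored members for a cluster to enter the test.
#' @return One-row tibble: `statistic` (F), `p.value`, `df_between`,
#'   `df_within`, `n_groups`, `note`.
#' @export
cluster_score_anova <- function(clusters, ensemble, min_size = 2) {
  scores <- setNames(ensemble$poses$score, ensemble$poses$pose_id)
  groups <- map(clusters$clusters$members, function(m) {
    s <- scores[m]
    s[!is.na(s)]
  })
  groups <- groups[lengths(groups) >= min_size]
  if (length(groups) < 2) {
    abort("cluster_score_anova(): need >= 2 clusters of sufficient size")
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ss_within <- sum(unlist(lapply(groups, function(s) sum((s - mean(s))^2))))
  means <- vapply(groups, mean, 0)
  note <- ""
  if (ss_within <= 1e-300) {
    if (max(means) - min(means) > 0) {
      return(tibble(statistic = Inf, p.value = 0,
                    df_between = length(groups) - 1,
                    df_within = length(y) - length(groups),
                    n_groups = length(groups),
                    note = "zero within-group variance, unequal means"))
    }
    abort("cluster_score_anova(): all scores identical; F undefined")
  }
  fit <- oneway.test(y ~ g, var.equal = TRUE)
  tibble(statistic = unname(fit$statistic), p.value = fit$p.value,
         df_between = unname(fit$parameter[1]),
         df_within = unname(fit$parameter[2]),
         n_groups = length(groups), note = note)
}

#' Distribution of a pose subset over clusters
#'
#' Counts, per cluster, how many members of `subset` it holds; fractions are
#' relative to the subset size and sum to 1 over clusters. Used e.g. to see
#' how the top-ranked 5 or 10 percent of poses spread across clusters.
#'
#' @param clusters A `cluster_set`.
#' @param subset A `pose_ensemble` or character vector of pose ids; all ids
#'   must be clustered.
#' @return Tibble with `cluster_id`, `count`, `fraction`.
#' @export
cluster_occupancy <- function(clusters, subset) {
  ids <- if (inherits(subset, "pose_ensemble")) subset$poses$pose_id
         else as.character(subset)
  mem <- clusters$membership
  foreign <- setdiff(ids, mem$pose_id)
  if (length(foreign) > 0) {
    abort(sprintf("cluster_occupancy(): id(s) not clustered: %s",
                  paste(head(foreign, 5), collapse = ", ")))
  }
  hits <- mem[mem$pose_id %in% ids, ]
  counts <- hits |> count(.data$cluster_id, name = "count")
  clusters$clusters |>
    select("cluster_id") |>
    left_join(counts, by = "cluster_id") |>
    mutate(count = coalesce(.data$count, 0L),
           fraction = .data$count / length(ids))
}

#' Write a cluster set as TSV
#' @param clusters A `cluster_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  out <- clusters$clusters |>
    mutate(member_ids = map_chr(.data$members, paste, collapse = ";")) |>
    select("cluster_id", "seed_id", "size", "median_score", "member_ids")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
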