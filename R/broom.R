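# broom-style accessors: tidy() rows per component, glance() one-row model
# summaries.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy.cluster_set
#' @method glance cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters), n_poses = nrow(x$membership),
         cutoff = x$cutoff,
         largest = max(x$clusters$size),
         best_median = if (all(is.na(x$clusters$median_score))) NA_real_
           else min(x$clusters$median_score, na.rm = TRUE))
}

#' Tidy a cluster set
#'
#' `tidy()` returns one row per cluster (`cluster_id`, `seed_id`, `size`,
#' `median_score`, plus `rank` once scored); `glance()` a one-row summary.
#'
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, ...) {
  x$clusters |> select(-"members")
}

#' Tidy a pose embedding
#'
#' `tidy()` returns the `pose_id`/`x`/`y` coordinate tibble; `glance()` the
#' final stress, iteration count and convergence flag.
#'
#' @param x A `pose_embedding`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pose_embedding
#' @export
tidy.pose_embedding <- function(x, ...) {
  out <- as_tibble(unclass(x)[c("pose_id", "x", "y")])
  out
}

#' @rdname tidy.pose_embedding
#' @method glance pose_embedding
#' @export
glance.pose_embedding <- function(x, ...) {
  tibble(stress = attr(x, "stress"), iterations = attr(x, "iterations"),
         converged = attr(x, "converged"), n = nrow(x))
}

#' Tidy a filter report
#'
#' `tidy()` returns the per-pose verdict table; `glance()` pass/fail counts.
#'
#' @param x A `filter_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) x$verdicts

#' @rdname tidy.filter_report
#' @method glance filter_report
#' @export
glance.filter_report <- function(x, ...) {
  tibble(rule = x$rule, n = nrow(x$verdicts), n_pass = sum(x$verdicts$pass),
         n_fail = sum(!x$verdicts$pass))
}
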