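# Metric multidimensional scaling of pose RMSD matrices into 2D.
#
# SMACOF stress majorization from a classical-scaling (Torgerson) start:
# deterministic given the seed, with monotonically non-increasing Kruskal
# stress-1 across iterations.

#' Embed an RMSD matrix in two dimensions (metric MDS)
#'
#' Minimizes Kruskal stress-1,
#' `sqrt(sum((d_ij - dhat_ij)^2) / sum(d_ij^2))` over unordered pairs, by
#' iterative majorization (Guttman transform), initialized from classical
#' scaling. The result is deterministic given `seed` (randomness is used only
#' to break a fully degenerate start).
#'
#' @param matrix An `rmsd_matrix` or symmetric distance matrix (>= 3 poses).
#' @param seed Integer seed controlling any stochastic fallback.
#' @param max_iter Maximum majorization iterations.
#' @param tol Relative stress-decrease tolerance for convergence.
#' @param ndim Embedding dimension (default 2).
#' @return A `pose_embedding`: tibble (`pose_id`, `x`, `y`) with attributes
#'   `stress`, `iterations`, `converged`, `seed`, `stress_trace`.
#' @export
mds_embed <- function(matrix, seed = 1337, max_iter = 500, tol = 1e-7,
                      ndim = 2) {
  D <- unclass(matrix)
  if (nrow(D) < 3) abort("mds_embed(): need at least 3 poses")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    abort("mds_embed(): matrix must be symmetric")
  }
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  n <- nrow(D)
  X <- suppressWarnings(cmdscale(D, k = ndim))
  if (ncol(X) < ndim || all(abs(X) < 1e-12)) {
    # degenerate classical start (e.g. all-equal distances in low rank):
    # seed-controlled jitter
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    J <- matrix(rnorm(n * ndim, sd = mean(D) / 10 + 1e-6), n, ndim)
    X <- cbind(X, matrix(0, n, ndim))[, seq_len(ndim), drop = FALSE] + J
  }
  denom <- sum(D[upper.tri(D)]^2)
  stress1 <- function(X) {
    E <- as.matrix(dist(X))
    sqrt(sum((D[upper.tri(D)] - E[upper.tri(E)])^2) / denom)
  }
  s_prev <- stress1(X)
  trace <- s_prev
  iter <- 0
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    E <- as.matrix(dist(X))
    B <- matrix(0, n, n)
    nz <- E > 1e-12
    B[nz] <- -D[nz] / E[nz]
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    s <- stress1(X)
    trace <- c(trace, s)
    if (s_prev - s < tol * max(s_prev, 1e-12)) {
      s_prev <- s
      converged <- TRUE
      break
    }
    s_prev <- s
  }
  out <- tibble(pose_id = ids, x = X[, 1], y = X[, 2])
  class(out) <- c("pose_embedding", class(out))
  attr(out, "stress") <- s_prev
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "seed") <- seed
  attr(out, "stress_trace") <- trace
  out
}

# save/restore .Random.seed so embedding never perturbs the caller's RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Write an embedding as TSV
#' @param embedding A `pose_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  write.table(as.data.frame(embedding[, c("pose_id", "x", "y")]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
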