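#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr unnest pivot_wider
#' @importFrom purrr map map_dbl map_int map_chr map2
#' @importFrom stats median dist cmdscale rnorm runif setNames oneway.test
#' @importFrom utils head read.delim write.table
NULL

# angular helpers: degrees everywhere, results wrapped to [0, 360)
wrap_deg <- function(x) x %% 360

# signed smallest difference a - b in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# rotation about z by theta degrees (acts on row-vector coords: X %*% t(Rz))
rot_z <- function(theta) {
  t <- deg2rad(theta)
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

# coerce an n x 3 numeric matrix from various inputs
as_xyz <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3)
  x
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)
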