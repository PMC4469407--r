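# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_segment
#'   geom_histogram scale_fill_gradient coord_equal labs theme_minimal
#' @importFrom grid arrow unit
#' @export
ggplot2::autoplot

#' Plot a 2D pose landscape
#'
#' Scatter of the MDS embedding, optionally coloured by cluster or any other
#' per-pose label.
#'
#' @param object A `pose_embedding`.
#' @param colour_by Optional data frame with `pose_id` and one extra column
#'   used for colour (e.g. the membership table of a `cluster_set`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pose_embedding
#' @export
autoplot.pose_embedding <- function(object, colour_by = NULL, ...) {
  df <- tidy(object)
  p <- if (!is.null(colour_by)) {
    cb <- as_tibble(colour_by)
    col <- setdiff(names(cb), "pose_id")[1]
    df <- left_join(df, cb, by = "pose_id")
    ggplot(df, aes(.data$x, .data$y,
                   colour = factor(.data[[col]]))) +
      labs(colour = col)
  } else {
    ggplot(df, aes(.data$x, .data$y))
  }
  p + geom_point(alpha = 0.7) + coord_equal() + theme_minimal() +
    labs(x = "MDS-1 (A)", y = "MDS-2 (A)",
         subtitle = sprintf("stress %.3g", attr(object, "stress")))
}

#' Plot a contact map as a heatmap
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot (receptor residues x ligand residues, fill = contact
#'   frequency).
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(receptor_label = factor(.data$receptor_label,
                                   levels = unique(.data$receptor_label)))
  ggplot(df, aes(factor(.data$ligand_resno), .data$receptor_label,
                 fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        limits = c(0, 1), name = "frequency") +
    theme_minimal() +
    labs(x = "peptide residue", y = "receptor residue")
}

#' Compass plot of pose rotational states
#'
#' Draws each pose's in-plane azimuth vector from a common origin, the view
#' used to spot preferred peptide orientations; tilted peptides give shorter
#' arrows.
#'
#' @param assignments A `mode_assignment` tibble.
#' @return A ggplot.
#' @export
plot_pose_compass <- function(assignments) {
  df <- as_tibble(assignments) |> filter(!is.na(.data$azimuth))
  df <- df |>
    mutate(dx = .data$inplane * cos(deg2rad(.data$azimuth)),
           dy = .data$inplane * sin(deg2rad(.data$azimuth)))
  ggplot(df) +
    geom_segment(aes(x = 0, y = 0, xend = .data$dx, yend = .data$dy,
                     colour = .data$mode),
                 arrow = arrow(length = unit(1.5, "mm")), alpha = 0.6) +
    coord_equal() + theme_minimal() +
    labs(x = "x (A)", y = "y (A)", colour = "mode")
}

#' Histogram of binding depths
#'
#' @param depths Tibble from [binding_depth()].
#' @param binwidth Bin width in Angstrom.
#' @return A ggplot.
#' @export
plot_depth_distribution <- function(depths, binwidth = 0.5) {
  ggplot(as_tibble(depths), aes(.data$depth)) +
    geom_histogram(binwidth = binwidth, fill = "steelblue",
                   colour = "white") +
    theme_minimal() +
    labs(x = "binding depth (A above zero-plane)", y = "poses")
}
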