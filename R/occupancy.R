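# Grid-based spanned area. The enclosure is divided into an n x n grid of
# square cells (default 24 x 24); a cell is visited if any sample of any
# worker falls in it, and the spanned area is the visited-cell count times
# the cell area. By default the cell length tiles the enclosure exactly
# (enclosure_mm / n); a fixed cell length (e.g. 10.6 mm, matching the
# interaction area pi * 6^2 ~ 10.6^2) can be forced, in which case the grid
# may extend past the far wall and the outermost cells are partly outside.

cell_index <- function(coord, cell_length, n_cells_side) {
  pmin(pmax(floor(coord / cell_length), 0), n_cells_side - 1) + 1L
}

occupancy_counts <- function(trajectories, colonies, n_cells_side, cell_length) {
  meta <- select(colonies, "colony_id", "enclosure_mm")
  trajectories %>%
    left_join(meta, by = "colony_id") %>%
    mutate(cell_length_mm = cell_length %||%
             (.data$enclosure_mm / n_cells_side),
           col = cell_index(.data$x_mm, .data$cell_length_mm, n_cells_side),
           row = cell_index(.data$y_mm, .data$cell_length_mm, n_cells_side)) %>%
    count(.data$colony_id, .data$cell_length_mm, .data$row, .data$col,
          name = "n_samples")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spanned area on an occupancy grid
#'
#' @param trajectories Trajectory tibble (`colony_id, worker_id, t_s, x_mm,
#'   y_mm`). All samples contribute, active and inactive workers alike.
#' @param colonies Colony metadata, as from [read_colonies()].
#' @param n_cells_side Cells per side of the square grid (default 24).
#' @param cell_length Cell side length in mm, or `NULL` (default) for
#'   `enclosure_mm / n_cells_side`. Points on a cell boundary belong to the
#'   higher-index cell; the far enclosure edge belongs to the last cell.
#' @return A tibble `colony_id, n_cells_visited, cell_length_mm, area_mm2`.
#' @export
spanned_area <- function(trajectories, colonies, n_cells_side = 24,
                         cell_length = NULL) {
  if (nrow(trajectories) == 0) abort("no trajectories supplied")
  if (n_cells_side < 1) abort("n_cells_side must be at least 1")
  occupancy_counts(trajectories, colonies, n_cells_side, cell_length) %>%
    group_by(.data$colony_id, .data$cell_length_mm) %>%
    summarise(n_cells_visited = n(), .groups = "drop") %>%
    mutate(area_mm2 = .data$n_cells_visited * .data$cell_length_mm^2) %>%
    select("colony_id", "n_cells_visited", "cell_length_mm", "area_mm2")
}

#' Occupancy heat map
#'
#' Per-cell counts of position samples, suitable for a grey-scale occupancy
#' map. All grid cells are returned, including never-visited ones (count 0);
#' the counts sum to the total number of samples.
#'
#' @inheritParams spanned_area
#' @return A tibble `colony_id, row, col, n_samples` with `n_cells_side^2`
#'   rows per colony (rows/cols are 1-based from the bottom-left).
#' @export
occupancy_heatmap <- function(trajectories, colonies, n_cells_side = 24,
                              cell_length = NULL) {
  if (nrow(trajectories) == 0) abort("no trajectories supplied")
  if (n_cells_side < 1) abort("n_cells_side must be at least 1")
  occupancy_counts(trajectories, colonies, n_cells_side, cell_length) %>%
    select("colony_id", "row", "col", "n_samples") %>%
    complete(.data$colony_id,
             row = seq_len(n_cells_side), col = seq_len(n_cells_side),
             fill = list(n_samples = 0L)) %>%
    arrange(.data$colony_id, .data$row, .data$col)
}

#' Plot an occupancy heat map
#'
#' @param heatmap A tibble from [occupancy_heatmap()] (one or more colonies;
#'   facetted if several).
#' @return A ggplot object (grey scale: white = never occupied, black = most
#'   occupied).
#' @export
plot_occupancy <- function(heatmap) {
  p <- ggplot(heatmap, aes(x = .data$col, y = .data$row,
                           fill = .data$n_samples)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "black", name = "samples") +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
  if (length(unique(heatmap$colony_id)) > 1) {
    p <- p + facet_wrap(~colony_id)
  }
  p
}
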