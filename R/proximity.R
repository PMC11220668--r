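# Spatial proximity networks. For each sampled frame, two workers are linked
# if their Euclidean distance is at most d (default 6 mm, about one body
# length); the interaction count E is the time average of the per-frame edge
# count, and the mean degree is <k> = 2E/N with N the colony's tracked count.

#' Proximity pairs in a single frame
#'
#' All unordered worker pairs within distance `d` of each other at one sample
#' time. The comparison is inclusive (`<= d`).
#'
#' @param positions A data frame with columns `worker_id, x_mm, y_mm` holding
#'   one position per worker at a common sample time.
#' @param d Interaction distance in mm (default 6).
#' @return A tibble `worker_a, worker_b, dist_mm` with `worker_a < worker_b`.
#' @export
proximity_pairs <- function(positions, d = 6) {
  if (d <= 0) abort("interaction distance d must be positive")
  if (anyDuplicated(positions$worker_id)) {
    abort("duplicated worker_id within a single frame")
  }
  n <- nrow(positions)
  empty <- tibble(worker_a = character(), worker_b = character(),
                  dist_mm = numeric())
  if (n < 2) return(empty)
  ord <- order(positions$worker_id)
  ids <- as.character(positions$worker_id)[ord]
  dm <- as.matrix(dist(cbind(positions$x_mm, positions$y_mm)[ord, , drop = FALSE]))
  hit <- which(upper.tri(dm) & dm <= d, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  tibble(worker_a = ids[hit[, 1]], worker_b = ids[hit[, 2]],
         dist_mm = dm[hit]) %>%
    arrange(.data$worker_a, .data$worker_b)
}

#' Per-frame edge counts of the proximity network
#'
#' @param trajectories Trajectory tibble (`colony_id, worker_id, t_s, x_mm,
#'   y_mm`). Workers missing from a frame simply contribute no edges there.
#' @param d Interaction distance in mm (default 6).
#' @return A tibble `colony_id, t_s, n_edges` with one row per colony per
#'   sample time present in the data.
#' @export
proximity_edges <- function(trajectories, d = 6) {
  if (nrow(trajectories) == 0) abort("no trajectories supplied")
  if (d <= 0) abort("interaction distance d must be positive")
  trajectories %>%
    group_by(.data$colony_id, .data$t_s) %>%
    summarise(n_edges = count_edges(.data$x_mm, .data$y_mm, d),
              .groups = "drop")
}

count_edges <- function(x, y, d) {
  if (length(x) < 2) return(0L)
  sum(dist(cbind(x, y)) <= d)
}

#' Time-aggregated proximity network
#'
#' Accumulates, per colony, how many frames each worker pair spent within the
#' interaction distance (the weighted contact network of the video).
#'
#' @inheritParams proximity_edges
#' @return A tibble `colony_id, worker_a, worker_b, n_frames` with
#'   `worker_a < worker_b` and `n_frames >= 1`.
#' @export
proximity_network <- function(trajectories, d = 6) {
  if (nrow(trajectories) == 0) abort("no trajectories supplied")
  if (d <= 0) abort("interaction distance d must be positive")
  trajectories %>%
    group_split(.data$colony_id) %>%
    map(function(tr) {
      ids <- sort(unique(as.character(tr$worker_id)))
      k <- length(ids)
      counts <- matrix(0L, k, k, dimnames = list(ids, ids))
      for (fr in split(tr, tr$t_s)) {
        if (nrow(fr) < 2) next
        idx <- match(as.character(fr$worker_id), ids)
        adj <- as.matrix(dist(cbind(fr$x_mm, fr$y_mm))) <= d
        counts[idx, idx] <- counts[idx, idx] + adj
      }
      hit <- which(upper.tri(counts) & counts > 0, arr.ind = TRUE)
      tibble(colony_id = tr$colony_id[1],
             worker_a = ids[hit[, 1]], worker_b = ids[hit[, 2]],
             n_frames = as.integer(counts[hit])) %>%
        arrange(.data$worker_a, .data$worker_b)
    }) %>%
    list_rbind()
}

#' Per-colony interaction summary
#'
#' The interaction count `E` is the arithmetic mean of the per-frame edge
#' counts over all sample times, and the mean degree is `2 E / N` where `N`
#' is the colony's tracked worker count from the metadata (not the number of
#' workers present in any one frame).
#'
#' @inheritParams proximity_edges
#' @param colonies Colony metadata, as from [read_colonies()].
#' @return A tibble `colony_id, n_frames, E, mean_degree`.
#' @export
proximity_summary <- function(trajectories, colonies, d = 6) {
  proximity_edges(trajectories, d = d) %>%
    group_by(.data$colony_id) %>%
    summarise(n_frames = n(), E = mean(.data$n_edges), .groups = "drop") %>%
    left_join(select(colonies, "colony_id", "n_tracked"), by = "colony_id") %>%
    mutate(mean_degree = 2 * .data$E / .data$n_tracked) %>%
    select("colony_id", "n_frames", "E", "mean_degree")
}

#' Export / read a weighted contact network
#'
#' Writes the time-aggregated network as a CSV edge list
#' (`colony_id,worker_a,worker_b,n_frames`); an empty network yields a
#' header-only file. With `format = "graphml"` (requires the igraph package)
#' a GraphML file is written instead, one graph per call, so the network must
#' contain a single colony.
#'
#' @param network A tibble from [proximity_network()].
#' @param path Output file path.
#' @param format `"csv"` (default) or `"graphml"`.
#' @return The network, invisibly.
#' @export
export_network <- function(network, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(network, path)
  } else {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      abort("GraphML export requires the igraph package")
    }
    if (length(unique(network$colony_id)) > 1) {
      abort("GraphML export takes one colony at a time")
    }
    g <- igraph::graph_from_data_frame(
      network[, c("worker_a", "worker_b", "n_frames")], directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(network)
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    colony_id = readr::col_character(),
                    worker_a = readr::col_character(),
                    worker_b = readr::col_character(),
                    n_frames = readr::col_integer()))
}
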