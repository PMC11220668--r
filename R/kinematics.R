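# Per-worker path lengths and speeds, active/inactive classification, and
# per-colony aggregates. A worker counts as active when its average speed over
# the video strictly exceeds the threshold (default 0.1 mm/s, i.e. more than
# 3 mm travelled in 30 s).

#' Path length of a sampled trajectory
#'
#' Sum of Euclidean distances between consecutive position samples, in the
#' units of the coordinates. A single sample has path length 0. No
#' interpolation is performed: the path is measured at the sampling resolution
#' of the tracking (by default every 5th frame, 3 Hz).
#'
#' @param x,y Numeric coordinate vectors of equal length, ordered by time.
#' @return Total distance travelled (mm if coordinates are in mm).
#' @examples
#' path_length(c(0, 3), c(0, 4)) # 5
#' @export
path_length <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) == 0) abort("at least one sample is required")
  if (length(x) == 1) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Per-worker kinematic summaries
#'
#' Computes each tracked worker's path length, mean speed, and activity flag.
#' Fully tracked workers use the colony's nominal video duration; partially
#' tracked workers (fewer samples than `floor(duration * frame_rate /
#' sample_stride)`) are kept, flagged, and use their own observed time span
#' (sample span plus one sampling interval) so that speeds stay comparable.
#'
#' @param trajectories Trajectory tibble (`colony_id, worker_id, t_s, x_mm,
#'   y_mm`), as from [read_trajectories()].
#' @param colonies Colony metadata, as from [read_colonies()].
#' @param speed_threshold Activity threshold in mm/s; a worker is active iff
#'   its mean speed is strictly greater than this. Default 0.1.
#' @return A tibble with one row per worker: `colony_id, worker_id,
#'   n_samples, duration_s, path_length_mm, mean_speed_mm_s, active, partial`.
#' @export
worker_kinematics <- function(trajectories, colonies, speed_threshold = 0.1) {
  if (nrow(trajectories) == 0) abort("no trajectories supplied")
  if (speed_threshold < 0) abort("speed_threshold must be non-negative")
  meta <- colonies %>%
    mutate(n_expected = floor(.data$duration_s * .data$frame_rate /
                                .data$sample_stride),
           dt_s = .data$sample_stride / .data$frame_rate) %>%
    select("colony_id", "duration_s", "n_expected", "dt_s")
  trajectories %>%
    group_by(.data$colony_id, .data$worker_id) %>%
    summarise(n_samples = n(),
              t_span = max(.data$t_s) - min(.data$t_s),
              path_length_mm = path_length(.data$x_mm, .data$y_mm),
              .groups = "drop") %>%
    left_join(meta, by = "colony_id") %>%
    mutate(partial = .data$n_samples < .data$n_expected,
           duration_s = ifelse(.data$partial, .data$t_span + .data$dt_s,
                               .data$duration_s),
           mean_speed_mm_s = .data$path_length_mm / .data$duration_s,
           active = .data$mean_speed_mm_s > speed_threshold) %>%
    select("colony_id", "worker_id", "n_samples", "duration_s",
           "path_length_mm", "mean_speed_mm_s", "active", "partial")
}

#' Per-colony kinematic aggregates
#'
#' Mean and median per-worker path length and the number of active workers
#' (`A`), over tracked workers only.
#'
#' @inheritParams worker_kinematics
#' @return A tibble with one row per colony: `colony_id, L_mm, L_median_mm,
#'   n_active`.
#' @export
colony_kinematics <- function(trajectories, colonies, speed_threshold = 0.1) {
  worker_kinematics(trajectories, colonies, speed_threshold) %>%
    group_by(.data$colony_id) %>%
    summarise(L_mm = mean(.data$path_length_mm),
              L_median_mm = median(.data$path_length_mm),
              n_active = sum(.data$active),
              .groups = "drop")
}
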