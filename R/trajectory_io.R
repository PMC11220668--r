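# Tabular IO for colony metadata, worker trajectories, and per-colony
# summaries. Positions are stored in mm with a bottom-left origin; an optional
# px_per_mm column in the metadata converts pixel coordinates at read time.

colony_required_cols <- c("colony_id", "n_total", "n_tracked", "mass_g",
                          "metabolic_rate_mW")
colony_default_cols <- c(enclosure_mm = 248, duration_s = 30, frame_rate = 15,
                         sample_stride = 5)
summary_cols <- c("colony_id", "n_total", "n_tracked", "L_mm", "L_median_mm",
                  "n_active", "E", "mean_degree", "area_mm2", "a_star",
                  "i_star")

#' Read colony metadata
#'
#' Reads a CSV of per-colony metadata (worker counts, wet mass, metabolic
#' rate, enclosure and video parameters) and validates it. Missing optional
#' columns (`enclosure_mm`, `duration_s`, `frame_rate`, `sample_stride`) are
#' filled with the defaults of the tracking protocol the package assumes:
#' a 248 mm square enclosure filmed for 30 s at 15 frames/s, with positions
#' tagged every 5th frame.
#'
#' @param path Path to a CSV file with header
#'   `colony_id,n_total,n_tracked,mass_g,metabolic_rate_mW,enclosure_mm,duration_s,frame_rate,sample_stride`.
#'   An optional `px_per_mm` column gives a pixel-to-mm conversion applied to
#'   trajectory coordinates read against these records.
#' @return A tibble with one validated row per colony.
#' @seealso [read_trajectories()], [write_colonies()]
#' @export
read_colonies <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_colonies(df)
}

#' Validate a colony metadata table
#'
#' Checks column presence, positivity of all physical quantities,
#' `n_tracked <= n_total`, and uniqueness of `colony_id`; fills defaulted
#' enclosure/video columns. Errors name the offending row.
#'
#' @param df A data frame of colony metadata.
#' @return The validated tibble, with defaults filled in.
#' @export
validate_colonies <- function(df) {
  df <- as_tibble(df)
  missing <- setdiff(colony_required_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("colony metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("colony metadata has no rows")
  for (col in names(colony_default_cols)) {
    if (!col %in% names(df)) df[[col]] <- colony_default_cols[[col]]
  }
  dup <- df$colony_id[duplicated(df$colony_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate colony_id: ", paste(unique(dup), collapse = ", ")))
  }
  pos_cols <- c("n_total", "n_tracked", "mass_g", "metabolic_rate_mW",
                "enclosure_mm", "duration_s", "frame_rate", "sample_stride")
  for (col in pos_cols) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad) > 0) {
      abort(paste0("non-positive or missing `", col, "` in row ", bad[1],
                   " (colony ", df$colony_id[bad[1]], ")"))
    }
  }
  bad <- which(df$n_tracked > df$n_total)
  if (length(bad) > 0) {
    abort(paste0("n_tracked > n_total in row ", bad[1],
                 " (colony ", df$colony_id[bad[1]], ")"))
  }
  df %>%
    mutate(n_total = as.integer(round(.data$n_total)),
           n_tracked = as.integer(round(.data$n_tracked)))
}

#' Read worker trajectories
#'
#' Reads a long CSV of time-stamped worker positions and validates it against
#' colony metadata: every `colony_id` must exist in `colonies`, per-worker
#' time stamps must be distinct (rows are sorted to a canonical
#' colony/worker/time order, so input row order is immaterial), and positions
#' must lie inside the enclosure. If the metadata carries a `px_per_mm`
#' column, coordinates are divided by it on read.
#'
#' @param path Path to a CSV with header `colony_id,worker_id,t_s,x_mm,y_mm`.
#' @param colonies Colony metadata as returned by [read_colonies()].
#' @param mode `"strict"` (default) rejects out-of-bounds positions with an
#'   error; `"lenient"` clips them to the enclosure with a warning.
#' @return A tibble `colony_id, worker_id, t_s, x_mm, y_mm` sorted by colony,
#'   worker and time.
#' @export
read_trajectories <- function(path, colonies, mode = c("strict", "lenient")) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_trajectories(df, colonies, mode = mode)
}

#' Validate a trajectory table
#'
#' @inheritParams read_trajectories
#' @param df A data frame with columns `colony_id,worker_id,t_s,x_mm,y_mm`.
#' @return The validated, canonically sorted tibble.
#' @export
validate_trajectories <- function(df, colonies, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  df <- as_tibble(df)
  needed <- c("colony_id", "worker_id", "t_s", "x_mm", "y_mm")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("trajectory table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  orphan <- setdiff(unique(df$colony_id), colonies$colony_id)
  if (length(orphan) > 0) {
    abort(paste0("trajectories reference unknown colony_id: ",
                 paste(orphan, collapse = ", ")))
  }
  meta <- colonies %>% select("colony_id", "enclosure_mm",
                              dplyr::any_of("px_per_mm"))
  df <- df %>% left_join(meta, by = "colony_id")
  if ("px_per_mm" %in% names(df)) {
    scale <- ifelse(is.na(df$px_per_mm), 1, df$px_per_mm)
    df$x_mm <- df$x_mm / scale
    df$y_mm <- df$y_mm / scale
    df$px_per_mm <- NULL
  }
  oob <- df$x_mm < 0 | df$x_mm > df$enclosure_mm |
    df$y_mm < 0 | df$y_mm > df$enclosure_mm
  if (any(oob)) {
    if (mode == "strict") {
      i <- which(oob)[1]
      abort(paste0("position outside the enclosure for worker ",
                   df$worker_id[i], " (colony ", df$colony_id[i], ") at t = ",
                   df$t_s[i], " s; use mode = \"lenient\" to clip"))
    }
    warn(paste0("clipped ", sum(oob), " out-of-bounds position(s) to the enclosure"))
    df <- df %>%
      mutate(x_mm = pmin(pmax(.data$x_mm, 0), .data$enclosure_mm),
             y_mm = pmin(pmax(.data$y_mm, 0), .data$enclosure_mm))
  }
  df <- df %>%
    select(-"enclosure_mm") %>%
    arrange(.data$colony_id, .data$worker_id, .data$t_s)
  dup <- df %>%
    group_by(.data$colony_id, .data$worker_id) %>%
    filter(duplicated(.data$t_s)) %>%
    ungroup()
  if (nrow(dup) > 0) {
    abort(paste0("non-monotone (duplicated) time stamps for worker ",
                 dup$worker_id[1], " (colony ", dup$colony_id[1], ")"))
  }
  df
}

#' Write colony metadata, trajectories, or summaries
#'
#' Plain CSV writers matching the package's table schemas; each round-trips
#' losslessly through its reader.
#'
#' @param colonies,trajectories,summaries Tibbles as produced by the
#'   corresponding readers or by [summarize_colonies()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @name io_writers
NULL

#' @rdname io_writers
#' @export
write_colonies <- function(colonies, path) {
  readr::write_csv(colonies, path)
  invisible(colonies)
}

#' @rdname io_writers
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(trajectories, path)
  invisible(trajectories)
}

#' @rdname io_writers
#' @export
write_summaries <- function(summaries, path) {
  if (nrow(summaries) == 0) abort("refusing to write an empty summary table")
  missing <- setdiff(summary_cols, names(summaries))
  if (length(missing) > 0) {
    abort(paste0("summary table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(summaries[summary_cols], path)
  invisible(summaries)
}

#' Read a per-colony summary table
#'
#' @param path Path to a CSV written by [write_summaries()].
#' @return A tibble with the summary schema (`L_mm`, `n_active`, `E`,
#'   `mean_degree`, `area_mm2`, `a_star`, `i_star`, ...).
#' @export
read_summaries <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(summary_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("summary table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df
}

# Expected number of position samples for a fully tracked worker.
expected_samples <- function(record) {
  floor(record$duration_s * record$frame_rate / record$sample_stride)
}
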