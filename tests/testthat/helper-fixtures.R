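# In-code fixtures shared across test files.

make_colonies <- function(ids = "c1", n_total = 100, n_tracked = 85,
                          mass_g = 0.9, metabolic_rate_mW = 1.2, ...) {
  tibble::tibble(colony_id = ids, n_total = n_total, n_tracked = n_tracked,
                 mass_g = mass_g, metabolic_rate_mW = metabolic_rate_mW,
                 enclosure_mm = 248, duration_s = 30, frame_rate = 15,
                 sample_stride = 5, ...)
}

# One worker's trajectory from coordinate vectors, sampled at 3 Hz.
make_traj <- function(x, y, worker_id = "w1", colony_id = "c1",
                      t = (seq_along(x) - 1) / 3) {
  tibble::tibble(colony_id = colony_id, worker_id = worker_id, t_s = t,
                 x_mm = x, y_mm = y)
}

# n_workers random-walk trajectories inside the enclosure, fixed seed.
make_random_walks <- function(n_workers = 5, n_samples = 90, seed = 42,
                              colony_id = "c1", step_sd = 2, origin = 124) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n_workers), function(w) {
      x <- pmin(pmax(cumsum(c(origin, rnorm(n_samples - 1, 0, step_sd))),
                     0), 248)
      y <- pmin(pmax(cumsum(c(origin, rnorm(n_samples - 1, 0, step_sd))),
                     0), 248)
      make_traj(x, y, worker_id = sprintf("w%02d", w), colony_id = colony_id)
    }) |> purrr::list_rbind()
  })
}

# Static worker positions repeated over n_frames (for proximity tests).
make_static_frames <- function(positions, n_frames = 3, colony_id = "c1") {
  purrr::map(seq_len(n_frames) - 1, function(f) {
    tibble::tibble(colony_id = colony_id,
                   worker_id = positions$worker_id,
                   t_s = f / 3, x_mm = positions$x_mm, y_mm = positions$y_mm)
  }) |> purrr::list_rbind()
}

# O(N^2) brute-force proximity edge count, independent of the implementation.
brute_force_edges <- function(x, y, d) {
  n <- length(x)
  cnt <- 0L
  if (n < 2) return(0L)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= d) cnt <- cnt + 1L
    }
  }
  cnt
}

# Independent point-in-cell binning oracle for occupancy.
brute_force_cells <- function(x, y, cell_length, n_cells_side) {
  cells <- character(0)
  for (i in seq_along(x)) {
    cx <- min(max(floor(x[i] / cell_length), 0), n_cells_side - 1)
    cy <- min(max(floor(y[i] / cell_length), 0), n_cells_side - 1)
    cells <- c(cells, paste(cy, cx))
  }
  unique(cells)
}
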