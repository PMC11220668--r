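test_that("frame graphs are simple, undirected, and boundary-inclusive", {
  pos <- tibble::tibble(worker_id = c("a", "b"), x_mm = c(0, 5), y_mm = 0)
  expect_equal(nrow(proximity_pairs(pos)), 1)

  # equilateral triangle with side exactly d: all three edges included
  tri <- tibble::tibble(worker_id = c("a", "b", "c"),
                        x_mm = c(0, 6, 3), y_mm = c(0, 0, 3 * sqrt(3)))
  pairs <- proximity_pairs(tri, d = 6)
  expect_equal(nrow(pairs), 3)
  expect_true(all(pairs$worker_a < pairs$worker_b))

  expect_equal(nrow(proximity_pairs(pos[1, ])), 0)
  expect_error(proximity_pairs(pos, d = 0), "positive")
  expect_error(proximity_pairs(dplyr::mutate(pos, worker_id = "a")),
               "duplicated")
})

test_that("edge counts agree with the all-pairs brute-force oracle", {
  for (seed in 1:5) {
    pos <- withr::with_seed(seed, tibble::tibble(
      worker_id = sprintf("w%02d", 1:40),
      x_mm = runif(40, 0, 60), y_mm = runif(40, 0, 60)))
    for (d in c(3, 6, 12)) {
      expect_equal(nrow(proximity_pairs(pos, d)),
                   brute_force_edges(pos$x_mm, pos$y_mm, d))
    }
  }
})

test_that("E is the time average of per-frame edge counts and <k> = 2E/N", {
  col <- make_colonies(n_tracked = 2, n_total = 2)
  # two workers overlapping every frame: E = 1, <k> = 1
  pos <- tibble::tibble(worker_id = c("a", "b"), x_mm = c(10, 10),
                        y_mm = c(10, 10))
  traj <- make_static_frames(pos, n_frames = 5)
  ps <- proximity_summary(traj, col)
  expect_equal(ps$E, 1)
  expect_equal(ps$mean_degree, 1)

  # pinned far apart: E = 0
  apart <- tibble::tibble(worker_id = c("a", "b"), x_mm = c(0, 200),
                          y_mm = c(0, 0))
  expect_equal(proximity_summary(make_static_frames(apart, 5), col)$E, 0)

  # mixed frames: edge in 2 of 4 frames -> E = 0.5
  mixed <- dplyr::bind_rows(
    make_traj(c(0, 0, 0, 0), c(0, 0, 0, 0), "a"),
    make_traj(c(3, 100, 3, 100), c(0, 0, 0, 0), "b"))
  ps2 <- proximity_summary(mixed, col)
  expect_equal(ps2$E, 0.5)
  expect_equal(ps2$mean_degree, 0.5)
})

test_that("the mean degree denominator is the colony's tracked count", {
  # 3 tracked workers, but only 2 appear in the data
  col <- make_colonies(n_tracked = 3, n_total = 4)
  pos <- tibble::tibble(worker_id = c("a", "b"), x_mm = c(10, 12),
                        y_mm = c(10, 10))
  ps <- proximity_summary(make_static_frames(pos, 3), col)
  expect_equal(ps$E, 1)
  expect_equal(ps$mean_degree, 2 / 3)
})

test_that("E is monotone non-decreasing in the interaction distance", {
  traj <- make_random_walks(15, 30, seed = 9, step_sd = 6)
  col <- make_colonies(n_tracked = 15, n_total = 18)
  e_values <- vapply(c(1, 2, 4, 6, 9, 12), function(d) {
    proximity_summary(traj, col, d = d)$E
  }, numeric(1))
  expect_true(all(diff(e_values) >= 0))
  n <- 15
  expect_true(all(e_values <= n * (n - 1) / 2))
})

test_that("pair weights count frames in proximity and round-trip export", {
  col <- make_colonies(n_tracked = 3, n_total = 3)
  traj <- dplyr::bind_rows(
    make_traj(rep(0, 12), rep(0, 12), "a"),
    make_traj(c(rep(3, 5), rep(100, 7)), rep(0, 12), "b"),
    make_traj(rep(200, 12), rep(0, 12), "c"))
  net <- proximity_network(traj)
  expect_equal(nrow(net), 1)
  expect_equal(net$n_frames, 5L)
  expect_equal(net$worker_a, "a")

  path <- withr::local_tempfile(fileext = ".csv")
  export_network(net, path)
  expect_equal(as.data.frame(read_network(path)), as.data.frame(net))

  # cumulative weights equal the per-frame accumulation oracle
  walks <- make_random_walks(8, 20, seed = 4, step_sd = 8)
  net2 <- proximity_network(walks, d = 6)
  total_from_net <- sum(net2$n_frames)
  total_from_frames <- sum(proximity_edges(walks, d = 6)$n_edges)
  expect_equal(total_from_net, total_from_frames)

  # empty network: header-only file round-trips to zero rows
  empty <- proximity_network(make_static_frames(
    tibble::tibble(worker_id = c("a", "b"), x_mm = c(0, 200), y_mm = 0), 2))
  export_network(empty, path)
  expect_equal(nrow(read_network(path)), 0)
})

test_that("uniform placement matches the mean-field edge expectation", {
  # ~ N^2 pi d^2 / (2 S) edges per frame for uniform placement in area S
  side <- 248
  n <- 120
  d <- 6
  frames <- withr::with_seed(31, purrr::map(1:40, function(f) {
    tibble::tibble(colony_id = "c1", worker_id = sprintf("w%03d", 1:n),
                   t_s = (f - 1) / 3,
                   x_mm = runif(n, 0, side), y_mm = runif(n, 0, side))
  }) |> purrr::list_rbind())
  col <- make_colonies(n_tracked = n, n_total = n)
  e_hat <- proximity_summary(frames, col)$E
  expected <- n^2 * pi * d^2 / (2 * side^2)
  expect_gt(e_hat, expected * 0.75)
  expect_lt(e_hat, expected * 1.25)
})
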