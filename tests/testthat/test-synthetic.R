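test_that("generator configuration validates its parameters", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_colonies = 0), "n_colonies")
  expect_error(generator_config(n_range = c(400, 40)), "n_range")
  expect_error(generator_config(tracked_fraction = 0), "tracked_fraction")
  expect_error(generator_config(e0 = -1), "positive")
  expect_error(generator_config(activity_fraction = 2), "activity_fraction")
})

test_that("generation is deterministic and order-stable in the seed", {
  cfg <- generator_config(seed = 123)
  a <- generate_summaries(cfg)
  b <- generate_summaries(cfg)
  expect_identical(a, b)
  t1 <- generate_trajectories(generator_config(n_colonies = 2,
                                               n_range = c(40, 80),
                                               seed = 123))
  t2 <- generate_trajectories(generator_config(n_colonies = 2,
                                               n_range = c(40, 80),
                                               seed = 123))
  expect_identical(t1, t2)
  expect_false(identical(
    a, generate_summaries(generator_config(seed = 124))))

  # per-colony child streams: adding a colony never changes earlier ones
  more <- generate_summaries(generator_config(n_colonies = 18, seed = 123))
  expect_identical(more$summaries[1:16, ], a$summaries)
})

test_that("noise-free summaries reproduce the generating laws exactly", {
  cfg <- generator_config(noise_sigma_log = 0, mass_sigma_log = 0, seed = 2)
  gs <- generate_summaries(cfg)
  e_fit <- fit_power_law(gs$summaries, n_tracked, E)
  expect_equal(e_fit$exponent, 1.47, tolerance = 1e-10)
  expect_equal(e_fit$prefactor, 0.0944, tolerance = 1e-8)
  area_fit <- fit_power_law(gs$summaries, n_tracked, area_mm2)
  expect_equal(area_fit$exponent, 0.51, tolerance = 1e-10)
  expect_equal(area_fit$prefactor, 3050, tolerance = 1e-4)
  # balance statistic deviates from qN only through integer rounding of A
  bal <- balance_statistic(gs$summaries)
  expect_equal(bal$balance / bal$n_tracked, rep(0.519, 16), tolerance = 0.02)
})

test_that("summary-mode structure matches the assumed model", {
  gs <- generate_summaries(generator_config(seed = 7))
  s <- gs$summaries
  expect_equal(s$mean_degree, 2 * s$E / s$n_tracked)
  expect_equal(s$a_star + s$i_star, as.numeric(s$n_total))
  expect_true(all(s$n_active <= s$n_tracked))
  expect_true(all(gs$colonies$metabolic_rate_mW > 0))
  expect_true(all(gs$colonies$mass_g > 0))
  # mass tracks N* with mild noise
  mfit <- fit_power_law(
    dplyr::left_join(s, gs$colonies[c("colony_id", "mass_g")],
                     by = "colony_id"), n_total, mass_g)
  expect_equal(mfit$exponent, 1, tolerance = 0.25)
})

test_that("trajectory mode yields valid, analysis-ready positional data", {
  cfg <- generator_config(n_colonies = 4, n_range = c(40, 120), seed = 31)
  gt <- generate_trajectories(cfg)
  # passes the io validators untouched
  col <- validate_colonies(gt$colonies)
  traj <- validate_trajectories(gt$trajectories, col)
  expect_equal(nrow(traj), nrow(gt$trajectories))
  counts <- dplyr::count(traj, colony_id, worker_id)
  expect_true(all(counts$n == 90))
  # every downstream stage runs without error
  s <- summarize_colonies(traj, col)
  expect_true(all(s$E >= 0))
  expect_true(all(s$area_mm2 > 0))
  expect_true(all(s$a_star + s$i_star == s$n_total))
})

test_that("an all-inactive override produces no classified activity", {
  cfg <- generator_config(n_colonies = 3, n_range = c(40, 80),
                          activity_fraction = 0, seed = 17)
  gt <- generate_trajectories(cfg)
  s <- summarize_colonies(gt$trajectories, gt$colonies)
  expect_equal(sum(s$n_active), 0)
})

test_that("clustered trajectories give emergent hypermetric interaction scaling", {
  hyper <- vapply(1:5, function(seed) {
    cfg <- generator_config(n_colonies = 8, n_range = c(40, 250),
                            seed = seed)
    gt <- generate_trajectories(cfg)
    s <- summarize_colonies(gt$trajectories, gt$colonies)
    fit_power_law(s, n_tracked, E)$exponent
  }, numeric(1))
  expect_gte(mean(hyper > 1), 0.8)
  # and area stays hypometric on average
  expect_true(mean(hyper) > 1)
})

test_that("pinned clusters collapse the spanned area to the sites", {
  cfg <- generator_config(n_colonies = 1, n_range = c(100, 100),
                          n_clusters = 3, cluster_sd_mm = 1e-4,
                          jitter_sd_mm = 1e-6, activity_fraction = 0,
                          seed = 41)
  gt <- generate_trajectories(cfg)
  sa <- spanned_area(gt$trajectories, gt$colonies)
  expect_lte(sa$n_cells_visited, 3)
})
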