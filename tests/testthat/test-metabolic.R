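test_that("scaled counts conserve the total worker count", {
  s <- tibble::tibble(colony_id = "c1", n_total = 100, n_tracked = 80,
                      n_active = 40)
  sc <- scale_counts(s)
  expect_equal(sc$a_star, 50)
  expect_equal(sc$i_star, 50)

  none <- scale_counts(dplyr::mutate(s, n_active = 0))
  expect_equal(none$a_star, 0)
  expect_equal(none$i_star, 100)

  rnd <- withr::with_seed(13, tibble::tibble(
    colony_id = sprintf("c%02d", 1:20),
    n_total = sample(50:400, 20)) |>
      dplyr::mutate(n_tracked = round(0.85 * n_total),
                    n_active = round(runif(20) * n_tracked)))
  sc2 <- scale_counts(rnd)
  expect_equal(sc2$a_star + sc2$i_star, sc2$n_total)
  expect_error(scale_counts(dplyr::mutate(s, n_active = 90)),
               "exceed")
})

test_that("a noise-free Cobb-Douglas model is recovered to high precision", {
  d <- withr::with_seed(21, tibble::tibble(
    a_star = runif(16, 20, 200),
    i_star = runif(16, 30, 300),
    metabolic_rate_mW = 0.03 * a_star^0.8 * i_star^0.2))
  fit <- fit_cobb_douglas(d)
  expect_equal(fit$alpha_b, 0.8, tolerance = 1e-10)
  expect_equal(fit$b0, 0.03, tolerance = 1e-10)
  expect_equal(fit$r2_log, 1, tolerance = 1e-10)
})

test_that("Cobb-Douglas fitting rejects degenerate inputs", {
  prop <- tibble::tibble(a_star = c(10, 20, 40), i_star = c(5, 10, 20),
                         metabolic_rate_mW = c(1, 2, 4))
  expect_error(fit_cobb_douglas(prop), "degenerate")
  withzero <- tibble::tibble(a_star = c(0, 10, 20, 40),
                             i_star = c(50, 5, 80, 20),
                             metabolic_rate_mW = c(1, 1, 2, 4))
  expect_warning(fit <- fit_cobb_douglas(withzero), "non-positive")
  expect_equal(fit$n, 3)
  expect_error(suppressWarnings(fit_cobb_douglas(withzero[1:3, ])),
               "at least 3")
})

test_that("marginal products follow the elasticities and Euler's identity", {
  params <- cobb_douglas_params(b0 = 1 / (50^0.85 * 60^0.15), alpha_b = 0.85)
  mp <- marginal_products(params, 50, 60)
  expect_equal(mp$rate_mW, 1, tolerance = 1e-12)
  expect_equal(mp$mp_active, 0.85 / 50)

  sym <- cobb_douglas_params(0.5, 0.5)
  mp_sym <- marginal_products(sym, 30, 30)
  expect_equal(mp_sym$mp_active, mp_sym$mp_inactive)

  # Euler: A* MP(A*) + I* MP(I*) = B, checked over random inputs
  rnd <- withr::with_seed(9, tibble::tibble(a = runif(25, 1, 300),
                                            i = runif(25, 1, 300)))
  p <- cobb_douglas_params(0.0301, 0.85)
  mps <- marginal_products(p, rnd$a, rnd$i)
  expect_equal(rnd$a * mps$mp_active + rnd$i * mps$mp_inactive,
               mps$rate_mW, tolerance = 1e-12)
  expect_error(marginal_products(p, 0, 10), "positive")
})

test_that("the Cobb-Douglas function is homogeneous of degree one", {
  p <- cobb_douglas_params(0.0301, 0.85)
  a <- c(10, 45, 120)
  i <- c(60, 80, 140)
  expect_equal(cobb_douglas_rate(p, 2 * a, 2 * i),
               2 * cobb_douglas_rate(p, a, i), tolerance = 1e-12)
})

test_that("the composed metabolic prediction equals contagion + Cobb-Douglas", {
  cg <- contagion_params(0.519, 0.0944, 1.47)
  cd <- cobb_douglas_params(0.0301, 0.85)
  n <- seq(40, 400, by = 30)
  n_total <- round(n / 0.85)
  direct <- predict_metabolic_rate(cd, cg, n, n_total)
  a_star <- predict_active(cg, n) * n_total / n
  i_star <- n_total - a_star
  composed <- cobb_douglas_rate(cd, a_star, i_star)
  expect_equal(direct, composed, tolerance = 1e-12)
})

test_that("the metabolic prediction respects its domain bound", {
  cg <- contagion_params(0.519, 0.0944, 1.47)
  cd <- cobb_douglas_params(0.0301, 0.85)
  # active fraction reaches 1 when n = (2 E0 / q)^(1/(1-beta_e)) ~ 8.7
  n_min <- (2 * 0.0944 / 0.519)^(1 / (1 - 1.47))
  expect_error(predict_metabolic_rate(cd, cg, floor(n_min)),
               "active fraction")
  expect_gt(predict_metabolic_rate(cd, cg, ceiling(n_min) + 1), 0)

  # alpha_b = 1: only active workers cost energy
  all_active <- suppressWarnings(cobb_douglas_params(0.0301, 1))
  n <- 100
  frac <- sqrt(0.519 / (2 * 0.0944)) * n^((1 - 1.47) / 2)
  expect_equal(predict_metabolic_rate(all_active, cg, n),
               0.0301 * n * frac, tolerance = 1e-12)
})

test_that("the derived exponent links interaction scaling to Kleiber-like scaling", {
  expect_equal(round(derived_exponent(1.47, 0.85), 2), 0.8)
  expect_equal(derived_exponent(1, 0.85), 1)
  expect_equal(derived_exponent(1.47, 0), 1)
  cg <- contagion_params(0.519, 0.0944, 1.47)
  cd <- cobb_douglas_params(0.0301, 0.85)
  expect_equal(derived_exponent(cg, cd), (1 - 1.47) * 0.85 / 2 + 1)
})

test_that("the log-log slope of the prediction approaches the derived exponent", {
  cg <- contagion_params(0.519, 0.0944, 1.47)
  cd <- cobb_douglas_params(0.0301, 0.85)
  target <- derived_exponent(cg, cd)
  # two-point log-log slope over successive decades n = 10^3 .. 10^6
  slopes <- vapply(3:5, function(k) {
    b <- predict_metabolic_rate(cd, cg, 10^c(k, k + 1))
    diff(log(b)) / log(10)
  }, numeric(1))
  expect_true(all(diff(abs(slopes - target)) < 0))
  expect_equal(slopes[3], target, tolerance = 5e-3)
})
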