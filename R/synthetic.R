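# Synthetic colony generator, in two modes. Summary mode draws per-colony
# derived quantities directly from the assumed scaling structure (interaction
# and area power laws, the contagion balance, the Cobb-Douglas metabolic
# function) with multiplicative lognormal noise: it is the sharp instrument
# for parameter-recovery tests. Trajectory mode emits full positional data
# with clustered spatial occupancy (workers aggregate around a few attractor
# sites, as around a brood pile or food tubes), inactive workers jittering in
# place and active workers walking between sites with a size-independent mean
# path length: it exercises every pipeline stage end to end, where the
# spatial scaling is emergent rather than imposed.

#' Generator configuration
#'
#' Parameters of the synthetic-colony generator. The scaling and model
#' parameters default to the values the analysis pipeline is designed to
#' recover (interaction scaling `E = E0 N^betaE` with `betaE = 1.47`,
#' `E0 = 0.0944`; area scaling `Area0 = 3050` mm^2, `betaArea = 0.51`;
#' balance rate `q = 0.519`; Cobb-Douglas `alphaB = 0.85`, `B0 = 0.0301`
#' mW). Sixteen colonies with total worker counts log-uniform on [40, 400]
#' and 85% of workers tracked emulate the study design the package targets.
#'
#' @param n_colonies Number of colonies (default 16).
#' @param n_range Range (min, max) of total worker count `N*`, drawn
#'   log-uniformly (default `c(40, 400)`).
#' @param tracked_fraction Fraction of workers that are tracked (default
#'   0.85).
#' @param beta_e,e0 Interaction-scaling exponent and prefactor.
#' @param beta_area,area0 Spanned-area scaling exponent and prefactor (mm^2).
#' @param q Contagion balance rate.
#' @param alpha_b,b0 Cobb-Douglas elasticity and baseline (mW).
#' @param noise_sigma_log Lognormal sigma of the multiplicative noise on
#'   `E`, `Area` and `B` in summary mode (default 0.2).
#' @param mass_per_worker_g Mean wet mass per worker, g (default 0.009, a
#'   plausible per-capita wet mass for a small harvester-ant colony
#'   including brood).
#' @param mass_sigma_log Lognormal sigma of colony mass about `M ~ N*`
#'   (default 0.1).
#' @param path_length_mean_mm,path_length_sigma_log Size-independent
#'   per-worker path length distribution (default lognormal about 77 mm,
#'   sigma 0.25).
#' @param activity_fraction Optional override: fix the active fraction
#'   instead of solving the contagion balance (e.g. 0 for an all-inactive
#'   colony).
#' @param n_clusters Attractor sites per colony in trajectory mode
#'   (default 6).
#' @param cluster_sd_mm Spatial spread of workers around their site, mm
#'   (default 10).
#' @param site_switch_prob Per-step probability that an active worker picks
#'   a new target site (default 0.05).
#' @param jitter_sd_mm Per-axis positional jitter of inactive workers, mm
#'   (default 0.01; keeps their apparent path well under the 3 mm activity
#'   threshold).
#' @param enclosure_mm,duration_s,frame_rate,sample_stride Video protocol
#'   (defaults 248 mm, 30 s, 15 fps, every 5th frame: 90 samples at 3 Hz).
#' @param seed Root RNG seed. Each colony derives its own child stream from
#'   it, so adding colonies never perturbs earlier ones.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_colonies = 16, n_range = c(40, 400),
                             tracked_fraction = 0.85,
                             beta_e = 1.47, e0 = 0.0944,
                             beta_area = 0.51, area0 = 3050,
                             q = 0.519, alpha_b = 0.85, b0 = 0.0301,
                             noise_sigma_log = 0.2,
                             mass_per_worker_g = 0.009,
                             mass_sigma_log = 0.1,
                             path_length_mean_mm = 77,
                             path_length_sigma_log = 0.25,
                             activity_fraction = NULL,
                             n_clusters = 6, cluster_sd_mm = 10,
                             site_switch_prob = 0.05, jitter_sd_mm = 0.01,
                             enclosure_mm = 248, duration_s = 30,
                             frame_rate = 15, sample_stride = 5,
                             seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_colonies < 1) abort("n_colonies must be at least 1")
  if (length(cfg$n_range) != 2 || cfg$n_range[1] < 1 ||
      cfg$n_range[2] < cfg$n_range[1]) {
    abort("n_range must be (min, max) with 1 <= min <= max")
  }
  if (cfg$tracked_fraction <= 0 || cfg$tracked_fraction > 1) {
    abort("tracked_fraction must be in (0, 1]")
  }
  for (p in c("e0", "area0", "q", "b0", "mass_per_worker_g",
              "path_length_mean_mm", "enclosure_mm", "duration_s",
              "frame_rate", "sample_stride")) {
    if (cfg[[p]] <= 0) abort(paste0(p, " must be positive"))
  }
  if (cfg$noise_sigma_log < 0) abort("noise_sigma_log must be non-negative")
  if (!is.null(cfg$activity_fraction) &&
      (cfg$activity_fraction < 0 || cfg$activity_fraction > 1)) {
    abort("activity_fraction must be in [0, 1]")
  }
  structure(cfg, class = "generator_config")
}

# Deterministic per-colony child seed, independent of colony order.
child_seed <- function(seed, i) {
  ((seed %% 100000) * 20011 + i * 7919) %% 2147483629
}

draw_colony_core <- function(cfg, i) {
  nstar <- round(exp(runif(1, log(cfg$n_range[1]), log(cfg$n_range[2]))))
  n <- max(1L, as.integer(round(cfg$tracked_fraction * nstar)))
  mass <- cfg$mass_per_worker_g * nstar * exp(rnorm(1, 0, cfg$mass_sigma_log))
  list(colony_id = sprintf("syn%02d", i), nstar = as.integer(nstar), n = n,
       mass = mass)
}

active_count <- function(cfg, n, e) {
  if (!is.null(cfg$activity_fraction)) {
    return(as.integer(round(cfg$activity_fraction * n)))
  }
  a <- n * sqrt(cfg$q * n / (2 * e))
  as.integer(min(n, max(0, round(a))))
}

#' Generate summary-level synthetic colonies
#'
#' Draws per-colony summary quantities directly from the generating model:
#' `N*` log-uniform, `E = E0 N^betaE eps`, `Area = Area0 N^betaArea eps'`,
#' the active count solving the contagion balance `<k> A^2 / N = q N` with
#' the colony's own (noisy) `E`, and `B` from the Cobb-Douglas function of
#' the scaled counts with lognormal noise. Mass is proportional to `N*` with
#' mild noise and path length is drawn independently of colony size.
#'
#' @param config A [generator_config()] object.
#' @return A list with tibbles `colonies` (metadata schema) and `summaries`
#'   (summary schema), each with one row per colony.
#' @export
generate_summaries <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  rows <- map(seq_len(cfg$n_colonies), function(i) {
    set.seed(child_seed(cfg$seed, i))
    core <- draw_colony_core(cfg, i)
    n <- core$n
    e <- cfg$e0 * n^cfg$beta_e * exp(rnorm(1, 0, cfg$noise_sigma_log))
    area <- cfg$area0 * n^cfg$beta_area * exp(rnorm(1, 0, cfg$noise_sigma_log))
    a <- active_count(cfg, n, e)
    a_star <- a * core$nstar / n
    i_star <- core$nstar - a_star
    # floor keeps B positive for a degenerate all-inactive colony
    a_eff <- max(a_star, 0.5)
    b <- cfg$b0 * a_eff^cfg$alpha_b * i_star^(1 - cfg$alpha_b) *
      exp(rnorm(1, 0, cfg$noise_sigma_log))
    l <- cfg$path_length_mean_mm * exp(rnorm(1, 0, cfg$path_length_sigma_log))
    l_median <- l * 0.9 * exp(rnorm(1, 0, 0.05))
    tibble(colony_id = core$colony_id, n_total = core$nstar, n_tracked = n,
           mass_g = core$mass, metabolic_rate_mW = b,
           L_mm = l, L_median_mm = l_median, n_active = a, E = e,
           mean_degree = 2 * e / n, area_mm2 = area,
           a_star = a_star, i_star = i_star)
  }) %>% list_rbind()
  colonies <- rows %>%
    select("colony_id", "n_total", "n_tracked", "mass_g",
           "metabolic_rate_mW") %>%
    mutate(enclosure_mm = cfg$enclosure_mm, duration_s = cfg$duration_s,
           frame_rate = cfg$frame_rate, sample_stride = cfg$sample_stride)
  summaries <- rows %>%
    select("colony_id", "n_total", "n_tracked", "L_mm", "L_median_mm",
           "n_active", "E", "mean_degree", "area_mm2", "a_star", "i_star")
  list(colonies = colonies, summaries = summaries)
}

#' Generate trajectory-level synthetic colonies
#'
#' Emits full positional data. Each colony gets `n_clusters` attractor sites
#' with heavy-tailed occupation weights; inactive workers sit near their
#' site with sub-threshold jitter, while active workers walk between sites
#' at a size-independent mean speed (path length ~ 77 mm over the video).
#' The active count follows the contagion-balance prediction unless
#' `activity_fraction` overrides it. Sampling follows the video protocol:
#' 90 samples per worker at 3 Hz.
#'
#' @param config A [generator_config()] object.
#' @return A list with tibbles `colonies` (metadata schema) and
#'   `trajectories` (`colony_id, worker_id, t_s, x_mm, y_mm`).
#' @export
generate_trajectories <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  n_samples <- floor(cfg$duration_s * cfg$frame_rate / cfg$sample_stride)
  dt <- cfg$sample_stride / cfg$frame_rate
  times <- (seq_len(n_samples) - 1) * dt
  side <- cfg$enclosure_mm
  out <- map(seq_len(cfg$n_colonies), function(i) {
    set.seed(child_seed(cfg$seed, i))
    core <- draw_colony_core(cfg, i)
    n <- core$n
    e_nominal <- cfg$e0 * n^cfg$beta_e
    a <- active_count(cfg, n, e_nominal)
    k <- cfg$n_clusters
    sites <- cbind(runif(k, 0.15 * side, 0.85 * side),
                   runif(k, 0.15 * side, 0.85 * side))
    w <- (seq_len(k))^(-1.2)
    assignment <- sample.int(k, n, replace = TRUE, prob = w)
    active <- rep(FALSE, n)
    if (a > 0) active[sample.int(n, a)] <- TRUE
    base <- sites[assignment, , drop = FALSE] +
      matrix(rnorm(2 * n, 0, cfg$cluster_sd_mm), n, 2)
    base <- pmin(pmax(base, 1), side - 1)
    xs <- matrix(NA_real_, n, n_samples)
    ys <- matrix(NA_real_, n, n_samples)
    xs[, 1] <- base[, 1]
    ys[, 1] <- base[, 2]
    n_act <- sum(active)
    speed <- rep(0, n)
    target <- assignment
    if (n_act > 0) {
      speed[active] <- (cfg$path_length_mean_mm / cfg$duration_s) *
        exp(rnorm(n_act, 0, cfg$path_length_sigma_log))
    }
    for (s in 2:n_samples) {
      # inactive: fresh jitter about the resting spot
      idle <- !active
      if (any(idle)) {
        xs[idle, s] <- base[idle, 1] + rnorm(sum(idle), 0, cfg$jitter_sd_mm)
        ys[idle, s] <- base[idle, 2] + rnorm(sum(idle), 0, cfg$jitter_sd_mm)
      }
      if (n_act > 0) {
        ia <- which(active)
        switch_now <- runif(n_act) < cfg$site_switch_prob
        if (any(switch_now)) {
          target[ia[switch_now]] <- sample.int(k, sum(switch_now),
                                               replace = TRUE, prob = w)
        }
        dx <- sites[target[ia], 1] - xs[ia, s - 1]
        dy <- sites[target[ia], 2] - ys[ia, s - 1]
        gap <- sqrt(dx^2 + dy^2)
        heading <- ifelse(gap < 5, runif(n_act, -pi, pi),
                          atan2(dy, dx) + rnorm(n_act, 0, 0.5))
        step <- speed[ia] * dt
        xs[ia, s] <- xs[ia, s - 1] + step * cos(heading) +
          rnorm(n_act, 0, 0.1)
        ys[ia, s] <- ys[ia, s - 1] + step * sin(heading) +
          rnorm(n_act, 0, 0.1)
      }
      xs[, s] <- pmin(pmax(xs[, s], 0), side)
      ys[, s] <- pmin(pmax(ys[, s], 0), side)
    }
    ids <- sprintf("w%03d", seq_len(n))
    traj <- tibble(colony_id = core$colony_id,
                   worker_id = rep(ids, each = n_samples),
                   t_s = rep(times, n),
                   x_mm = as.vector(t(xs)), y_mm = as.vector(t(ys)))
    a_star <- a * core$nstar / n
    i_star <- core$nstar - a_star
    a_eff <- max(a_star, 0.5)
    b <- cfg$b0 * a_eff^cfg$alpha_b * i_star^(1 - cfg$alpha_b) *
      exp(rnorm(1, 0, cfg$noise_sigma_log))
    colony <- tibble(colony_id = core$colony_id, n_total = core$nstar,
                     n_tracked = n, mass_g = core$mass,
                     metabolic_rate_mW = b, enclosure_mm = side,
                     duration_s = cfg$duration_s, frame_rate = cfg$frame_rate,
                     sample_stride = cfg$sample_stride)
    list(colony = colony, traj = traj)
  })
  list(colonies = list_rbind(map(out, "colony")),
       trajectories = list_rbind(map(out, "traj")))
}
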