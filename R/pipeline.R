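# Orchestration: trajectories -> per-colony summaries -> scaling fits ->
# contagion and Cobb-Douglas estimates -> model predictions and report,
# plus the robustness sweep over interaction distance and grid cell size.

#' Summarize colonies from trajectories
#'
#' Runs the kinematic, proximity-network and occupancy stages and assembles
#' the per-colony summary table: mean/median path length, active count,
#' time-averaged interaction count `E`, mean degree, spanned area, and the
#' whole-colony scaled counts `A*`, `I*`.
#'
#' @param trajectories Trajectory tibble (`colony_id, worker_id, t_s, x_mm,
#'   y_mm`).
#' @param colonies Colony metadata, as from [read_colonies()].
#' @param d Interaction distance in mm (default 6).
#' @param speed_threshold Activity threshold in mm/s (default 0.1).
#' @param n_cells_side Occupancy grid cells per side (default 24).
#' @param cell_length Grid cell length in mm, or `NULL` for
#'   `enclosure_mm / n_cells_side`.
#' @return A tibble with the summary schema: `colony_id, n_total, n_tracked,
#'   L_mm, L_median_mm, n_active, E, mean_degree, area_mm2, a_star, i_star`.
#' @export
summarize_colonies <- function(trajectories, colonies, d = 6,
                               speed_threshold = 0.1, n_cells_side = 24,
                               cell_length = NULL) {
  kin <- colony_kinematics(trajectories, colonies, speed_threshold)
  prox <- proximity_summary(trajectories, colonies, d = d)
  occ <- spanned_area(trajectories, colonies, n_cells_side, cell_length)
  colonies %>%
    select("colony_id", "n_total", "n_tracked") %>%
    left_join(kin, by = "colony_id") %>%
    left_join(select(prox, "colony_id", "E", "mean_degree"),
              by = "colony_id") %>%
    left_join(select(occ, "colony_id", "area_mm2"), by = "colony_id") %>%
    scale_counts() %>%
    select("colony_id", "n_total", "n_tracked", "L_mm", "L_median_mm",
           "n_active", "E", "mean_degree", "area_mm2", "a_star", "i_star")
}

#' Run the full analysis pipeline
#'
#' Chains every analysis stage on a set of colonies: (optionally) simulate,
#' summarize, fit the interaction and area scaling laws, the `L`-vs-`N`
#' linear fit, the contagion balance (`q`), and the Cobb-Douglas metabolic
#' function; then produce the model predictions for the active count
#' (contagion law) and the metabolic rate (composed model) with their
#' prediction R-squared values, the effective interaction area, the Kleiber
#' (mass) scaling diagnostic, and the derived metabolic exponent.
#'
#' Exactly one of `config` (simulate) or `colonies` plus either
#' `trajectories` or `summaries` must be supplied.
#'
#' @param trajectories Optional trajectory tibble (trajectory-level input).
#' @param colonies Colony metadata (required unless simulating).
#' @param summaries Optional precomputed summary table (summary-level input).
#' @param config Optional [generator_config()]; when given, data are
#'   simulated in the requested `mode`.
#' @param mode Simulation mode, `"summary"` or `"trajectory"`.
#' @param d,speed_threshold,n_cells_side,cell_length Summarization
#'   parameters, see [summarize_colonies()].
#' @param out_dir Optional directory; when given, the summary table (CSV),
#'   fitted constants (JSON) and prediction tables (CSV) are written there.
#' @return An object of class `pipeline_report`: a list with `summaries`,
#'   the fit objects (`e_fit`, `area_fit`, `l_fit`, `q_fit`, `cd_fit`,
#'   `kleiber_fit`), parameter bundles (`contagion`, `cobb_douglas`),
#'   `predictions` (per-colony observed vs predicted `A` and `B`),
#'   `constants` (tidy table of every fitted constant), `effective_area`,
#'   and `derived_exponent`.
#' @export
run_pipeline <- function(trajectories = NULL, colonies = NULL,
                         summaries = NULL, config = NULL,
                         mode = c("summary", "trajectory"), d = 6,
                         speed_threshold = 0.1, n_cells_side = 24,
                         cell_length = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (!is.null(config)) {
    if (mode == "summary") {
      sim <- generate_summaries(config)
      colonies <- sim$colonies
      summaries <- sim$summaries
    } else {
      sim <- generate_trajectories(config)
      colonies <- sim$colonies
      trajectories <- sim$trajectories
    }
  }
  if (is.null(colonies)) {
    abort("no colony metadata: supply `colonies` or a generator `config`")
  }
  if (is.null(summaries)) {
    if (is.null(trajectories)) {
      abort("no input data: supply `trajectories`, `summaries`, or a generator `config`")
    }
    summaries <- summarize_colonies(trajectories, colonies, d,
                                    speed_threshold, n_cells_side,
                                    cell_length)
  }
  with_meta <- summaries %>%
    left_join(select(colonies, "colony_id", "mass_g", "metabolic_rate_mW"),
              by = "colony_id")

  l_fit <- fit_linear(summaries, .data$n_tracked, .data$L_mm)
  e_fit <- fit_power_law(summaries, .data$n_tracked, .data$E)
  area_fit <- fit_power_law(summaries, .data$n_tracked, .data$area_mm2)
  q_fit <- estimate_q(summaries)
  cg <- contagion_params(q_fit$q, e_fit$prefactor, e_fit$exponent)
  cd_fit <- fit_cobb_douglas(with_meta)
  cd <- cd_fit$params
  kleiber_fit <- fit_power_law(with_meta, .data$mass_g,
                               .data$metabolic_rate_mW)

  predictions <- with_meta %>%
    mutate(pred_active = predict_active(cg, .data$n_tracked),
           pred_rate_mW = predict_metabolic_rate(
             cd, cg, .data$n_tracked, .data$n_total)) %>%
    select("colony_id", "n_tracked", "n_total", "n_active", "pred_active",
           "metabolic_rate_mW", "pred_rate_mW")
  r2_active <- prediction_r2(predictions$n_active, predictions$pred_active)
  r2_rate <- prediction_r2(predictions$metabolic_rate_mW,
                           predictions$pred_rate_mW)

  constants <- tibble(
    quantity = c("beta_E", "E0", "beta_Area", "Area0", "q", "alpha_B", "B0",
                 "beta_B", "derived_metabolic_exponent",
                 "effective_interaction_area_mm2",
                 "prediction_r2_active", "prediction_r2_metabolic"),
    value = c(e_fit$exponent, e_fit$prefactor, area_fit$exponent,
              area_fit$prefactor, q_fit$q, cd_fit$alpha_b, cd_fit$b0,
              kleiber_fit$exponent, derived_exponent(cg, cd),
              2 * area_fit$prefactor * e_fit$prefactor, r2_active, r2_rate))
  if (!is.null(config)) {
    gen <- c(config$beta_e, config$e0, config$beta_area, config$area0,
             config$q, config$alpha_b, config$b0,
             derived_exponent(config$beta_e, config$alpha_b),
             derived_exponent(config$beta_e, config$alpha_b),
             2 * config$area0 * config$e0, NA_real_, NA_real_)
    constants$generating <- gen
  }

  report <- structure(list(
    summaries = summaries, colonies = colonies,
    l_fit = l_fit, e_fit = e_fit, area_fit = area_fit, q_fit = q_fit,
    cd_fit = cd_fit, kleiber_fit = kleiber_fit,
    contagion = cg, cobb_douglas = cd,
    predictions = predictions,
    prediction_r2_active = r2_active,
    prediction_r2_metabolic = r2_rate,
    effective_area = effective_interaction_area(
      area_fit, e_fit, d = d, path_length_mm = mean(summaries$L_mm)),
    derived_exponent = derived_exponent(cg, cd),
    constants = constants
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_summaries(summaries, file.path(out_dir, "summaries.csv"))
    readr::write_csv(predictions, file.path(out_dir, "predictions.csv"))
    jsonlite::write_json(
      list(constants = constants,
           ci95 = list(beta_E = e_fit$ci95_exponent,
                       beta_Area = area_fit$ci95_exponent,
                       q = q_fit$fit$ci95_slope,
                       alpha_B = cd_fit$ci95_alpha)),
      file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Colony activity-scaling pipeline report (",
      nrow(x$summaries), " colonies)\n", sep = "")
  cat(sprintf("  E ~ N scaling:    beta_E = %.3f [%.3f, %.3f], E0 = %.4g\n",
              x$e_fit$exponent, x$e_fit$ci95_exponent[1],
              x$e_fit$ci95_exponent[2], x$e_fit$prefactor))
  cat(sprintf("  Area ~ N scaling: beta_Area = %.3f [%.3f, %.3f], Area0 = %.4g\n",
              x$area_fit$exponent, x$area_fit$ci95_exponent[1],
              x$area_fit$ci95_exponent[2], x$area_fit$prefactor))
  cat(sprintf("  balance rate:     q = %.3f (p = %.3g)\n",
              x$q_fit$q, x$q_fit$fit$p_slope))
  cat(sprintf("  Cobb-Douglas:     alpha_B = %.3f [%.3f, %.3f], B0 = %.4g mW\n",
              x$cd_fit$alpha_b, x$cd_fit$ci95_alpha[1],
              x$cd_fit$ci95_alpha[2], x$cd_fit$b0))
  cat(sprintf("  Kleiber (B ~ M):  beta_B = %.3f\n", x$kleiber_fit$exponent))
  cat(sprintf("  derived metabolic exponent: %.3f\n", x$derived_exponent))
  cat(sprintf("  prediction R2: active %.3f, metabolic %.3f\n",
              x$prediction_r2_active, x$prediction_r2_metabolic))
  invisible(x)
}

#' Robustness sweep over interaction distance and grid cell size
#'
#' Re-summarizes trajectory-level data and refits the scaling laws, the
#' balance rate and the Cobb-Douglas elasticity for every combination of
#' interaction distance and occupancy cell length, flagging qualitative
#' changes (interaction scaling crossing hypermetric, `beta_E > 1`).
#' A non-positive `d` yields `E = 0` everywhere; fits are skipped for that
#' grid point with a warning and reported as `NA`.
#'
#' @param trajectories Trajectory tibble.
#' @param colonies Colony metadata.
#' @param d_values Interaction distances to sweep, mm (default 6).
#' @param cell_lengths Cell lengths to sweep, mm; `NA` entries mean
#'   `enclosure_mm / n_cells_side` (default `NA`).
#' @param n_cells_side Grid cells per side (default 24).
#' @param speed_threshold Activity threshold, mm/s.
#' @return A tibble with one row per grid point: `d_mm, cell_length_mm,
#'   beta_E, E0, beta_Area, q, alpha_B, hypermetric`.
#' @export
run_sweep <- function(trajectories, colonies, d_values = 6,
                      cell_lengths = NA, n_cells_side = 24,
                      speed_threshold = 0.1) {
  if (length(d_values) == 0 || length(cell_lengths) == 0) {
    abort("empty sweep grid")
  }
  grid <- expand_grid(d_mm = d_values, cell_length_mm = cell_lengths)
  pmap(grid, function(d_mm, cell_length_mm) {
    cl <- if (is.na(cell_length_mm)) NULL else cell_length_mm
    base <- tibble(d_mm = d_mm,
                   cell_length_mm = if (is.na(cell_length_mm))
                     colonies$enclosure_mm[1] / n_cells_side
                   else cell_length_mm)
    if (d_mm <= 0) {
      warn(paste0("d = ", d_mm, " mm yields no interactions; fits skipped"))
      return(base %>% mutate(beta_E = NA_real_, E0 = NA_real_,
                             beta_Area = NA_real_, q = NA_real_,
                             alpha_B = NA_real_, hypermetric = NA))
    }
    s <- summarize_colonies(trajectories, colonies, d = d_mm,
                            speed_threshold = speed_threshold,
                            n_cells_side = n_cells_side, cell_length = cl)
    sm <- s %>% left_join(select(colonies, "colony_id", "metabolic_rate_mW"),
                          by = "colony_id")
    e_fit <- fit_power_law(s, .data$n_tracked, .data$E)
    area_fit <- fit_power_law(s, .data$n_tracked, .data$area_mm2)
    q_fit <- estimate_q(s)
    cd_fit <- fit_cobb_douglas(sm)
    base %>% mutate(beta_E = e_fit$exponent, E0 = e_fit$prefactor,
                    beta_Area = area_fit$exponent, q = q_fit$q,
                    alpha_B = cd_fit$alpha_b,
                    hypermetric = e_fit$exponent > 1)
  }) %>% list_rbind()
}

#' Predicted-versus-observed plot
#'
#' Scatter of model predictions against observations with the bisectrix
#' (perfect-match) line, as used to assess the contagion activity law and
#' the composed metabolic prediction.
#'
#' @param data A data frame.
#' @param observed,predicted Columns (tidy-eval).
#' @param log_scale Plot on log-log axes.
#' @return A ggplot object.
#' @export
plot_prediction <- function(data, observed, predicted, log_scale = FALSE) {
  d <- tibble(observed = eval_tidy(enquo(observed), data),
              predicted = eval_tidy(enquo(predicted), data))
  p <- ggplot(d, aes(x = .data$predicted, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_point() +
    labs(x = "predicted", y = "observed") +
    theme_minimal()
  if (log_scale) p <- p + scale_x_log10() + scale_y_log10()
  p
}
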