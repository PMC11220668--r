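# Reverse-social-contagion model of activity regulation. Under complete
# mixing, each worker meets <k> = 2E/N others, active with probability A/N;
# active-active encounters (which deactivate one of the pair) then number
# <k> A^2 / N per unit of the balance. Equating this with spontaneous
# activation at rate q per worker and per worker available, <k> A^2 / N = qN,
# and using the interaction scaling E = E0 N^betaE gives the hypometric
# activity law A = sqrt(q / (2 E0)) * N^((3 - betaE)/2).

#' Active-active encounter statistic
#'
#' Adds the balance statistic `<k> A^2 / N` (mean degree times squared active
#' count over tracked count) to a summary table. Under the
#' reverse-social-contagion balance this statistic grows linearly with `N`
#' with slope `q`.
#'
#' @param summaries Per-colony summary tibble with columns `mean_degree`,
#'   `n_active`, `n_tracked` (as from [summarize_colonies()]).
#' @return The input with an added `balance` column.
#' @export
balance_statistic <- function(summaries) {
  if (any(summaries$n_tracked <= 0)) abort("n_tracked must be positive")
  summaries %>%
    mutate(balance = .data$mean_degree * .data$n_active^2 / .data$n_tracked)
}

#' Estimate the balance rate q
#'
#' Regresses the active-active encounter statistic `<k> A^2 / N` on the
#' tracked worker count `N` across colonies (raw-variable OLS); the slope is
#' the balance rate `q`. The default regression includes an intercept (whose
#' p-value diagnoses the balance's zero-intercept form); set
#' `zero_intercept = TRUE` for the model-faithful fit through the origin.
#'
#' @param summaries Per-colony summary tibble (>= 3 colonies).
#' @param zero_intercept Force the regression through the origin.
#' @return An object of class `contagion_fit`: the underlying [fit_linear()]
#'   object plus `q`. Has `tidy()`, `glance()` and `print()` methods.
#' @export
estimate_q <- function(summaries, zero_intercept = FALSE) {
  bal <- balance_statistic(summaries)
  fit <- fit_linear(bal, .data$n_tracked, .data$balance,
                    force_zero_intercept = zero_intercept)
  structure(list(fit = fit, q = fit$slope, zero_intercept = zero_intercept),
            class = "contagion_fit")
}

#' Contagion model parameters
#'
#' Bundles the balance rate `q` with the interaction-scaling parameters
#' (`E0`, `beta_E`) needed by [predict_active()] and
#' [predict_metabolic_rate()]. Hypometric activity scaling requires
#' `beta_E > 1`; a warning is issued otherwise.
#'
#' @param q Balance rate (> 0), e.g. from [estimate_q()].
#' @param e0 Interaction prefactor (> 0), e.g. the prefactor of a
#'   [fit_power_law()] of `E` on `N`.
#' @param beta_e Interaction scaling exponent.
#' @return An object of class `contagion_params`.
#' @export
contagion_params <- function(q, e0, beta_e) {
  if (q <= 0) abort("q must be positive")
  if (e0 <= 0) abort("e0 must be positive")
  if (beta_e <= 1) {
    warn("beta_e <= 1: activity will not scale hypometrically")
  }
  structure(list(q = q, e0 = e0, beta_e = beta_e), class = "contagion_params")
}

#' Predicted number of active workers
#'
#' Evaluates the contagion-balance activity law
#' `A(n) = sqrt(q / (2 E0)) * n^((3 - beta_E)/2)`.
#'
#' @param params A [contagion_params()] object.
#' @param n Colony size(s) (tracked worker count), >= 1.
#' @return Predicted active-worker count(s), same length as `n`.
#' @export
predict_active <- function(params, n) {
  stopifnot(inherits(params, "contagion_params"))
  if (any(n < 1)) abort("colony size n must be at least 1")
  sqrt(params$q / (2 * params$e0)) * n^((3 - params$beta_e) / 2)
}

#' Effective per-worker interaction area
#'
#' Mean-field estimate of the area within which a worker interacts: with
#' uniformly mixed workers in the spanned area, `E = N^2 a / (2 Area)`, so
#' the fitted prefactors give `a = 2 * Area0 * E0`. For context the result
#' is reported alongside the two limiting mean-field bounds: `pi d^2`
#' (complete inactivity) and `2 d L` (steady motion at path length `L`).
#'
#' @param area_fit Spanned-area scaling fit (a `power_law_fit`) or its
#'   prefactor `Area0` (mm^2).
#' @param e_fit Interaction scaling fit (a `power_law_fit`) or its prefactor
#'   `E0`.
#' @param d Interaction distance in mm (default 6).
#' @param path_length_mm Average per-worker path length `L` for the
#'   steady-motion bound, or `NULL` to omit it.
#' @return A tibble `a_mm2, bound_inactive_mm2, bound_motion_mm2`.
#' @export
effective_interaction_area <- function(area_fit, e_fit, d = 6,
                                       path_length_mm = NULL) {
  area0 <- if (inherits(area_fit, "power_law_fit")) area_fit$prefactor else area_fit
  e0 <- if (inherits(e_fit, "power_law_fit")) e_fit$prefactor else e_fit
  if (area0 < 0 || e0 < 0) abort("prefactors must be non-negative")
  tibble(a_mm2 = 2 * area0 * e0,
         bound_inactive_mm2 = pi * d^2,
         bound_motion_mm2 = if (is.null(path_length_mm)) NA_real_ else
           2 * d * path_length_mm)
}

#' @method tidy contagion_fit
#' @export
tidy.contagion_fit <- function(x, ...) tidy(x$fit)

#' @method glance contagion_fit
#' @export
glance.contagion_fit <- function(x, ...) {
  glance(x$fit) %>% rename(q = "slope")
}

#' @export
print.contagion_fit <- function(x, ...) {
  cat("Reverse-social-contagion balance fit\n")
  cat("  q (slope of <k>A²/N vs N) = ", signif(x$q, 4), "\n", sep = "")
  cat("  slope 95% CI: [", signif(x$fit$ci95_slope[1], 4), ", ",
      signif(x$fit$ci95_slope[2], 4), "]\n", sep = "")
  cat("  R^2 (raw) = ", signif(x$fit$r2_raw, 3),
      ", p(slope) = ", format.pval(x$fit$p_slope, digits = 3),
      if (!x$zero_intercept)
        paste0(", p(intercept) = ",
               format.pval(x$fit$p_intercept, digits = 3)),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.contagion_params <- function(x, ...) {
  cat("Contagion parameters: q = ", signif(x$q, 4), ", E0 = ",
      signif(x$e0, 4), ", beta_E = ", signif(x$beta_e, 4), "\n", sep = "")
  cat("  implied activity law: A = ", signif(sqrt(x$q / (2 * x$e0)), 4),
      " * N^", signif((3 - x$beta_e) / 2, 4), "\n", sep = "")
  invisible(x)
}
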