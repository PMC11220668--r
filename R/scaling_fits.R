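# Regression conventions used throughout: scaling (power) laws are fitted by
# OLS on natural-log-transformed variables, with R^2 computed on the log
# residuals; linear relations are fitted on raw variables with R^2 on raw
# residuals. 95% confidence intervals and two-sided p-values use the t
# distribution with the residual degrees of freedom (n - 2 with an intercept,
# so 14 for a 16-colony design).

#' Fit a power law y = Y0 * x^beta
#'
#' Ordinary least squares of `ln y` on `ln x`; the slope is the scaling
#' exponent and `exp(intercept)` the prefactor. Non-positive responses cannot
#' enter a log-space fit and are dropped with a warning.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval) holding the positive predictor and response.
#' @return An object of class `power_law_fit` with elements `exponent`,
#'   `prefactor`, `ci95_exponent`, `r2_log`, `p_slope`, `p_intercept`, `dof`,
#'   `n`, the underlying `lm` model, and the fitted data. Has [tidy()],
#'   [glance()], [autoplot()] and `print()` methods.
#' @examples
#' d <- tibble::tibble(n = c(1, 2, 4, 8), e = 2 * n^1.5)
#' fit_power_law(d, n, e)
#' @export
fit_power_law <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (any(xv <= 0)) abort("power-law fit requires strictly positive x")
  if (any(yv <= 0)) {
    warn(paste0("dropping ", sum(yv <= 0),
                " non-positive response value(s) from the log-space fit"))
    xv <- xv[yv > 0]; yv <- yv[yv > 0]
  }
  if (length(xv) < 3) abort("power-law fit needs at least 3 points")
  if (var(log(xv)) == 0) abort("x has zero variance on the log scale")
  model <- lm(log(yv) ~ log(xv))
  sm <- summary(model)
  ci <- confint(model, level = 0.95)
  structure(list(
    exponent = unname(coef(model)[2]),
    prefactor = exp(unname(coef(model)[1])),
    ci95_exponent = unname(ci[2, ]),
    ci95_prefactor = exp(unname(ci[1, ])),
    r2_log = sm$r.squared,
    p_slope = sm$coefficients[2, 4],
    p_intercept = sm$coefficients[1, 4],
    dof = model$df.residual,
    n = length(xv),
    model = model,
    data = tibble(x = xv, y = yv)
  ), class = "power_law_fit")
}

#' Fit a linear relation y = a + b x on raw variables
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval) holding predictor and response.
#' @param force_zero_intercept If `TRUE`, fit `y = b x` through the origin
#'   (residual dof `n - 1`).
#' @return An object of class `linear_fit` with `slope`, `intercept`,
#'   `ci95_slope`, `r2_raw`, `p_slope`, `p_intercept`, `dof`, `n`, the `lm`
#'   model, and the fitted data. Has [tidy()], [glance()], [autoplot()] and
#'   `print()` methods.
#' @export
fit_linear <- function(data, x, y, force_zero_intercept = FALSE) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) abort("linear fit needs at least 3 points")
  if (var(xv) == 0) abort("x has zero variance")
  model <- if (force_zero_intercept) lm(yv ~ xv - 1) else lm(yv ~ xv)
  sm <- summary(model)
  cf <- sm$coefficients
  ci <- confint(model, level = 0.95)
  if (force_zero_intercept) {
    slope <- unname(coef(model)[1])
    intercept <- 0
    ci_slope <- unname(ci[1, ])
    p_slope <- cf[1, 4]
    p_intercept <- NA_real_
  } else {
    slope <- unname(coef(model)[2])
    intercept <- unname(coef(model)[1])
    ci_slope <- unname(ci[2, ])
    p_slope <- cf[2, 4]
    p_intercept <- cf[1, 4]
  }
  structure(list(
    slope = slope, intercept = intercept, ci95_slope = ci_slope,
    r2_raw = sm$r.squared, p_slope = p_slope, p_intercept = p_intercept,
    dof = model$df.residual, n = length(xv), model = model,
    data = tibble(x = xv, y = yv)
  ), class = "linear_fit")
}

#' Coefficient of determination of a prediction
#'
#' `1 - SS_res / SS_tot` comparing observations with model predictions, on
#' raw or log-transformed values. Unlike a regression R^2 this can be
#' negative when the prediction does worse than the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @param log_scale If `TRUE`, compare on natural logs (all values must then
#'   be positive).
#' @return A scalar in `(-Inf, 1]`.
#' @export
prediction_r2 <- function(observed, predicted, log_scale = FALSE) {
  if (length(observed) != length(predicted)) {
    abort("observed and predicted must have equal length")
  }
  if (length(observed) < 2) abort("need at least 2 values")
  if (log_scale) {
    if (any(observed <= 0) || any(predicted <= 0)) {
      abort("log-scale comparison requires positive values")
    }
    observed <- log(observed)
    predicted <- log(predicted)
  }
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("ln_prefactor", "exponent"),
         estimate = unname(sm[, 1]),
         std.error = unname(sm[, 2]),
         statistic = unname(sm[, 3]),
         p.value = unname(sm[, 4]),
         conf.low = c(log(x$ci95_prefactor[1]), x$ci95_exponent[1]),
         conf.high = c(log(x$ci95_prefactor[2]), x$ci95_exponent[2]))
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(exponent = x$exponent, prefactor = x$prefactor,
         r.squared = x$r2_log, p.value = x$p_slope, df.residual = x$dof,
         nobs = x$n)
}

#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  terms <- if (nrow(sm) == 1) "slope" else c("intercept", "slope")
  ci <- confint(x$model)
  tibble(term = terms,
         estimate = unname(sm[, 1]),
         std.error = unname(sm[, 2]),
         statistic = unname(sm[, 3]),
         p.value = unname(sm[, 4]),
         conf.low = unname(ci[, 1]),
         conf.high = unname(ci[, 2]))
}

#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r.squared = x$r2_raw,
         p.value = x$p_slope, df.residual = x$dof, nobs = x$n)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law fit: y = ", signif(x$prefactor, 4), " * x^",
      signif(x$exponent, 4), "\n", sep = "")
  cat("  exponent 95% CI: [", signif(x$ci95_exponent[1], 4), ", ",
      signif(x$ci95_exponent[2], 4), "]\n", sep = "")
  cat("  R^2 (log) = ", signif(x$r2_log, 3), ", p(slope) = ",
      format.pval(x$p_slope, digits = 3), ", dof = ", x$dof, "\n", sep = "")
  invisible(x)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear fit: y = ", signif(x$intercept, 4), " + ",
      signif(x$slope, 4), " * x\n", sep = "")
  cat("  slope 95% CI: [", signif(x$ci95_slope[1], 4), ", ",
      signif(x$ci95_slope[2], 4), "]\n", sep = "")
  cat("  R^2 (raw) = ", signif(x$r2_raw, 3), ", p(slope) = ",
      format.pval(x$p_slope, digits = 3), ", dof = ", x$dof, "\n", sep = "")
  invisible(x)
}

#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  grid <- tibble(x = exp(seq(log(min(object$data$x)), log(max(object$data$x)),
                             length.out = 100)))
  pr <- stats::predict(object$model,
                       newdata = list(xv = grid$x),
                       interval = "confidence")
  grid <- grid %>% mutate(fit = exp(pr[, "fit"]), lwr = exp(pr[, "lwr"]),
                          upr = exp(pr[, "upr"]))
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_ribbon(data = grid, aes(x = .data$x, ymin = .data$lwr,
                                 ymax = .data$upr),
                inherit.aes = FALSE, alpha = 0.2) +
    geom_line(data = grid, aes(x = .data$x, y = .data$fit),
              inherit.aes = FALSE) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "x", y = "y",
         title = sprintf("y = %.3g x^%.3g (R² = %.2f)",
                         object$prefactor, object$exponent, object$r2_log)) +
    theme_minimal()
}

#' @method autoplot linear_fit
#' @export
autoplot.linear_fit <- function(object, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x),
                         length.out = 100))
  pr <- stats::predict(object$model, newdata = list(xv = grid$x),
                       interval = "confidence")
  grid <- grid %>% mutate(fit = pr[, "fit"], lwr = pr[, "lwr"],
                          upr = pr[, "upr"])
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_ribbon(data = grid, aes(x = .data$x, ymin = .data$lwr,
                                 ymax = .data$upr),
                inherit.aes = FALSE, alpha = 0.2) +
    geom_line(data = grid, aes(x = .data$x, y = .data$fit),
              inherit.aes = FALSE) +
    geom_point() +
    labs(x = "x", y = "y",
         title = sprintf("y = %.3g + %.3g x (R² = %.2f)",
                         object$intercept, object$slope, object$r2_raw)) +
    theme_minimal()
}
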