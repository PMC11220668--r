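# Cobb-Douglas metabolic model. Whole-colony metabolic rate is modelled as
# B = B0 * (A*)^alphaB * (I*)^(1 - alphaB), a degree-one homogeneous
# production function of the scaled active and inactive worker counts
# (A* = A N*/N rescales the tracked active count to the whole colony,
# I* = N* - A*). Fitted as the univariate regression
# ln(B/I*) = ln B0 + alphaB ln(A*/I*), which controls the multicollinearity
# of A* and I*.

#' Rescale active/inactive counts to the whole colony
#'
#' Adds (or recomputes) `a_star = n_active * n_total / n_tracked` and
#' `i_star = n_total - a_star`, so that untracked workers contribute to the
#' metabolic inputs in proportion to the tracked activity fraction.
#'
#' @param summaries Per-colony tibble with `n_active`, `n_total`, `n_tracked`.
#' @return The input with `a_star` and `i_star` columns.
#' @export
scale_counts <- function(summaries) {
  if (any(summaries$n_tracked <= 0)) abort("n_tracked must be positive")
  if (any(summaries$n_active > summaries$n_tracked)) {
    abort("n_active cannot exceed n_tracked")
  }
  summaries %>%
    mutate(a_star = .data$n_active * .data$n_total / .data$n_tracked,
           i_star = .data$n_total - .data$a_star)
}

#' Cobb-Douglas parameters
#'
#' @param b0 Baseline metabolic scale in mW (> 0).
#' @param alpha_b Elasticity of the active-worker input; a warning is issued
#'   outside (0, 1).
#' @return An object of class `cobb_douglas_params`.
#' @export
cobb_douglas_params <- function(b0, alpha_b) {
  if (b0 <= 0) abort("b0 must be positive")
  if (alpha_b <= 0 || alpha_b >= 1) {
    warn("alpha_b outside (0, 1): inputs are no longer complementary")
  }
  structure(list(b0 = b0, alpha_b = alpha_b), class = "cobb_douglas_params")
}

#' Evaluate the Cobb-Douglas metabolic rate
#'
#' @param params A [cobb_douglas_params()] object.
#' @param a_star,i_star Scaled active and inactive worker counts (> 0),
#'   vectorised.
#' @return Metabolic rate(s) `B0 * a_star^alpha_b * i_star^(1 - alpha_b)`
#'   in mW.
#' @export
cobb_douglas_rate <- function(params, a_star, i_star) {
  stopifnot(inherits(params, "cobb_douglas_params"))
  if (any(a_star <= 0) || any(i_star <= 0)) {
    abort("a_star and i_star must be positive")
  }
  params$b0 * a_star^params$alpha_b * i_star^(1 - params$alpha_b)
}

#' Fit the Cobb-Douglas metabolic function
#'
#' OLS of `ln(B / I*)` on `ln(A* / I*)`: the slope is the elasticity
#' `alpha_B` and `exp(intercept)` the baseline `B0`. Colonies with a zero
#' (or negative) count or rate cannot enter the log regression and are
#' dropped with a warning; at least 3 must remain.
#'
#' @param data A data frame.
#' @param a_star,i_star,rate Columns (tidy-eval) holding the scaled counts
#'   and the measured metabolic rate (mW). Defaults match the summary schema
#'   joined with colony metadata (`a_star`, `i_star`, `metabolic_rate_mW`).
#' @return An object of class `cobb_douglas_fit` with `alpha_b`, `b0`,
#'   `ci95_alpha`, `r2_log`, `p_slope`, `p_intercept`, `dof`, `n`, the `lm`
#'   model, and a `params` element ([cobb_douglas_params()]). Has `tidy()`,
#'   `glance()`, `autoplot()` and `print()` methods.
#' @export
fit_cobb_douglas <- function(data, a_star = .data$a_star,
                             i_star = .data$i_star,
                             rate = .data$metabolic_rate_mW) {
  av <- eval_tidy(enquo(a_star), data)
  iv <- eval_tidy(enquo(i_star), data)
  bv <- eval_tidy(enquo(rate), data)
  keep <- is.finite(av) & is.finite(iv) & is.finite(bv) &
    av > 0 & iv > 0 & bv > 0
  if (any(!keep)) {
    warn(paste0("dropping ", sum(!keep),
                " colony(ies) with non-positive counts or rate"))
  }
  av <- av[keep]; iv <- iv[keep]; bv <- bv[keep]
  if (length(av) < 3) abort("Cobb-Douglas fit needs at least 3 usable colonies")
  xr <- log(av / iv)
  if (var(xr) == 0) abort("degenerate regressor: A*/I* constant across colonies")
  model <- lm(log(bv / iv) ~ xr)
  sm <- summary(model)
  ci <- confint(model, level = 0.95)
  alpha_b <- unname(coef(model)[2])
  b0 <- exp(unname(coef(model)[1]))
  structure(list(
    alpha_b = alpha_b, b0 = b0,
    ci95_alpha = unname(ci[2, ]),
    ci95_b0 = exp(unname(ci[1, ])),
    r2_log = sm$r.squared,
    p_slope = sm$coefficients[2, 4],
    p_intercept = sm$coefficients[1, 4],
    dof = model$df.residual, n = length(av), model = model,
    params = cobb_douglas_params(b0, alpha_b),
    data = tibble(a_star = av, i_star = iv, rate = bv)
  ), class = "cobb_douglas_fit")
}

#' Marginal products of active and inactive workers
#'
#' The marginal product of an input is the change in colony metabolic rate
#' from one additional worker of that type, holding the other fixed:
#' `MP(A*) = alpha_B B / A*` and `MP(I*) = (1 - alpha_B) B / I*`, with `B`
#' the Cobb-Douglas rate at the given counts. By Euler's theorem for a
#' degree-one homogeneous function, `A* MP(A*) + I* MP(I*) = B`.
#'
#' @param params A [cobb_douglas_params()] object.
#' @param a_star,i_star Scaled worker counts (> 0), vectorised.
#' @return A tibble `a_star, i_star, rate_mW, mp_active, mp_inactive`
#'   (mW per worker).
#' @export
marginal_products <- function(params, a_star, i_star) {
  b <- cobb_douglas_rate(params, a_star, i_star)
  tibble(a_star = a_star, i_star = i_star, rate_mW = b,
         mp_active = params$alpha_b * b / a_star,
         mp_inactive = (1 - params$alpha_b) * b / i_star)
}

#' Predict colony metabolic rate from colony size
#'
#' Composes the contagion activity law with the Cobb-Douglas function:
#' `B(n) = B0 N* (q/(2 E0))^(alphaB/2) n^((1-betaE) alphaB / 2)
#' (1 - sqrt(q/(2 E0)) n^((1-betaE)/2))^(1-alphaB)`. This equals the
#' Cobb-Douglas rate evaluated at the scaled counts implied by
#' [predict_active()]. The model is only defined while the predicted active
#' fraction is below 1; smaller `n` raise an error rather than silently
#' clipping.
#'
#' @param cd A [cobb_douglas_params()] object.
#' @param cg A [contagion_params()] object.
#' @param n Tracked worker count(s).
#' @param n_total Total worker count(s) `N*` (default: equal to `n`).
#' @return Predicted metabolic rate(s) in mW.
#' @export
predict_metabolic_rate <- function(cd, cg, n, n_total = n) {
  stopifnot(inherits(cd, "cobb_douglas_params"),
            inherits(cg, "contagion_params"))
  if (any(n < 1)) abort("n must be at least 1")
  root <- sqrt(cg$q / (2 * cg$e0))
  bracket <- 1 - root * n^((1 - cg$beta_e) / 2)
  if (any(bracket <= 0)) {
    abort(paste0("predicted active fraction >= 1 at n = ",
                 paste(n[bracket <= 0], collapse = ", "),
                 ": the prediction is outside the model's domain"))
  }
  cd$b0 * n_total * root^cd$alpha_b * n^((1 - cg$beta_e) * cd$alpha_b / 2) *
    bracket^(1 - cd$alpha_b)
}

#' Derived metabolic scaling exponent
#'
#' Under the combined model, with mass proportional to worker count, colony
#' metabolic rate scales with mass as `B ~ M^((1 - beta_E) alpha_B / 2 + 1)`.
#' Hypermetric interaction scaling (`beta_E > 1`) therefore yields hypometric
#' (Kleiber-like) metabolic scaling; `beta_E = 1` gives isometry.
#'
#' @param cg A [contagion_params()] object (or a numeric `beta_E`).
#' @param cd A [cobb_douglas_params()] object (or a numeric `alpha_B`).
#' @return The scaling exponent of metabolic rate versus colony mass.
#' @export
derived_exponent <- function(cg, cd) {
  beta_e <- if (inherits(cg, "contagion_params")) cg$beta_e else cg
  alpha_b <- if (inherits(cd, "cobb_douglas_params")) cd$alpha_b else cd
  (1 - beta_e) * alpha_b / 2 + 1
}

#' @method tidy cobb_douglas_fit
#' @export
tidy.cobb_douglas_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("ln_b0", "alpha_b"),
         estimate = unname(sm[, 1]),
         std.error = unname(sm[, 2]),
         statistic = unname(sm[, 3]),
         p.value = unname(sm[, 4]),
         conf.low = c(log(x$ci95_b0[1]), x$ci95_alpha[1]),
         conf.high = c(log(x$ci95_b0[2]), x$ci95_alpha[2]))
}

#' @method glance cobb_douglas_fit
#' @export
glance.cobb_douglas_fit <- function(x, ...) {
  tibble(alpha_b = x$alpha_b, b0 = x$b0, r.squared = x$r2_log,
         p.value = x$p_slope, df.residual = x$dof, nobs = x$n)
}

#' @export
print.cobb_douglas_fit <- function(x, ...) {
  cat("Cobb-Douglas metabolic fit: B = ", signif(x$b0, 4),
      " * (A*)^", signif(x$alpha_b, 4),
      " * (I*)^", signif(1 - x$alpha_b, 4), "\n", sep = "")
  cat("  alpha_B 95% CI: [", signif(x$ci95_alpha[1], 4), ", ",
      signif(x$ci95_alpha[2], 4), "]\n", sep = "")
  cat("  R^2 (log) = ", signif(x$r2_log, 3), ", dof = ", x$dof, "\n", sep = "")
  invisible(x)
}

#' @export
print.cobb_douglas_params <- function(x, ...) {
  cat("Cobb-Douglas parameters: B0 = ", signif(x$b0, 4), " mW, alpha_B = ",
      signif(x$alpha_b, 4), "\n", sep = "")
  invisible(x)
}

#' @method autoplot cobb_douglas_fit
#' @export
autoplot.cobb_douglas_fit <- function(object, ...) {
  d <- object$data %>%
    mutate(ratio = .data$a_star / .data$i_star,
           per_inactive = .data$rate / .data$i_star)
  grid <- tibble(ratio = exp(seq(log(min(d$ratio)), log(max(d$ratio)),
                                 length.out = 100))) %>%
    mutate(fit = object$b0 * .data$ratio^object$alpha_b)
  ggplot(d, aes(x = .data$ratio, y = .data$per_inactive)) +
    geom_line(data = grid, aes(x = .data$ratio, y = .data$fit),
              inherit.aes = FALSE) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "A*/I*", y = "B/I* (mW per inactive worker)",
         title = sprintf("B = %.3g (A*)^%.2f (I*)^%.2f",
                         object$b0, object$alpha_b, 1 - object$alpha_b)) +
    theme_minimal()
}
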