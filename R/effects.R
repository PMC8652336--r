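#' Conditional indirect effects at a moderator value
#'
#' Because X moderates the second stage of its own mediated pathways, the
#' indirect effect through mediator i is conditional on the (centered)
#' moderator value x: `a1_i * (b1_i + c2_i' * x)`. At x = 0 this is the
#' indirect effect for a respondent at the sample-average level of X.
#'
#' @param fit A `modmed_fit`.
#' @param x Scalar centered moderator value (0 = sample mean of X).
#' @return List with `effects` (named per-mediator vector), `total` (their
#'   sum) and `x`.
#' @examples
#' fit <- fit_from_moments(survey_moments())
#' conditional_indirect(fit, 0)$effects     # -0.041, -0.108, -0.087
#' @export
conditional_indirect <- function(fit, x = 0) {
  stopifnot(inherits(fit, "modmed_fit"), length(x) == 1L, is.finite(x))
  med <- fit$spec$mediators
  eff <- fit$a1 * (fit$b[med] + fit$b[fit$spec$products] * x)
  names(eff) <- med
  list(effects = eff, total = sum(eff), x = x)
}

#' Direct effect of X on the outcome
#'
#' `c1' + sum(a0_i * c2_i')`: the coefficient on X plus the contribution of
#' the mediator intercepts through the interaction terms. With grand-mean
#' centered mediators all `a0_i = 0` and the direct effect is simply the X
#' coefficient.
#'
#' @param fit A `modmed_fit`.
#' @return Scalar direct effect.
#' @export
direct_effect <- function(fit) {
  stopifnot(inherits(fit, "modmed_fit"))
  unname(fit$b[fit$spec$x] + sum(fit$a0 * fit$b[fit$spec$products]))
}

#' Full effect decomposition
#'
#' Direct effect, per-mediator conditional indirect effects at each
#' requested moderator value, total indirect effects, the total effect at
#' x = 0, each pathway's percentage share of the total indirect effect, and
#' the indirect share of the total effect. Shares are computed from
#' unrounded estimates.
#'
#' @param fit A `modmed_fit`.
#' @param x_values Centered moderator values; default one sample SD of X
#'   below the mean, the mean, and one SD above.
#' @return Object of class `effect_estimates`: list with `conditional`
#'   (long data frame: x, mediator, effect), `total_indirect` (data frame:
#'   x, effect), `direct`, `total_effect` (at x = 0), `shares` (percent per
#'   mediator at x = 0), `indirect_share` (percent of the total effect),
#'   and `x_values`.
#' @examples
#' decomp <- effect_decomposition(fit_from_moments(survey_moments()))
#' decomp$total_effect   # about -0.34
#' @export
effect_decomposition <- function(fit, x_values = fit$sd_x * c(-1, 0, 1)) {
  stopifnot(inherits(fit, "modmed_fit"), length(x_values) >= 1L)
  med <- fit$spec$mediators
  rows <- lapply(x_values, function(x) {
    ci <- conditional_indirect(fit, x)
    data.frame(x = x, mediator = med, effect = unname(ci$effects))
  })
  conditional <- do.call(rbind, rows)
  total_ind <- data.frame(
    x = x_values,
    effect = vapply(x_values, function(x) conditional_indirect(fit, x)$total,
                    numeric(1))
  )
  at0 <- conditional_indirect(fit, 0)
  direct <- direct_effect(fit)
  total <- direct + at0$total
  structure(list(
    conditional = conditional,
    total_indirect = total_ind,
    direct = direct,
    total_effect = total,
    shares = 100 * at0$effects / at0$total,
    indirect_share = 100 * at0$total / total,
    x_values = x_values
  ), class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, digits = 3, ...) {
  cat("Effect decomposition\n")
  cat(sprintf("  direct effect:          %s\n", format(round(x$direct, digits))))
  at0 <- x$total_indirect$effect[match(0, x$total_indirect$x)]
  if (is.na(at0)) at0 <- x$total_effect - x$direct
  cat(sprintf("  total indirect (x = 0): %s\n", format(round(at0, digits))))
  cat(sprintf("  total effect (x = 0):   %s\n", format(round(x$total_effect, digits))))
  cat(sprintf("  indirect share:         %.1f%%\n", x$indirect_share))
  cat("\nConditional indirect effects:\n")
  wide <- stats::reshape(x$conditional, idvar = "mediator", timevar = "x",
                         direction = "wide")
  colnames(wide) <- sub("^effect\\.", "x = ", colnames(wide))
  wide[, -1] <- round(wide[, -1], digits)
  print(wide, row.names = FALSE)
  cat("\nPathway shares of the total indirect effect (x = 0): ",
      paste(sprintf("%s %.1f%%", names(x$shares), x$shares), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Simple intercept and slope of the reduced-form quadratic response
#'
#' Substituting the mediator equations into the outcome equation gives a
#' reduced form in which the coefficient of X is itself affine in X: the
#' simple slope `(c1' + sum a0_i c2_i') + sum a1_i (b1_i + c2_i' x)` — a
#' quadratic, not linear, moderation. This evaluates the simple intercept
#' `b0 + sum a0_i b1_i`, the simple slope, and the implied expected
#' outcome (residual means zero) over a grid of centered moderator values.
#'
#' @param fit A `modmed_fit`.
#' @param x_grid Nonempty numeric vector of centered moderator values.
#' @return Data frame: x, simple_intercept, simple_slope, predicted.
#' @export
quadratic_response <- function(fit, x_grid) {
  stopifnot(inherits(fit, "modmed_fit"))
  if (length(x_grid) == 0L) stop("x_grid must be nonempty")
  med <- fit$spec$mediators
  prod <- fit$spec$products
  intercept <- fit$b0 + sum(fit$a0 * fit$b[med])
  base_slope <- direct_effect(fit)
  slope <- base_slope + vapply(
    x_grid, function(x) conditional_indirect(fit, x)$total, numeric(1))
  data.frame(x = x_grid,
             simple_intercept = intercept,
             simple_slope = slope,
             predicted = intercept + slope * x_grid)
}

#' Plot data for the conditional-effect figures
#'
#' Tidy long-format table of the conditional indirect effect of each
#' pathway, the total indirect effect and the direct effect over a grid of
#' centered moderator values — the numbers behind moderated-mediation
#' figures; no rendering is done here.
#'
#' @param fit A `modmed_fit`.
#' @param x_grid Centered moderator grid; default 41 points spanning
#'   plus/minus one sample SD of X.
#' @return Data frame with columns x, path, effect.
#' @export
conditional_curve_data <- function(fit,
                                   x_grid = seq(-fit$sd_x, fit$sd_x,
                                                length.out = 41)) {
  stopifnot(inherits(fit, "modmed_fit"))
  if (length(x_grid) == 0L) stop("x_grid must be nonempty")
  med <- fit$spec$mediators
  rows <- lapply(x_grid, function(x) {
    ci <- conditional_indirect(fit, x)
    data.frame(x = x,
               path = c(med, "total_indirect", "direct"),
               effect = c(unname(ci$effects), ci$total, direct_effect(fit)))
  })
  do.call(rbind, rows)
}
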