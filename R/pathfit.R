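#' Model specification for the moderated parallel-mediation model
#'
#' Fixes the roles of the analysis columns: one outcome, one independent
#' variable X, k parallel mediators, and one product term per mediator
#' pairing X with that mediator (X moderates the second stage of its own
#' mediated pathways). Mediator residual covariances are left free; for
#' this saturated recursive system per-equation least squares coincides
#' with the joint maximum-likelihood point estimates.
#'
#' @param outcome Outcome column name.
#' @param x Independent-variable column name.
#' @param mediators Character vector of mediator column names.
#' @param products Product-term column names, one per mediator; default
#'   `paste0(x, mediators)`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome = "Y", x = "X",
                       mediators = c("M1", "M2", "M3"),
                       products = paste0(x, mediators)) {
  stopifnot(length(products) == length(mediators), length(mediators) >= 1L)
  structure(list(outcome = outcome, x = x, mediators = mediators,
                 products = products),
            class = "model_spec")
}

#' Fit the moderated mediation path model from summary moments
#'
#' Per-equation least squares computed directly from the correlation
#' matrix: standardized slopes solve `R_pp beta = r_py` for each equation,
#' unstandardized slopes rescale by `sd(outcome)/sd(predictor)`, and
#' intercepts come from the means. First stage: each mediator regressed on
#' X alone. Second stage: the outcome regressed on X, all mediators and all
#' X-by-mediator products. Classical homoskedastic least-squares standard
#' errors are derived from the moment-implied residual variance; the
#' bias-corrected bootstrap ([bootstrap_model()]) is the authoritative
#' uncertainty source for derived effects.
#'
#' @param moments A [summary_moments()] covering all model columns.
#' @param spec A [model_spec()].
#' @return Object of class `modmed_fit` with components
#'   \describe{
#'     \item{a0, a1}{first-stage intercepts and slopes per mediator, with
#'       `a1_se` and standardized `a1_std` (= the X-mediator correlation).}
#'     \item{b0, b}{second-stage intercept and named slope vector (X,
#'       mediators, products), with `b_se` and standardized `b_std`;
#'       products are standardized by the observed SD of the product
#'       column.}
#'     \item{pseudo_r2}{variance explained per equation (mediators and
#'       outcome).}
#'     \item{resid_var_y, resid_cov_m}{moment-implied residual variance of
#'       the outcome equation and residual covariance matrix of the
#'       mediators.}
#'     \item{sd_x}{sample SD of X, used as the default moderator step.}
#'   }
#' @examples
#' fit <- fit_from_moments(survey_moments())
#' fit$a1          # first-stage slopes
#' fit$b["X"]      # direct effect (centered mediators)
#' @export
fit_from_moments <- function(moments, spec = model_spec()) {
  stopifnot(inherits(moments, "summary_moments"))
  cols <- .model_cols(spec)
  missing_cols <- setdiff(cols, moments$columns)
  if (length(missing_cols))
    stop("moments are missing column(s): ", paste(missing_cols, collapse = ", "))
  R <- moments$corr[cols, cols]
  sds <- moments$sds[cols]
  means <- moments$means[cols]
  n <- moments$n
  y <- spec$outcome
  med <- spec$mediators
  pred <- c(spec$x, med, spec$products)
  if (n < length(pred) + 2)
    stop(sprintf("n = %d is too small for %d predictors", n, length(pred)))

  kappa_p <- rcond(R[pred, pred])
  if (!is.finite(kappa_p) || kappa_p < 1e-12)
    stop(sprintf("predictor correlation submatrix is numerically singular (rcond = %.3g)",
                 kappa_p))

  # first stage: Mi ~ X (single regressor)
  r_xm <- R[spec$x, med]
  a1 <- r_xm * sds[med] / sds[spec$x]
  a0 <- means[med] - a1 * means[spec$x]
  r2_m <- r_xm^2
  sigma2_m <- sds[med]^2 * (1 - r2_m) * (n - 1) / (n - 2)
  a1_se <- sqrt(sigma2_m / ((n - 1) * sds[spec$x]^2))

  # second stage: Y ~ X + M + XM
  beta <- solve(R[pred, pred], R[pred, y])
  b <- beta * sds[y] / sds[pred]
  b0 <- unname(means[y] - sum(b * means[pred]))
  r2_y <- sum(beta * R[pred, y])
  sigma2_y <- sds[y]^2 * (1 - r2_y) * (n - 1) / (n - length(pred) - 1)
  S_pp <- diag(sds[pred]) %*% R[pred, pred] %*% diag(sds[pred])
  Vinv <- solve(S_pp)
  b_se <- sqrt(diag(Vinv) * sigma2_y / (n - 1))
  names(b_se) <- pred
  b0_se <- sqrt(sigma2_y * (1 / n +
    drop(t(means[pred]) %*% Vinv %*% means[pred]) / (n - 1)))

  # residual covariances of the mediators (moment-implied, not used in
  # point estimation)
  S_mm <- diag(sds[med], nrow = length(med)) %*% R[med, med] %*%
    diag(sds[med], nrow = length(med))
  resid_cov_m <- S_mm - outer(a1, a1) * sds[spec$x]^2
  dimnames(resid_cov_m) <- list(med, med)

  fit <- structure(list(
    spec = spec,
    a0 = a0, a1 = a1, a1_se = a1_se, a1_std = r_xm,
    b0 = b0, b0_se = b0_se, b = b, b_se = b_se, b_std = beta,
    pseudo_r2 = c(r2_m, stats::setNames(r2_y, y)),
    resid_var_y = sds[y]^2 * (1 - r2_y),
    resid_cov_m = resid_cov_m,
    sd_x = unname(sds[spec$x]),
    sds = sds, means = means, n = n,
    moments = moments
  ), class = "modmed_fit")
  fit
}

#' Fit the moderated mediation path model from respondent-level data
#'
#' Centers X and the mediators, forms the product columns, computes the
#' sample moments and delegates to [fit_from_moments()]; the two routes
#' agree to machine precision by construction.
#'
#' @param data Raw scored data frame (or prepared model frame).
#' @param spec A [model_spec()].
#' @return A `modmed_fit`; see [fit_from_moments()].
#' @export
fit_from_raw <- function(data, spec = model_spec()) {
  fit_from_moments(compute_moments(data, spec), spec)
}

#' Standardized coefficients of a fit
#'
#' Each slope is rescaled by `sd(predictor)/sd(outcome)`; product terms use
#' the observed SD of the product column. First-stage standardized slopes
#' equal the X-mediator correlations.
#'
#' @param fit A `modmed_fit`.
#' @return List with `a1_std` and `b_std`.
#' @export
standardized_coefficients <- function(fit) {
  stopifnot(inherits(fit, "modmed_fit"))
  list(a1_std = fit$a1_std, b_std = fit$b_std)
}

#' Pseudo R-squared per structural equation
#'
#' Proportion of each endogenous variable's variance explained by its
#' equation: `1 - residual variance / outcome variance`, equivalently the
#' sum of standardized slopes times predictor-outcome correlations.
#'
#' @param fit A `modmed_fit`.
#' @return Named vector over the mediators and the outcome, each in `[0, 1]`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "modmed_fit"))
  fit$pseudo_r2
}

#' @export
print.modmed_fit <- function(x, digits = 3, ...) {
  spec <- x$spec
  cat(sprintf("Moderated parallel mediation fit (n = %d)\n", x$n))
  cat(sprintf("  outcome %s; X = %s; mediators: %s\n", spec$outcome, spec$x,
              paste(spec$mediators, collapse = ", ")))
  cat("\nFirst stage (X -> M):\n")
  tab1 <- data.frame(estimate = round(x$a1, digits),
                     se = round(x$a1_se, digits),
                     std = round(x$a1_std, digits))
  print(tab1)
  cat(sprintf("\nSecond stage (%s equation), intercept %s (%s):\n",
              spec$outcome, format(round(x$b0, digits)),
              format(round(x$b0_se, digits))))
  tab2 <- data.frame(estimate = round(x$b, digits),
                     se = round(x$b_se, digits),
                     std = round(x$b_std, digits))
  print(tab2)
  cat("\nPseudo R2: ",
      paste(sprintf("%s = %s", names(x$pseudo_r2),
                    format(round(x$pseudo_r2, digits))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Export a fit as a plain list (JSON-ready)
#'
#' Mirrors the published table layout: first stage, second stage,
#' standardized coefficients, residual (co)variances and pseudo R2.
#'
#' @param fit A `modmed_fit`.
#' @return A nested list suitable for `jsonlite::write_json`.
#' @export
fit_report <- function(fit) {
  list(
    n = fit$n,
    first_stage = list(estimate = as.list(fit$a1),
                       se = as.list(fit$a1_se),
                       standardized = as.list(fit$a1_std)),
    second_stage = list(intercept = fit$b0, intercept_se = fit$b0_se,
                        estimate = as.list(fit$b),
                        se = as.list(fit$b_se),
                        standardized = as.list(fit$b_std)),
    residual_variance_outcome = fit$resid_var_y,
    residual_covariance_mediators =
      lapply(seq_len(nrow(fit$resid_cov_m)),
             function(i) as.list(fit$resid_cov_m[i, ])),
    pseudo_r2 = as.list(fit$pseudo_r2),
    sd_x = fit$sd_x
  )
}
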