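#' Specification of the synthetic survey generator
#'
#' The generating model mirrors the structural equations: centered
#' X ~ Normal(0, sd_x^2); mediators M_i = a1_i * Xc + e_mi with jointly
#' Gaussian residuals whose covariance is solved from the target
#' inter-mediator correlations minus the X-induced common component; and
#' Y = b0 + c1' Xc + sum b1_i M_ic + sum c2_i' Xc M_ic + e_y with the
#' outcome residual variance solved from the target SD of Y (product-term
#' moments under normality enter in closed form). Defaults are calibrated
#' to the published survey: its path coefficients, means and SDs at
#' n = 2,133, so the generator's default output emulates the study
#' population.
#'
#' @param n Sample size.
#' @param mean_x,sd_x Mean and SD of the independent variable (PsyCap
#'   scale, 26-130).
#' @param mean_m Raw means of the three mediators.
#' @param a1 First-stage slopes.
#' @param b1 Second-stage mediator slopes.
#' @param c1 Direct-effect coefficient of centered X.
#' @param c2 Interaction (X-by-mediator) coefficients.
#' @param b0 Outcome-equation intercept.
#' @param sd_m Target SDs of the mediators.
#' @param sd_y Target SD of the outcome.
#' @param cor_m Target inter-mediator correlations, order (1,2), (1,3),
#'   (2,3).
#' @return Object of class `synthetic_spec`; construction fails if the
#'   implied mediator residual covariance is not positive semi-definite or
#'   the implied outcome residual variance is negative.
#' @export
synthetic_spec <- function(n = 2133L,
                           mean_x = 90.364, sd_x = 13.111,
                           mean_m = c(M1 = 24.635, M2 = 17.235, M3 = 16.038),
                           a1 = c(M1 = 0.160, M2 = 0.124, M3 = 0.076),
                           b1 = c(M1 = -0.254, M2 = -0.874, M3 = -1.138),
                           c1 = -0.103,
                           c2 = c(M1 = -0.013, M2 = 0.002, M3 = 0.030),
                           b0 = 40.752,
                           sd_m = c(M1 = 6.315, M2 = 3.746, M3 = 3.014),
                           sd_y = 13.487,
                           cor_m = c(0.262, 0.371, 0.381)) {
  k <- length(a1)
  stopifnot(k == length(b1), k == length(c2), k == length(sd_m),
            k == length(mean_m), length(cor_m) == k * (k - 1) / 2,
            sd_x > 0, all(sd_m > 0), sd_y > 0, n >= 10)
  med <- paste0("M", seq_len(k))
  a1 <- stats::setNames(as.numeric(a1), med)
  b1 <- stats::setNames(as.numeric(b1), med)
  c2 <- stats::setNames(as.numeric(c2), med)
  sd_m <- stats::setNames(as.numeric(sd_m), med)
  mean_m <- stats::setNames(as.numeric(mean_m), med)

  R_m <- diag(k)
  R_m[lower.tri(R_m)] <- cor_m
  R_m <- R_m + t(R_m) - diag(k)
  S_m <- diag(sd_m, k) %*% R_m %*% diag(sd_m, k)
  resid_cov_m <- S_m - outer(a1, a1) * sd_x^2
  dimnames(resid_cov_m) <- list(med, med)
  ev <- eigen(resid_cov_m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("implied mediator residual covariance is not positive semi-definite (min eigenvalue %.4g)",
                 min(ev)))

  # Var(Y) = Var(linear part) + Var(quadratic part) + resid_y under joint
  # normality of (Xc, M): the linear and product parts are uncorrelated
  # (odd moments vanish)
  cov_xm <- a1 * sd_x^2
  S_lin <- rbind(c(sd_x^2, cov_xm), cbind(cov_xm, S_m))
  w <- c(c1, b1)
  var_lin <- drop(t(w) %*% S_lin %*% w)
  cov_prod <- sd_x^2 * S_m + outer(cov_xm, cov_xm)  # Cov(XMi, XMj), Isserlis
  var_quad <- drop(t(c2) %*% cov_prod %*% c2)
  resid_var_y <- sd_y^2 - var_lin - var_quad
  if (resid_var_y < -1e-8)
    stop(sprintf("target SD of Y (%.3f) is below the SD implied by the structural part (%.3f)",
                 sd_y, sqrt(var_lin + var_quad)))
  resid_var_y <- max(resid_var_y, 0)

  structure(list(n = as.integer(n), mean_x = mean_x, sd_x = sd_x,
                 mean_m = mean_m, a1 = a1, b1 = b1, c1 = c1, c2 = c2,
                 b0 = b0, sd_m = sd_m, sd_y = sd_y, cor_m = cor_m,
                 mediators = med,
                 resid_cov_m = resid_cov_m, resid_var_y = resid_var_y,
                 cov_xm = cov_xm, cov_prod = cov_prod),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> n = %d, %d mediators; resid var(Y) = %.3f\n",
              x$n, length(x$mediators), x$resid_var_y))
  invisible(x)
}

#' Population moments implied by a synthetic specification
#'
#' Closed-form means, SDs and correlations of (Y, Xc, M_1c..M_kc,
#' XM_1..XM_k) under the Gaussian generating model, including the
#' product-term moments (`Var(XM_i) = Var(X) Var(M_i) + Cov(X, M_i)^2` and
#' the corresponding Isserlis cross-covariances). Sample moments of
#' [simulate_raw()] output converge to these as n grows.
#'
#' @param spec A [synthetic_spec()].
#' @return A [summary_moments()] with `n = spec$n`.
#' @export
implied_moments <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- length(spec$mediators)
  med <- spec$mediators
  prods <- paste0("XM", seq_len(k))
  cols <- c("Y", "X", med, prods)
  p <- length(cols)

  S <- matrix(0, p, p, dimnames = list(cols, cols))
  S["X", "X"] <- spec$sd_x^2
  S["X", med] <- S[med, "X"] <- spec$cov_xm
  R_m <- diag(k); R_m[lower.tri(R_m)] <- spec$cor_m
  R_m <- R_m + t(R_m) - diag(k)
  S[med, med] <- diag(spec$sd_m, k) %*% R_m %*% diag(spec$sd_m, k)
  S[prods, prods] <- spec$cov_prod
  # Cov(X, XMi) and Cov(Mi, XMj) are third central moments: zero under
  # normality
  S["Y", "X"] <- S["X", "Y"] <-
    spec$c1 * spec$sd_x^2 + sum(spec$b1 * spec$cov_xm)
  S["Y", med] <- S[med, "Y"] <-
    spec$c1 * spec$cov_xm + drop(S[med, med] %*% spec$b1)
  S["Y", prods] <- S[prods, "Y"] <- drop(spec$cov_prod %*% spec$c2)
  S["Y", "Y"] <- spec$sd_y^2

  means <- c(Y = spec$b0 + sum(spec$c2 * spec$cov_xm),
             stats::setNames(rep(0, 1 + k), c("X", med)),
             stats::setNames(spec$cov_xm, prods))
  sds <- sqrt(diag(S))
  corr <- S / outer(sds, sds)
  diag(corr) <- 1
  summary_moments(cols, means[cols], sds, corr, spec$n,
                  raw_means = c(X = spec$mean_x, spec$mean_m))
}

#' Simulate respondent-level scale scores
#'
#' Draws `spec$n` respondents from the Gaussian generating model and
#' returns a prepared model frame: raw-scale Y, X, M1..Mk plus
#' sample-centered variants and product columns (centering is done on the
#' simulated sample, exactly as for real data). The same seed reproduces
#' the same dataset.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed.
#' @return A model frame (see [prepare_model_frame()]).
#' @export
simulate_raw <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  k <- length(spec$mediators)
  xc <- stats::rnorm(n, 0, spec$sd_x)
  em <- MASS::mvrnorm(n, rep(0, k), spec$resid_cov_m)
  mc <- outer(xc, spec$a1) + em
  ey <- stats::rnorm(n, 0, sqrt(spec$resid_var_y))
  y <- spec$b0 + spec$c1 * xc + drop(mc %*% spec$b1) +
    drop((xc * mc) %*% spec$c2) + ey
  raw <- data.frame(Y = y, X = xc + spec$mean_x)
  for (i in seq_len(k)) raw[[spec$mediators[i]]] <- mc[, i] + spec$mean_m[i]
  prepare_model_frame(raw, model_spec(mediators = spec$mediators))
}

# number of ways to write s as a sum of k integers each in 1..points;
# counts as doubles (ratios only are needed for sampling)
.composition_counts <- function(k_max, points) {
  counts <- matrix(0, nrow = k_max * points, ncol = k_max)
  counts[1:points, 1] <- 1
  for (k in seq_len(k_max - 1L)) {
    for (v in seq_len(points)) {
      src <- seq_len(k * points)
      counts[src + v, k + 1L] <- counts[src + v, k + 1L] + counts[src, k]
    }
  }
  counts
}

# uniformly sample, for each score in `scores`, one composition into k
# items each in 1..points; returns an n x k integer matrix
.sample_compositions <- function(scores, k, points) {
  n <- length(scores)
  if (any(scores < k | scores > k * points))
    stop(sprintf("score outside feasible range [%d, %d] for %d items",
                 k, k * points, k))
  counts <- .composition_counts(k, points)
  out <- matrix(0L, n, k)
  rem <- as.integer(scores)
  for (j in seq_len(k)) {
    m <- k - j  # items remaining after this one
    if (m == 0L) {
      out[, j] <- rem
      break
    }
    for (s in unique(rem)) {
      idx <- which(rem == s)
      vals <- seq_len(points)
      w <- numeric(points)
      ok <- s - vals >= m & s - vals <= m * points
      w[ok] <- counts[s - vals[ok], m]
      if (sum(w) <= 0) stop("internal error: no feasible item value")
      out[idx, j] <- sample.int(points, length(idx), replace = TRUE, prob = w)
    }
    rem <- rem - out[, j]
  }
  out
}

#' Simulate item-level responses consistent with given scale scores
#'
#' For each respondent and instrument, draws item responses uniformly at
#' random among all integer compositions of the (rounded, range-clamped)
#' score across the instrument's items, then emits reverse-coded items in
#' reversed polarity — so running the scoring pipeline
#' ([score_instruments()]) on the output returns the input scores exactly.
#'
#' @param scores Data frame with columns Y, X, M1, M2, M3 (e.g. from
#'   [simulate_raw()]); non-integer scores are rounded and clamped to each
#'   instrument's range.
#' @param definitions Instrument definitions with `model_roles`; defaults
#'   to [default_instruments()].
#' @param seed Optional integer seed.
#' @return Data frame of item responses (plus `id`), one column per item.
#' @export
simulate_items <- function(scores, definitions = default_instruments(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roles <- attr(definitions, "model_roles")
  if (is.null(roles)) stop("definitions must carry a model_roles attribute")
  out <- data.frame(id = seq_len(nrow(scores)))
  for (nm in names(definitions)) {
    def <- definitions[[nm]]
    col <- roles[[nm]]
    if (!col %in% colnames(scores))
      stop(sprintf("scores are missing column '%s' for instrument '%s'",
                   col, nm))
    s <- pmin(pmax(round(scores[[col]]), def$range[1]), def$range[2])
    items <- .sample_compositions(s, length(def$items), def$points)
    colnames(items) <- def$items
    rev_idx <- match(def$reversed, def$items)
    if (length(rev_idx))
      items[, rev_idx] <- def$points + 1L - items[, rev_idx]
    out <- cbind(out, as.data.frame(items))
  }
  out
}
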