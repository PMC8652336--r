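#' Bias-corrected bootstrap confidence interval
#'
#' Percentile interval with the normal-quantile bias correction and no
#' acceleration term. The bias-correction constant is
#' `z0 = qnorm(P(replicate < point))`, ties counted with half weight; the
#' interval endpoints are the `pnorm(2*z0 + z_alpha)` and
#' `pnorm(2*z0 + z_(1-alpha))` quantiles of the replicate distribution,
#' with linear interpolation between order statistics. When no (or every)
#' replicate falls below the point estimate, z0 is clamped using the
#' continuity correction `1/(2B)` with a warning; identical replicates
#' yield the degenerate interval `[v, v]` with a warning.
#'
#' @param replicates Numeric vector of bootstrap replicates.
#' @param point Full-sample point estimate.
#' @param level Confidence level in (0, 1).
#' @return Length-2 numeric vector `c(lo, hi)`.
#' @export
bc_interval <- function(replicates, point, level = 0.99) {
  replicates <- replicates[is.finite(replicates)]
  B <- length(replicates)
  if (B < 2L) stop("need at least 2 replicates")
  stopifnot(level > 0, level < 1)
  if (max(replicates) - min(replicates) <= .Machine$double.eps * max(1, abs(point))) {
    warning("all replicates identical; interval is degenerate")
    return(c(replicates[1], replicates[1]))
  }
  p0 <- (sum(replicates < point) + 0.5 * sum(replicates == point)) / B
  if (p0 <= 0) {
    warning("no replicates below the point estimate; clamping bias correction")
    p0 <- 1 / (2 * B)
  } else if (p0 >= 1) {
    warning("all replicates below the point estimate; clamping bias correction")
    p0 <- 1 - 1 / (2 * B)
  }
  z0 <- stats::qnorm(p0)
  a <- (1 - level) / 2
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(a, 1 - a)))
  unname(stats::quantile(replicates, probs, type = 7))
}

# least-squares refit on raw column vectors; returns the structural
# coefficients only (the bootstrap hot path, no data.frame overhead)
.fast_fit <- function(yv, xv, mm) {
  xc <- xv - mean(xv)
  mc <- sweep(mm, 2L, colMeans(mm))
  a1 <- drop(crossprod(xc, mc)) / sum(xc^2)
  P <- cbind(xc, mc, xc * mc)
  pm <- colMeans(P)
  Pc <- sweep(P, 2L, pm)
  b <- drop(solve(crossprod(Pc), crossprod(Pc, yv - mean(yv))))
  list(a1 = a1, b = b, b0 = mean(yv) - sum(b * pm))
}

# estimand vector from .fast_fit coefficients; sd0 is the full-sample SD
# of X, frozen across replicates so every replicate estimates the same
# functionals
.estimands <- function(coefs, spec, sd0) {
  k <- length(spec$mediators)
  a1 <- coefs$a1
  b1 <- coefs$b[1 + seq_len(k)]
  c2 <- coefs$b[1 + k + seq_len(k)]
  direct <- coefs$b[1]
  xs <- c(mSD = -sd0, `0` = 0, pSD = sd0)
  ind <- outer(a1, xs, function(a, x) a) * (b1 + outer(c2, xs, `*`))
  tot <- colSums(ind)
  out <- c(coefs$a1, coefs$b, coefs$b0, as.vector(ind), tot, direct,
           tot[["0"]] + direct)
  names(out) <- c(paste0("a1_", spec$mediators),
                  paste0("b_", c(spec$x, spec$mediators, spec$products)),
                  "b0",
                  paste0("ind_", rep(spec$mediators, 3), "_",
                         rep(names(xs), each = k)),
                  paste0("total_ind_", names(xs)),
                  "direct", "total_effect")
  out
}

#' Bootstrap the full fitting pipeline
#'
#' Draws B resamples of respondents (rows, i.i.d. with replacement, size
#' n), refits the path model on each — recentering and reforming the
#' product terms within the resample — and recomputes every estimand: all
#' structural coefficients, the per-mediator conditional indirect effects
#' at one sample SD of X below the mean, at the mean, and one SD above
#' (SD frozen at the full-sample value), the total indirect effects, the
#' direct effect and the total effect. Bias-corrected intervals are
#' attached per estimand; resamples with a singular refit are dropped and
#' counted, and more than 5 percent of failures aborts.
#'
#' @param data Raw respondent-level scored data (summary moments cannot be
#'   resampled).
#' @param spec A [model_spec()].
#' @param B Number of bootstrap replicates (published analysis: 1,000).
#' @param level Confidence level (published analysis: 0.99).
#' @param seed Optional integer seed; fixing it makes the result
#'   reproducible.
#' @return Object of class `modmed_boot`: list with `points` (named
#'   estimand vector), `replicates` (B-row matrix), `intervals` (data
#'   frame: estimand, point, se, lo, hi, excludes_zero), `settings`, and
#'   `failed` (dropped replicate count).
#' @export
bootstrap_model <- function(data, spec = model_spec(), B = 1000L,
                            level = 0.99, seed = NULL) {
  stopifnot(B >= 2L, level > 0, level < 1)
  need <- c(spec$outcome, spec$x, spec$mediators)
  missing_cols <- setdiff(need, colnames(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  yv <- as.numeric(data[[spec$outcome]])
  xv <- as.numeric(data[[spec$x]])
  mm <- as.matrix(data[, spec$mediators, drop = FALSE])
  n <- length(yv)
  sd0 <- stats::sd(xv)
  if (!is.null(seed)) set.seed(seed)

  points <- .estimands(.fast_fit(yv, xv, mm), spec, sd0)
  reps <- matrix(NA_real_, nrow = B, ncol = length(points),
                 dimnames = list(NULL, names(points)))
  failed <- 0L
  for (r in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      .estimands(.fast_fit(yv[idx], xv[idx], mm[idx, , drop = FALSE]),
                 spec, sd0),
      error = function(e) NULL)
    if (is.null(est)) failed <- failed + 1L else reps[r, ] <- est
  }
  if (failed > 0.05 * B)
    stop(sprintf("%d of %d bootstrap refits failed (> 5%%)", failed, B))
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]

  ints <- t(vapply(names(points), function(nm)
    bc_interval(reps[, nm], points[[nm]], level), numeric(2)))
  intervals <- data.frame(
    estimand = names(points),
    point = unname(points),
    se = apply(reps, 2, stats::sd),
    lo = ints[, 1], hi = ints[, 2],
    excludes_zero = ints[, 1] > 0 | ints[, 2] < 0,
    row.names = NULL)
  structure(list(points = points, replicates = reps, intervals = intervals,
                 settings = list(B = as.integer(B), level = level,
                                 seed = seed, n = n, sd_x = sd0),
                 failed = failed),
            class = "modmed_boot")
}

#' @export
print.modmed_boot <- function(x, digits = 3, ...) {
  cat(sprintf("Bias-corrected bootstrap: B = %d, level = %s, n = %d (%d failed refits)\n",
              x$settings$B, format(x$settings$level), x$settings$n, x$failed))
  tab <- x$intervals
  tab[, c("point", "se", "lo", "hi")] <-
    round(tab[, c("point", "se", "lo", "hi")], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pairwise contrasts between mediated pathways
#'
#' Replicate-wise differences of the per-mediator conditional indirect
#' effects at a common moderator value, with BC intervals and the bootstrap
#' SE (replicate standard deviation). Contrasts are antisymmetric:
#' `d(i, j) = -d(j, i)`.
#'
#' @param result A `modmed_boot`.
#' @param at Moderator value label: `"0"`, `"mSD"` or `"pSD"`.
#' @return Data frame: pair, point difference, se, lo, hi, excludes_zero.
#' @export
contrast_mediators <- function(result, at = "0") {
  stopifnot(inherits(result, "modmed_boot"))
  at <- match.arg(at, c("0", "mSD", "pSD"))
  med <- grep(paste0("^ind_.*_", at, "$"), colnames(result$replicates),
              value = TRUE)
  labels <- sub(paste0("^ind_(.*)_", at, "$"), "\\1", med)
  pairs <- utils::combn(seq_along(med), 2)
  level <- result$settings$level
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- result$replicates[, med[i]] - result$replicates[, med[j]]
    pt <- result$points[[med[i]]] - result$points[[med[j]]]
    ci <- bc_interval(d, pt, level)
    data.frame(pair = paste(labels[i], "-", labels[j]),
               point = pt, se = stats::sd(d), lo = ci[1], hi = ci[2],
               excludes_zero = ci[1] > 0 | ci[2] < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delta-method (Sobel) standard error of a simple indirect effect
#'
#' `sqrt(a^2 SE_b^2 + b^2 SE_a^2)` for the product a*b of the two stage
#' coefficients of one mediator — the normal-theory baseline that the
#' bootstrap replaces, since the product of two estimates is generally not
#' normal in finite samples.
#'
#' @param fit A `modmed_fit`.
#' @param mediator Mediator name.
#' @return Scalar standard error.
#' @export
sobel_se <- function(fit, mediator) {
  stopifnot(inherits(fit, "modmed_fit"),
            mediator %in% fit$spec$mediators)
  a <- fit$a1[[mediator]]; se_a <- fit$a1_se[[mediator]]
  b <- fit$b[[mediator]]; se_b <- fit$b_se[[mediator]]
  sqrt(a^2 * se_b^2 + b^2 * se_a^2)
}
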