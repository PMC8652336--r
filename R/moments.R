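#' Summary moments of the analysis variables
#'
#' The complete information set needed to fit the path model: means,
#' standard deviations and the correlation matrix of the outcome, the
#' (centered) predictor and mediators, and the product terms, together with
#' the sample size. Published correlation tables can be encoded directly
#' (see [survey_moments()]), so the model is fittable without access to the
#' raw survey responses.
#'
#' Means are on the analysis scale: 0 for grand-mean-centered X and
#' mediators, the raw mean for Y, and the (nonzero) means of the products
#' of centered factors, which equal the factor covariances up to the
#' `n` vs `n-1` denominator. Raw (uncentered) means may be carried in
#' `raw_means` for reporting.
#'
#' @param columns Character vector of column names.
#' @param means Named or positional numeric vector of analysis-scale means.
#' @param sds Positive standard deviations (denominator n-1).
#' @param corr Symmetric correlation matrix with unit diagonal, positive
#'   semi-definite within tolerance.
#' @param n Sample size (at least 3; [fit_from_moments()] additionally
#'   requires n to exceed its predictor count by 2).
#' @param raw_means Optional named vector of uncentered means.
#' @return Object of class `summary_moments`.
#' @export
summary_moments <- function(columns, means, sds, corr, n, raw_means = NULL) {
  p <- length(columns)
  stopifnot(length(means) == p, length(sds) == p,
            is.matrix(corr), all(dim(corr) == p))
  if (any(sds <= 0)) stop("all SDs must be positive")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("correlation matrix must have unit diagonal")
  if (any(abs(corr) > 1 + 1e-8)) stop("correlations must lie in [-1, 1]")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
                 min(ev)))
  if (n < 3) stop("sample size must be at least 3")
  means <- stats::setNames(as.numeric(means), columns)
  sds <- stats::setNames(as.numeric(sds), columns)
  dimnames(corr) <- list(columns, columns)
  structure(list(columns = columns, means = means, sds = sds,
                 corr = corr, n = as.integer(n), raw_means = raw_means),
            class = "summary_moments")
}

#' @export
print.summary_moments <- function(x, ...) {
  cat(sprintf("<summary_moments> %d columns, n = %d\n",
              length(x$columns), x$n))
  tab <- data.frame(mean = round(x$means, 3), sd = round(x$sds, 3))
  print(tab)
  invisible(x)
}

#' Covariance matrix implied by a summary_moments object
#' @param moments A [summary_moments()] object.
#' @return Covariance matrix `diag(sds) %*% corr %*% diag(sds)`.
#' @export
moments_cov <- function(moments) {
  d <- diag(moments$sds)
  s <- d %*% moments$corr %*% d
  dimnames(s) <- dimnames(moments$corr)
  s
}

.model_cols <- function(spec) {
  c(spec$outcome, spec$x, spec$mediators, spec$products)
}

#' Prepare a scored dataset for model fitting
#'
#' Grand-mean centers the predictor and the mediators and forms the
#' product (interaction) columns from the centered factors. The input must
#' contain raw columns Y, X, M1, ..., Mk (names per `spec`); the output
#' carries the raw columns plus `Xc`, `M1c`, ... and `XM1`, ... with the
#' centering means stored in attribute `"centers"`.
#'
#' @param data Data frame with the raw scored columns.
#' @param spec A [model_spec()].
#' @return The augmented data frame (a "model frame" accepted by
#'   [compute_moments()] and [fit_from_raw()]).
#' @export
prepare_model_frame <- function(data, spec = model_spec()) {
  need <- c(spec$outcome, spec$x, spec$mediators)
  missing_cols <- setdiff(need, colnames(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  centers <- numeric(0)
  xc <- center_grand_mean(data[[spec$x]])
  centers[spec$x] <- attr(xc, "center")
  data[[paste0(spec$x, "c")]] <- as.numeric(xc)
  for (m in spec$mediators) {
    mc <- center_grand_mean(data[[m]])
    centers[m] <- attr(mc, "center")
    data[[paste0(m, "c")]] <- as.numeric(mc)
  }
  for (i in seq_along(spec$mediators)) {
    data[[spec$products[i]]] <-
      data[[paste0(spec$x, "c")]] * data[[paste0(spec$mediators[i], "c")]]
  }
  attr(data, "centers") <- centers
  attr(data, "model_spec") <- spec
  data
}

#' Compute summary moments of a scored dataset
#'
#' Means, SDs (denominator n-1) and correlations over the outcome, the
#' centered predictor and mediators, and the product columns — the summary
#' table from which [fit_from_moments()] reproduces the raw-data fit
#' exactly.
#'
#' @param data A model frame from [prepare_model_frame()], or a raw scored
#'   data frame (it is prepared automatically).
#' @param spec A [model_spec()].
#' @return A [summary_moments()] object; `raw_means` holds the uncentered
#'   means of X and the mediators.
#' @export
compute_moments <- function(data, spec = model_spec()) {
  if (is.null(attr(data, "centers"))) data <- prepare_model_frame(data, spec)
  if (nrow(data) < 3L) stop("need at least 3 rows to compute moments")
  centered <- c(paste0(spec$x, "c"), paste0(spec$mediators, "c"))
  cols_in <- c(spec$outcome, centered, spec$products)
  m <- as.matrix(data[, cols_in, drop = FALSE])
  colnames(m) <- .model_cols(spec)
  centers <- attr(data, "centers")
  summary_moments(
    columns = colnames(m),
    means = colMeans(m),
    sds = apply(m, 2, stats::sd),
    corr = stats::cor(m),
    n = nrow(m),
    raw_means = centers
  )
}

#' Write / read summary moments as JSON
#'
#' The on-disk schema stores the lower triangle of the correlation matrix
#' row-major (including the unit diagonal), so published correlation
#' tables can be transcribed directly.
#'
#' @param moments A [summary_moments()] object.
#' @param path File path.
#' @return `read_moments` returns a [summary_moments()]; `write_moments`
#'   returns `path` invisibly.
#' @export
write_moments <- function(moments, path) {
  lt <- moments$corr[lower.tri(moments$corr, diag = TRUE)]
  # row-major lower triangle
  idx <- which(lower.tri(diag(length(moments$columns)), diag = TRUE),
               arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  obj <- list(columns = moments$columns,
              means = unname(moments$means),
              sds = unname(moments$sds),
              corr_lower = unname(lt[ord]),
              n = moments$n)
  if (!is.null(moments$raw_means))
    obj$raw_means <- as.list(moments$raw_means)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$columns)
  corr <- diag(p)
  k <- 1L
  for (i in seq_len(p)) for (j in seq_len(i)) {
    corr[i, j] <- corr[j, i] <- obj$corr_lower[k]
    k <- k + 1L
  }
  raw_means <- if (!is.null(obj$raw_means)) unlist(obj$raw_means) else NULL
  summary_moments(obj$columns, obj$means, obj$sds, corr, obj$n,
                  raw_means = raw_means)
}

#' Published summary moments of the college-student survey
#'
#' The packaged summary statistics (n = 2,133) of the survey behind the
#' moderated mediation analysis: IAT total (Y), centered PsyCap (X),
#' centered emotional / learning / interpersonal adaptation (M1-M3), and
#' the three centered product terms, with the full printed correlation
#' matrix. Fitting the model from this object reproduces the published
#' path coefficients and effect decomposition.
#'
#' @return A [summary_moments()] object.
#' @examples
#' fit <- fit_from_moments(survey_moments())
#' conditional_indirect(fit, 0)
#' @export
survey_moments <- function() {
  read_moments(system.file("extdata", "survey_moments.json",
                           package = "modmedpath", mustWork = TRUE))
}
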