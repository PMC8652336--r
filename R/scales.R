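#' Define a summed Likert instrument
#'
#' A scale definition names the item columns of an instrument, the subset
#' that is reverse-coded, and the per-item response range. The score is the
#' sum of the (recoded) items, so the attainable score range is
#' `[k_items, k_items * points]` for items answered on a 1..points scale.
#'
#' @param name Instrument label, e.g. `"iat"`.
#' @param items Character vector of item column names, in order.
#' @param reversed Character vector naming the reverse-coded items; must be a
#'   subset of `items`.
#' @param points Number of response points per item (5 for all default
#'   instruments).
#' @param range Optional declared score range `c(min, max)`; checked against
#'   the range implied by `items` and `points`.
#' @return An object of class `scale_definition`.
#' @examples
#' scale_def("emoada", paste0("emo_", 1:8), reversed = paste0("emo_", 1:8))
#' @export
scale_def <- function(name, items, reversed = character(), points = 5L,
                      range = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(items), length(items) >= 1L,
            !anyDuplicated(items))
  if (!all(reversed %in% items))
    stop("reversed items not in item list: ",
         paste(setdiff(reversed, items), collapse = ", "))
  implied <- c(length(items), length(items) * points)
  if (!is.null(range) && !identical(as.numeric(range), as.numeric(implied)))
    stop(sprintf("declared score range [%s, %s] does not match the range [%d, %d] implied by %d items on a 1..%d scale",
                 range[1], range[2], implied[1], implied[2],
                 length(items), points))
  structure(list(name = name, items = items, reversed = reversed,
                 points = as.integer(points), range = implied),
            class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items (%d reverse-coded), score range [%d, %d]\n",
              x$name, length(x$items), length(x$reversed),
              x$range[1], x$range[2]))
  invisible(x)
}

#' Default instrument definitions
#'
#' The three instruments of the motivating college-student survey: Young's
#' 20-item Internet Addiction Test (outcome Y, score 20-100), the 26-item
#' Positive Psychological Capital Questionnaire (predictor X, 26-130), and
#' three adaptation subscales drawn from the SACQ: emotional adaptation
#' (M1, 8 items, all reverse-coded so higher = better adaptation), learning
#' adaptation (M2, 5 items, one reverse-coded) and interpersonal adaptation
#' (M3, 4 items, three reverse-coded).
#'
#' @return Named list of [scale_def()] objects, with an attribute
#'   `model_roles` mapping instrument names to model columns Y, X, M1-M3.
#' @export
default_instruments <- function() {
  defs <- list(
    iat    = scale_def("iat",    sprintf("iat_%02d", 1:20)),
    ppq    = scale_def("ppq",    sprintf("ppq_%02d", 1:26)),
    emoada = scale_def("emoada", sprintf("emo_%02d", 1:8),
                       reversed = sprintf("emo_%02d", 1:8)),
    leaada = scale_def("leaada", sprintf("lea_%02d", 1:5),
                       reversed = "lea_05"),
    intada = scale_def("intada", sprintf("int_%02d", 1:4),
                       reversed = sprintf("int_%02d", 2:4))
  )
  attr(defs, "model_roles") <- c(iat = "Y", ppq = "X", emoada = "M1",
                                 leaada = "M2", intada = "M3")
  defs
}

.check_item_range <- function(items, points) {
  m <- as.matrix(items)
  if (!is.numeric(m)) stop("item responses must be numeric")
  bad <- which(!is.na(m) & (m < 1 | m > points | m != round(m)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("item response out of range [1, %d]: row %d, column '%s' (value %s)",
                 points, bad[1, 1], colnames(m)[bad[1, 2]],
                 format(m[bad[1, 1], bad[1, 2]])))
  }
  m
}

#' Reverse-code Likert items
#'
#' Maps each reversed item response x to `points + 1 - x` so that, after
#' recoding, a higher value always points in the scale's scoring direction.
#' Applying the function twice is the identity.
#'
#' @param items Data frame or matrix of integer responses in `[1, points]`.
#' @param reversed Character vector of column names to recode.
#' @param points Response points per item.
#' @return Object of the same shape with the reversed columns recoded.
#' @export
reverse_code <- function(items, reversed, points = 5L) {
  .check_item_range(items, points)
  if (!all(reversed %in% colnames(items)))
    stop("columns to reverse not found: ",
         paste(setdiff(reversed, colnames(items)), collapse = ", "))
  out <- items
  for (cn in reversed) out[[cn]] <- points + 1L - out[[cn]]
  out
}

#' Score a summed scale
#'
#' Sums the item columns of `definition` per respondent. Reverse coding is
#' assumed to have been applied already (see [reverse_code()]); use
#' [score_instruments()] for the combined recode-and-score pipeline.
#'
#' @param items Data frame or matrix of recoded responses.
#' @param definition A [scale_def()].
#' @return Integer vector of scores, one per row, within the declared range.
#' @export
score_scale <- function(items, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  missing_cols <- setdiff(definition$items, colnames(items))
  if (length(missing_cols))
    stop(sprintf("scale '%s' is missing item column(s): %s",
                 definition$name, paste(missing_cols, collapse = ", ")))
  m <- .check_item_range(items[, definition$items, drop = FALSE],
                         definition$points)
  rowSums(m)
}

#' Score all instruments of an item-level dataset
#'
#' Applies listwise deletion of incomplete rows, reverse codes each
#' instrument per its definition, sums the items, and returns one scored
#' column per instrument named by its model role (Y, X, M1, M2, M3 for the
#' default instruments).
#'
#' @param items Data frame of raw item responses; an `id` column, if
#'   present, is carried through.
#' @param definitions List of [scale_def()]s with a `model_roles` attribute;
#'   defaults to [default_instruments()].
#' @return Data frame of per-respondent scale scores.
#' @export
score_instruments <- function(items, definitions = default_instruments()) {
  roles <- attr(definitions, "model_roles")
  needed <- unlist(lapply(definitions, `[[`, "items"))
  missing_cols <- setdiff(needed, colnames(items))
  if (length(missing_cols))
    stop("missing item column(s): ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(items[, needed, drop = FALSE])
  items <- items[keep, , drop = FALSE]
  out <- data.frame(row.names = seq_len(nrow(items)))
  if ("id" %in% colnames(items)) {
    if (anyDuplicated(items$id)) stop("duplicated respondent ids")
    out$id <- items$id
  }
  for (nm in names(definitions)) {
    def <- definitions[[nm]]
    recoded <- reverse_code(items[, def$items, drop = FALSE],
                            def$reversed, def$points)
    col <- if (!is.null(roles) && nm %in% names(roles)) roles[[nm]] else nm
    out[[col]] <- score_scale(recoded, def)
  }
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`,
#' with sample variances on denominator n-1. Adding a constant to any item
#' leaves alpha unchanged; a zero total-score variance makes alpha undefined
#' and is reported as `NA` with a warning rather than silently as 0.
#'
#' @param items Data frame or matrix with at least two item columns and
#'   three complete rows.
#' @return Scalar alpha (can be negative for badly keyed scales).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) < 2L) stop("alpha needs at least 2 items")
  if (nrow(m) < 3L) stop("alpha needs at least 3 respondents")
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= .Machine$double.eps) {
    warning("total-score variance is zero; alpha is undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Grade Internet Addiction Test scores into severity bands
#'
#' Partitions the IAT score range 20-100 into none `[20,40)`, mild
#' `[40,60)`, moderate `[60,80)` and severe `[80,100]`. The published
#' cut-offs (40-60 mild, 60-80 moderate, 80-100 severe) overlap at the
#' boundaries; the half-open-on-the-left convention used here makes the
#' bands a partition, so every admissible score maps to exactly one
#' category.
#'
#' @param score Numeric vector of IAT total scores in `[20, 100]`.
#' @return Factor with levels none, mild, moderate, severe.
#' @export
grade_iat <- function(score) {
  if (any(score < 20 | score > 100, na.rm = TRUE))
    stop("IAT scores must lie in [20, 100]")
  cut(score, breaks = c(20, 40, 60, 80, 100),
      labels = c("none", "mild", "moderate", "severe"),
      right = FALSE, include.lowest = TRUE)
}

#' Grand-mean centering
#'
#' Subtracts the sample mean; the mean is retained as attribute `"center"`
#' so the transformation can be undone and product terms interpreted at the
#' sample average.
#'
#' @param x Nonempty numeric vector.
#' @return Centered vector with attribute `center`.
#' @export
center_grand_mean <- function(x) {
  stopifnot(length(x) >= 1L)
  m <- mean(x)
  structure(x - m, center = m)
}

#' Per-scale reliability report
#'
#' @param items Data frame of raw item responses.
#' @param definitions Instrument definitions; see [default_instruments()].
#' @return Data frame with one row per instrument: name, number of items,
#'   complete-case n and Cronbach's alpha (computed on recoded items).
#' @export
reliability_report <- function(items, definitions = default_instruments()) {
  rows <- lapply(definitions, function(def) {
    sub <- items[, def$items, drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    recoded <- reverse_code(sub, def$reversed, def$points)
    data.frame(scale = def$name, k = length(def$items), n = nrow(sub),
               alpha = cronbach_alpha(recoded))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
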