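#' Run the full analysis pipeline from a configuration
#'
#' One call that scores, fits, decomposes and (optionally) bootstraps,
#' writing a machine-readable report bundle. The configuration is an R
#' list, or a path to a YAML or JSON document with the same keys:
#'
#' \describe{
#'   \item{mode}{`"items"` (raw Likert responses; scored first),
#'     `"scores"` (pre-scored scale columns Y, X, M1-M3) or `"moments"`
#'     (summary-moments JSON; see [read_moments()]).}
#'   \item{input}{path to the input CSV (items/scores) or JSON (moments);
#'     alternatively supply `data` (a data frame or `summary_moments`)
#'     directly in the list.}
#'   \item{output_dir}{directory for the report files (created if
#'     needed).}
#'   \item{x_points}{optional centered moderator evaluation values;
#'     default -SD, 0, +SD of X.}
#'   \item{bootstrap}{optional list `(B, level, seed)`; bootstrapping
#'     requires respondent-level input and is an error in moments mode
#'     (summary statistics cannot be resampled).}
#'   \item{precision}{decimal places for the CSV tables (default 3); JSON
#'     keeps full precision.}
#' }
#'
#' Written files: `moments.json`, `fit.json`, `effects.json`,
#' `effects.csv` (conditional-indirect table), `plot_data.csv`
#' (conditional-effect curves), `reliability.json` (items mode),
#' `bootstrap.json` (if bootstrapped) and `run_log.txt`.
#'
#' @param config List or path to a YAML/JSON configuration.
#' @param quiet Suppress progress messages (they go to `stderr`).
#' @return Invisibly, a list with the moments, fit, effect decomposition,
#'   bootstrap result (or NULL) and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- .read_config(config)
  say <- function(...) if (!quiet) message(...)
  mode <- match.arg(cfg$mode, c("items", "scores", "moments"))
  if (!is.null(cfg$bootstrap) && mode == "moments")
    stop("bootstrapping needs respondent-level rows to resample; ",
         "summary moments cannot be bootstrapped")
  out_dir <- cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  precision <- cfg$precision %||% 3L
  spec <- model_spec()
  reliability <- NULL

  if (mode == "moments") {
    moments <- if (inherits(cfg$data, "summary_moments")) cfg$data
               else read_moments(.input_path(cfg))
    say(sprintf("loaded summary moments: %d columns, n = %d",
                length(moments$columns), moments$n))
    raw <- NULL
  } else {
    tab <- if (is.data.frame(cfg$data)) cfg$data
           else .read_table(.input_path(cfg))
    if (nrow(tab) == 0L) stop("input has no rows")
    if (mode == "items") {
      reliability <- reliability_report(tab)
      tab <- score_instruments(tab)
      say(sprintf("scored %d respondents", nrow(tab)))
    }
    raw <- tab
    moments <- compute_moments(prepare_model_frame(tab, spec), spec)
  }

  fit <- fit_from_moments(moments, spec)
  say(sprintf("model fitted (pseudo R2 of %s: %.3f)", spec$outcome,
              fit$pseudo_r2[[spec$outcome]]))
  x_points <- cfg$x_points %||% (fit$sd_x * c(-1, 0, 1))
  decomp <- effect_decomposition(fit, x_points)
  curves <- conditional_curve_data(fit)

  boot <- NULL
  if (!is.null(cfg$bootstrap)) {
    bs <- cfg$bootstrap
    boot <- bootstrap_model(raw, spec,
                            B = bs$B %||% 1000L,
                            level = bs$level %||% 0.99,
                            seed = bs$seed)
    say(sprintf("bootstrap done: B = %d, %d failed refits",
                boot$settings$B, boot$failed))
  }

  paths <- .write_bundle(out_dir, moments, fit, decomp, curves, boot,
                         reliability, precision)
  say("report written to ", out_dir)
  invisible(list(moments = moments, fit = fit, effects = decomp,
                 bootstrap = boot, reliability = reliability,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else
      yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else stop("config must be a list or a path to a YAML/JSON file")
}

.input_path <- function(cfg) {
  if (is.null(cfg$input)) stop("config needs an 'input' path (or 'data')")
  if (!file.exists(cfg$input)) stop("input file not found: ", cfg$input)
  cfg$input
}

.read_table <- function(path) {
  utils::read.csv(path, header = TRUE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}

.write_bundle <- function(out_dir, moments, fit, decomp, curves, boot,
                          reliability, precision) {
  p <- function(f) file.path(out_dir, f)
  write_moments(moments, p("moments.json"))
  jsonlite::write_json(fit_report(fit), p("fit.json"),
                       auto_unbox = TRUE, digits = NA)
  eff <- list(direct = decomp$direct,
              total_effect = decomp$total_effect,
              indirect_share_pct = decomp$indirect_share,
              shares_pct = as.list(decomp$shares),
              total_indirect = decomp$total_indirect,
              conditional = decomp$conditional)
  jsonlite::write_json(eff, p("effects.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  tab <- decomp$conditional
  tab$effect <- round(tab$effect, precision)
  utils::write.csv(tab, p("effects.csv"), row.names = FALSE)
  utils::write.csv(curves, p("plot_data.csv"), row.names = FALSE)
  paths <- c(moments = p("moments.json"), fit = p("fit.json"),
             effects_json = p("effects.json"), effects_csv = p("effects.csv"),
             plot_data = p("plot_data.csv"))
  if (!is.null(reliability)) {
    jsonlite::write_json(reliability, p("reliability.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths["reliability"] <- p("reliability.json")
  }
  if (!is.null(boot)) {
    rep <- list(settings = boot$settings[c("B", "level", "seed", "n")],
                failed = boot$failed,
                intervals = boot$intervals)
    jsonlite::write_json(rep, p("bootstrap.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    paths["bootstrap"] <- p("bootstrap.json")
  }
  log_lines <- c(
    sprintf("modmedpath %s", as.character(utils::packageVersion("modmedpath"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("n = %d", moments$n),
    if (!is.null(boot))
      sprintf("bootstrap: B = %d, level = %s, seed = %s",
              boot$settings$B, format(boot$settings$level),
              format(boot$settings$seed %||% NA)))
  writeLines(log_lines, p("run_log.txt"))
  paths["log"] <- p("run_log.txt")
  paths
}
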