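# File formats and the end-to-end "analyze one mixture" pipeline.
#
# Series files are delimited text with header `x2` plus exactly one of `et`
# (kcal/mol) or `lambda_nm`; `#` lines are comments. x2 is always the bulk
# mole fraction of the polar/protic cosolvent S2 — map your columns
# accordingly before reading.

#' Read a titration series from delimited text
#'
#' Expects a header row `x2,et` or `x2,lambda_nm` (any single-character
#' separator); wavelength input is converted to transition energies via
#' [lambda_to_transition_energy()]. Lines starting with `#` are ignored.
#' Parse and validation problems are reported with the offending line
#' numbers.
#'
#' @param path File path.
#' @param mixture_name Label for the series; defaults to the file name.
#' @param sep Field separator (default comma).
#' @return A validated, sorted [titration_series()].
#' @export
read_series <- function(path, mixture_name = NULL, sep = ",") {
  if (is.null(mixture_name)) {
    mixture_name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (sum(keep) < 2) stop("no data rows in ", path, call. = FALSE)
  line_no <- which(keep)
  df <- utils::read.table(text = lines[keep], header = TRUE, sep = sep,
                          strip.white = TRUE, colClasses = "character")
  data_lines <- line_no[-1]

  has_et <- "et" %in% names(df)
  has_lambda <- "lambda_nm" %in% names(df)
  if (!"x2" %in% names(df)) {
    stop("series file must have an `x2` column", call. = FALSE)
  }
  if (has_et && has_lambda) {
    stop("ambiguous input: both `et` and `lambda_nm` columns present; ",
         "supply exactly one", call. = FALSE)
  }
  if (!has_et && !has_lambda) {
    stop("series file must have an `et` or a `lambda_nm` column",
         call. = FALSE)
  }
  ycol <- if (has_et) "et" else "lambda_nm"

  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric `%s` value(s) at line(s) %s of %s", col,
                   paste(data_lines[bad], collapse = ", "), path),
           call. = FALSE)
    }
    v
  }
  x2 <- num("x2")
  y <- num(ycol)
  bad <- which(x2 < 0 | x2 > 1)
  if (length(bad)) {
    stop(sprintf("x2 outside [0, 1] at line(s) %s of %s",
                 paste(data_lines[bad], collapse = ", "), path),
         call. = FALSE)
  }
  et <- if (has_et) y else lambda_to_transition_energy(y)
  titration_series(x2, et, mixture_name = mixture_name)
}

#' Write a titration series to delimited text
#'
#' @param series A [titration_series()].
#' @param path Output path; written with header `x2,et`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  utils::write.csv(data.frame(x2 = series$x2, et = series$et), path,
                   row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param candidates Variant candidates for [compare_model_variants()].
#' @param seed Integer seed for the multi-start fits.
#' @param n_starts Multi-start count per fit.
#' @param fix_endpoints Pin E_T1/E_T2 to the measured endpoints.
#' @param cell_model Run the statistical cell model stage.
#' @param temperature Kelvin, for the cell model.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(candidates = list(
                              list(variant = "general", m = 2),
                              list(variant = "general", m = 3),
                              list(variant = "corrected", m = 2)
                            ),
                            seed = 1, n_starts = 32, fix_endpoints = FALSE,
                            cell_model = TRUE, temperature = 295.15) {
  structure(list(candidates = candidates, seed = as.integer(seed),
                 n_starts = as.integer(n_starts),
                 fix_endpoints = fix_endpoints,
                 cell_model = cell_model, temperature = temperature),
            class = "pipeline_config")
}

#' Analyze one binary mixture end to end
#'
#' Runs the full chain on a titration series: model-free shell composition,
#' exchange-model variant comparison, local-composition curves of the best
#' fit, and (optionally) the statistical cell model on the shell curve.
#' Deterministic given the config seed. Stage failures are recorded in the
#' report's `errors` field and independent downstream stages still run.
#'
#' @param series A [titration_series()].
#' @param config A [pipeline_config()].
#' @return An object of class `analysis_report`: list with `mixture_name`,
#'   `series_summary`, `shell` (data frame), `comparison` (ranked variant
#'   table), `best_fit`, `local_fractions` (best-fit shell curves on the
#'   measured grid), `cell_model` (or `NULL`), `errors`, `provenance`.
#' @export
run_pipeline <- function(series, config = pipeline_config()) {
  stopifnot(inherits(series, "titration_series"),
            inherits(config, "pipeline_config"))
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  shell <- tryCatch(shell_series(series), error = function(e) {
    note("shell", e); NULL
  })
  comparison <- tryCatch(
    compare_model_variants(series, candidates = config$candidates,
                           seed = config$seed, n_starts = config$n_starts,
                           fix_endpoints = config$fix_endpoints),
    error = function(e) { note("exchange", e); NULL }
  )
  fit <- if (!is.null(comparison)) {
    tryCatch(best_fit(comparison), error = function(e) {
      note("exchange", e); NULL
    })
  }
  local_fr <- if (!is.null(fit)) {
    local_shell_fractions(series$x2, fit$params, fit$cross_term)
  }
  cell <- NULL
  if (isTRUE(config$cell_model) && !is.null(shell)) {
    cell <- tryCatch(
      suppressWarnings(
        fit_cell_model(shell, temperature = config$temperature)
      ),
      error = function(e) { note("cell_model", e); NULL }
    )
  }
  ends <- tryCatch(series_endpoints(series), error = function(e) c(
    et1 = NA_real_, et2 = NA_real_))
  structure(
    list(
      mixture_name = attr(series, "mixture_name"),
      series_summary = list(n = nrow(series), et1 = unname(ends["et1"]),
                            et2 = unname(ends["et2"])),
      shell = if (!is.null(shell)) as.data.frame(shell),
      comparison = if (!is.null(comparison)) as.data.frame(comparison),
      best_fit = fit,
      local_fractions = local_fr,
      cell_model = cell,
      errors = errors,
      provenance = list(
        seed = config$seed, n_starts = config$n_starts,
        fix_endpoints = config$fix_endpoints,
        temperature = config$temperature,
        package_version = as.character(utils::packageVersion("prefsolv"))
      )
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s (%d points)\n", x$mixture_name,
              x$series_summary$n))
  if (!is.null(x$comparison)) {
    cat("variant comparison (best first):\n")
    print(x$comparison[, c("rank", "variant", "m", "converged",
                           "stability_flag", "sd")])
  }
  if (!is.null(x$best_fit)) print(x$best_fit)
  if (!is.null(x$cell_model)) print(x$cell_model)
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (s in names(x$errors)) cat("  ", s, ": ", x$errors[[s]], "\n", sep = "")
  }
  invisible(x)
}

report_to_list <- function(report) {
  fit <- report$best_fit
  list(
    mixture_name = report$mixture_name,
    series_summary = report$series_summary,
    shell = report$shell,
    comparison = report$comparison,
    best_fit = if (!is.null(fit)) list(
      variant = fit$params$variant, m = fit$params$m,
      et1 = fit$params$et1, et2 = fit$params$et2, et12 = fit$params$et12,
      f2_1 = fit$params$f2_1, f12_1 = fit$params$f12_1,
      k = fit$params$k,
      rss = fit$rss, r_squared = fit$r_squared, sd = fit$sd,
      n_points = fit$n_points, converged = fit$converged,
      n_starts = fit$n_starts, best_start = fit$best_start,
      stability_flag = fit$stability_flag
    ),
    local_fractions = report$local_fractions,
    cell_model = if (!is.null(report$cell_model)) {
      cm <- report$cell_model
      list(slope = cm$slope, intercept = cm$intercept,
           omega_diff = cm$omega_diff, temperature = cm$temperature,
           r_squared = cm$r_squared, n_points = cm$n_points)
    },
    errors = report$errors,
    provenance = report$provenance
  )
}

#' Write an analysis report as JSON
#'
#' Numeric fields are written at full precision so a write/read round trip
#' reproduces them bit-exactly.
#'
#' @param report An [run_pipeline()] result.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analysis report written by [write_report()]
#'
#' @param path JSON file path.
#' @return The report as a plain list (not re-classed); numeric fields are
#'   bit-identical to the written ones.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
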