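#' Read a concentration-response table from CSV
#'
#' Accepts either pre-aggregated rows (`concentration, n_exposed,
#' n_surviving[, day, label]`) or per-animal rows (`concentration,
#' survived` with `survived` in {0, 1}, one animal per row); per-animal rows
#' are aggregated by summing. Validation rejects missing controls, counts
#' with `n_surviving > n_exposed` and negative values, naming the offending
#' rows.
#'
#' @param path path to a CSV file.
#' @return A [conc_response()] object. The source path is attached as
#'   attribute `source` for report provenance.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- names(df)
  if (!"concentration" %in% cols) {
    stop("validation error: missing required column 'concentration'",
         call. = FALSE)
  }
  if ("survived" %in% cols && !"n_exposed" %in% cols) {
    if (any(!df$survived %in% c(0, 1))) {
      stop("validation error: per-animal column 'survived' must be 0/1; ",
           "offending rows: ",
           paste(which(!df$survived %in% c(0, 1)), collapse = ", "),
           call. = FALSE)
    }
    df$n_exposed <- 1L
    df$n_surviving <- as.integer(df$survived)
  }
  missing <- setdiff(c("n_exposed", "n_surviving"), names(df))
  if (length(missing)) {
    stop("validation error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- conc_response(df$concentration, df$n_exposed, df$n_surviving,
                       day = if ("day" %in% cols) df$day else NULL,
                       label = if ("label" %in% cols) df$label else NULL)
  attr(out, "source") <- path
  out
}

#' Write a concentration-response table to CSV
#'
#' @param data a [conc_response()] object.
#' @param path output CSV path.
#' @export
write_response_table <- function(data, path) {
  stopifnot(inherits(data, "conc_response"))
  cols <- c("concentration", "n_exposed", "n_surviving", "day", "label")
  utils::write.csv(as.data.frame(data)[, cols], path, row.names = FALSE)
  invisible(path)
}

report_list <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "ecxsys_fit"))
  src <- attr(fit$data, "source")
  lst <- list(
    schema_version = "1.0",
    input = list(
      path = if (is.null(src)) NA else src,
      md5 = if (is.null(src) || !file.exists(src)) NA
            else unname(tools::md5sum(src)),
      n_concentrations = nrow(fit$data),
      n_animals = sum(fit$data$n_exposed)
    ),
    config = unclass(fit$config),
    seed = seed,
    capacity = list(p = fit$capacity$p, q = fit$capacity$q),
    toxicant_curve = unclass(fit$toxicant_curve),
    sys_curve = unclass(fit$sys_curve),
    s_env = fit$s_env,
    hormesis_concentration = fit$hormesis_concentration,
    smoothing_points = fit$smoothing_points,
    decomposition = as.data.frame(fit$decomposition),
    lc = as.list(fit$lc),
    lc_definition = fit$config$lc_definition,
    hormetic_range = as.list(fit$hormetic_range),
    sys_ec99_stress = fit$sys_ec99_stress,
    residual_sum_of_squares = fit$rss,
    converged = fit$converged,
    warnings = fit$log
  )
  if (!is.null(fit$traditional)) {
    lst$traditional <- list(
      params = fit$traditional$params,
      residual_sum_of_squares = fit$traditional$residual_sum_of_squares,
      lc = as.list(fit$traditional$lc),
      converged = fit$traditional$converged
    )
  }
  lst
}

#' Write a JSON fit report and predicted-curve CSV
#'
#' The JSON report carries the schema version, input digest, configuration
#' echo, all fitted parameters, the stress-decomposition table, the LC map,
#' the hormetic range and the pipeline's audit log. A companion CSV
#' (`<path stem>_curve.csv`) samples the predicted survival curve on a
#' 200-point log-concentration grid. A failed (partial) fit may be reported
#' by passing the error via `failure`.
#'
#' @param fit an `ecxsys_fit`, or `NULL` when reporting a failure.
#' @param path output JSON path.
#' @param seed optional seed to record for reproducibility.
#' @param curve_csv whether to write the companion curve CSV.
#' @param failure optional condition/message describing a failed pipeline
#'   stage; recorded under `failure` in the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, seed = NULL, curve_csv = TRUE,
                         failure = NULL) {
  lst <- if (is.null(fit)) {
    list(schema_version = "1.0", seed = seed, converged = FALSE)
  } else {
    report_list(fit, seed = seed)
  }
  if (!is.null(failure)) {
    lst$failure <- if (inherits(failure, "condition")) {
      conditionMessage(failure)
    } else as.character(failure)
  }
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  if (curve_csv && !is.null(fit)) {
    pos <- fit$data$concentration[fit$data$concentration > 0]
    grid <- c(0, 10^seq(log10(min(pos) / 100), log10(max(pos) * 3),
                        length.out = 199L))
    utils::write.csv(
      data.frame(concentration = grid,
                 survival = predict_survival(fit, grid)),
      sub("\\.json$", "_curve.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Read a fit report back as a list
#'
#' @param path JSON report path.
#' @return The report as a list (numeric fields restored at full precision).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
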