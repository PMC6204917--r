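#' File formats and configuration
#'
#' All tables travel as CSV/TSV with unit-suffixed column names; fit
#' results serialize to JSON with explicit unit-bearing field names;
#' run configuration is YAML. No binary acquisition formats are read.
#'
#' @name cli-io
NULL

#' Read a sweep-record table
#'
#' Accepts CSV or TSV (dialect chosen by file extension, with a comma/tab
#' sniff fallback). Mandatory columns are checked and named in the error
#' when absent; unknown columns raise a warning but are kept, never
#' silently dropped.
#'
#' @param path file path
#' @return data.frame in the canonical column order (extra columns last)
#' @export
read_sweep_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("schema error: empty file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t"
         else if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
         else if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(sweep_columns, names(df))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), sweep_columns)
  if (length(extra))
    warning("unknown column(s) retained: ", paste(extra, collapse = ", "))
  df[, c(sweep_columns, extra), drop = FALSE]
}

#' Write a sweep-record table
#'
#' @param x sweep-record data.frame
#' @param path output path; `.tsv` extension selects tab separation
#' @return `path`, invisibly
#' @export
write_sweep_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(sweep_columns, names(x))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(x), sweep_columns)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(x[, c(sweep_columns, extra), drop = FALSE], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# unit-bearing JSON field names for each fit class
fit_json_fields <- function(fit) {
  switch(class(fit)[1],
    hill_fit = list(model = "hill", ic50_uM = fit$ic50, hill_slope = fit$h,
                    fixed_slope = fit$fixed_slope),
    boltzmann_fit = list(model = "boltzmann", v_half_mV = fit$v_half,
                         k_mV = fit$k, polarity = fit$polarity),
    biexp_fit = list(model = "biexponential", y0 = fit$y0,
                     plateau = fit$plateau, k_fast_per_s = fit$k_fast,
                     k_slow_per_s = fit$k_slow,
                     percent_fast = fit$percent_fast,
                     tau_fast_s = fit$tau_fast, tau_slow_s = fit$tau_slow),
    monoexp_fit = list(model = "monoexponential", y0 = fit$y0,
                       plateau = fit$plateau, k_per_s = fit$k,
                       tau_obs_s = fit$tau_obs),
    state_block_model = list(model = "state_block",
                             kd_rest_uM = fit$kd_rest,
                             kd_inact_uM = fit$kd_inact,
                             fold_ratio = fit$kd_rest / fit$kd_inact,
                             avail_v_half_mV = fit$availability$v_half,
                             avail_k_mV = fit$availability$k),
    stop("unsupported fit class: ", class(fit)[1]))
}

#' Serialize a fit object (or fit result) to JSON
#'
#' @param fit a model object ([hill_fit()] etc.) or a [fit_result()]
#' @param path optional output file; when NULL the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
write_fit_json <- function(fit, path = NULL) {
  if (inherits(fit, "fit_result")) {
    body <- list(converged = fit$converged, n_points = fit$n_points,
                 residual_ss = fit$residual_ss, diagnostic = fit$diagnostic)
    if (fit$converged) body <- c(fit_json_fields(fit$params), body)
  } else {
    body <- fit_json_fields(fit)
  }
  js <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a fit object from JSON
#'
#' @param path file path or a JSON string
#' @return the model object the JSON encodes
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  switch(x$model,
    hill = hill_fit(x$ic50_uM, x$hill_slope, isTRUE(x$fixed_slope)),
    boltzmann = boltzmann_fit(x$v_half_mV, x$k_mV, x$polarity),
    biexponential = biexp_fit(x$y0, x$plateau, x$k_fast_per_s,
                              x$k_slow_per_s, x$percent_fast),
    monoexponential = monoexp_fit(x$y0, x$plateau, x$k_per_s),
    state_block = state_block_model(
      x$kd_rest_uM, x$kd_inact_uM,
      boltzmann_fit(x$avail_v_half_mV, x$avail_k_mV, "availability")),
    stop("unknown model tag in JSON: ", x$model))
}

#' Read a YAML run configuration
#'
#' @param path YAML file with at least `schema_version`; recognized
#'   analysis keys: `seed`, `fix_slope`, `pooling` ("mean" or "cells"),
#'   `persist_fraction`, `out_dir`, `verbose`
#' @return named list of settings with defaults filled in
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version))
    stop("schema error: config lacks `schema_version`")
  if (cfg$schema_version != 1)
    stop("unsupported config schema_version: ", cfg$schema_version)
  defaults <- list(seed = 1L, fix_slope = NULL, pooling = "mean",
                   persist_fraction = 0.1, out_dir = ".", verbose = 0L)
  utils::modifyList(defaults, cfg)
}
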