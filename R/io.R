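## Readers/writers for the package's tabular formats and run manifests.
## Small tables are CSV; configurations YAML/JSON; results and manifests
## JSON.

#' Read / write a strength-duration table
#'
#' CSV with columns `duration_ms`, `irradiance_mW_mm2`.
#'
#' @param path file path
#' @return a `strength_duration_curve` data.frame
#' @export
read_sd_curve <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("duration_ms", "irradiance_mW_mm2") %in% names(d)))
  class(d) <- c("strength_duration_curve", "data.frame")
  d
}

#' @rdname read_sd_curve
#' @param curve a strength-duration data.frame
#' @export
write_sd_curve <- function(curve, path) {
  utils::write.csv(
    curve[, c("duration_ms", "irradiance_mW_mm2")], path,
    row.names = FALSE)
  invisible(path)
}

#' Read / write a gapFRAP fluorescence trace
#'
#' CSV with columns `time_s` and `fluorescence` (raw) or `f_norm`
#' (already normalized).
#'
#' @param path file path
#' @return a data.frame
#' @export
read_frap_trace <- function(path) {
  d <- utils::read.csv(path)
  stopifnot("time_s" %in% names(d),
            any(c("fluorescence", "f_norm") %in% names(d)))
  d
}

#' @rdname read_frap_trace
#' @param trace a data.frame with `time_s` and `fluorescence`/`f_norm`
#' @export
write_frap_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation trace to CSV
#'
#' @param trace a `tcu_trace` (or any data.frame of time and named
#'   variables)
#' @param path file path
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Build a run manifest
#'
#' A small reproducibility record: configuration hash, seed, package
#' version and an index of outputs. Identical manifests imply reproducible
#' outputs (all stochastic operations take explicit seeds).
#'
#' @param config any configuration object (hashed)
#' @param seed integer seed used for the run (`NULL` = a seed is generated
#'   and recorded)
#' @param outputs named list describing the run outputs
#' @return an object of class `run_manifest`
#' @export
run_manifest <- function(config, seed = NULL, outputs = list()) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  structure(list(
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    package = "optogap",
    version = as.character(utils::packageVersion("optogap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`
#' @param path file path
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
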