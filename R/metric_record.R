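#' Uniform result record for quantification stages
#'
#' A JSON-serializable record tying a metric value to its units, the
#' parameters that produced it, a hash of the input data and the package
#' version, so every reported number carries its provenance. The timestamp
#' is optional and omitted by default, keeping records byte-stable across
#' reruns of the same analysis.
#'
#' @param name metric name, e.g. `"wall_shear_stress"`.
#' @param value numeric scalar or vector.
#' @param units unit string (may be `""` for dimensionless).
#' @param parameters named list of parameters that produced the value.
#' @param inputs object(s) the metric was computed from; hashed (sum-based
#'   content digest) into `input_hash`.
#' @param timestamp optional POSIXct / string; omitted when `NULL`.
#' @return A `metric_record`.
#' @export
metric_record <- function(name, value, units = "", parameters = list(),
                          inputs = NULL, timestamp = NULL) {
  structure(list(
    name = name,
    value = value,
    units = units,
    parameters = parameters,
    input_hash = if (is.null(inputs)) NA_character_ else content_hash(inputs),
    package_version = as.character(utils::packageVersion("perfuseR")),
    timestamp = if (is.null(timestamp)) NULL else as.character(timestamp)
  ), class = "metric_record")
}

# light content digest: stable across sessions, no external dependency
content_hash <- function(x) {
  raw <- serialize(x, NULL, version = 3L)
  n <- as.numeric(raw)
  sprintf("%08x-%08x", sum(n * seq_along(n)) %% 2^31, sum(n) %% 2^31)
}

#' Write / read metric records as JSON
#'
#' Round-trip stable: writing, reading and re-writing a record yields
#' byte-identical JSON.
#'
#' @param record a [metric_record()] or plain list of them.
#' @param path JSON file path.
#' @return `path` (write) / the record list (read).
#' @export
write_metric_record <- function(record, path) {
  jsonlite::write_json(unclass_deep(record), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_metric_record
#' @export
read_metric_record <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
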