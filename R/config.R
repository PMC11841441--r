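#' Load porous-domain parameters from a flat key-value file
#'
#' Reads a plain-text configuration of `key = value` lines (comments with
#' `#`) whose keys mirror the modelling-constant names: `density`,
#' `water_content`, `youngs_modulus`, `matrix_viscosity` (Pa s),
#' `porosity`, `permeability` (m^2), `species_diffusivity` (m^2/s). Keys
#' omitted from the file keep the package defaults (the 8% GelMA constants,
#' see [porous_domain_params()]).
#'
#' @param path configuration file path.
#' @return A [porous_domain_params()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stopf("malformed config line (expected 'key = value'): '%s'", ln)
    }
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(parts[1L])
    val <- suppressWarnings(as.numeric(trimws(paste(parts[-1L], collapse = "="))))
    if (is.na(val)) stopf("malformed config value for field '%s'", key)
    kv[[key]] <- val
  }
  allowed <- names(formals(porous_domain_params))
  unknown <- setdiff(names(kv), allowed)
  if (length(unknown) > 0L) {
    stopf("unknown config field(s): %s (allowed: %s)",
          paste(unknown, collapse = ", "), paste(allowed, collapse = ", "))
  }
  do.call(porous_domain_params, kv)
}
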