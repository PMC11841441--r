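#' Specification for a synthetic dataset
#'
#' Describes one synthetic acquisition: what kind of image to generate, the
#' RNG seed, the physical sampling (pixel size, frame interval), the image
#' shape, and kind-specific parameters. A fixed spec yields bit-identical
#' output, so every generated dataset is a reproducible fixture with known
#' ground truth.
#'
#' @param kind one of `"frap"`, `"leak"`, `"pores"`, `"grid"`, `"nuclei"`,
#'   `"network"`.
#' @param seed integer RNG seed; identical specs produce identical stacks.
#' @param pixel_size micrometres per pixel (> 0).
#' @param shape `c(rows, cols)` in pixels, each at least 32.
#' @param frame_interval seconds between frames (time-series kinds only).
#' @param params named list of kind-specific parameters; see the individual
#'   `generate_*` functions for what each kind requires.
#'
#' @return An object of class `synth_spec`.
#' @seealso [generate_synthetic()]
#' @export
synth_spec <- function(kind, seed, pixel_size = 1, shape = c(128L, 128L),
                       frame_interval = NA_real_, params = list()) {
  kind <- match.arg(kind, c("frap", "leak", "pores", "grid", "nuclei", "network"))
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stopf("pixel_size must be positive (micrometres/pixel)")
  }
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L)) {
    stopf("shape must be c(rows, cols) with both dimensions >= 32")
  }
  structure(
    list(kind = kind, seed = as.integer(seed), pixel_size = pixel_size,
         shape = shape, frame_interval = frame_interval, params = params),
    class = "synth_spec"
  )
}

#' Generate a synthetic dataset from a spec
#'
#' Dispatches to the kind-specific generator. Every generator returns a list
#' with elements `stack` (an [image_stack()]) and `truth` (the ground-truth
#' record of the generating parameters, sufficient to compute the expected
#' output of the matching analysis stage in closed form).
#'
#' @param spec a [synth_spec()].
#' @return `list(stack = <image_stack>, truth = <list>)`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  switch(spec$kind,
    frap    = generate_frap_stack(spec),
    leak    = generate_leak_series(spec),
    pores   = generate_pore_texture(spec),
    grid    = generate_grid_print(spec),
    nuclei  = generate_nuclei_field(spec),
    network = generate_network_mask(spec)
  )
}

# pull a required parameter out of spec$params
spec_param <- function(spec, name, default = NULL) {
  if (!is.null(spec$params[[name]])) return(spec$params[[name]])
  if (!is.null(default)) return(default)
  stopf("synth_spec (kind '%s') requires params$%s", spec$kind, name)
}

# Intensities are scaled to 80% of the 16-bit dynamic range so additive noise
# has headroom before clipping.
SYNTH_HIGH <- 0.8

# write a generated dataset (stack + ground truth sidecar) to disk
write_synthetic <- function(gen, spec, path) {
  st <- gen$stack
  st$metadata <- c(st$metadata, list(
    synth_spec = unclass(spec),
    ground_truth = gen$truth
  ))
  write_image_stack(st, path)
}
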