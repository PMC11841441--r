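#' Generate a synthetic dextran-leak image series
#'
#' Emulates the vascular-permeability assay: a fluorescent tracer perfused
#' through a vertical channel leaks into the flanking matrix, whose mean
#' intensity rises linearly in time. Frame 1 is the pre-perfusion background
#' (level `Ib`); subsequent frames show the bright channel band (diameter
#' `d` um) and flanking regions at `I(t) = I0 + k * t` for `t = 0,
#' frame_interval, ...`.
#'
#' The ground-truth permeability is the leak equation evaluated on the
#' constructed intensities: `P = (1 / (I0 - Ib)) * k * (d_cm / 4)` in cm/s,
#' i.e. the intensity-slope form of the assay's working equation.
#'
#' Required `params`: `d` (channel diameter, um), `I0`, `Ib` (flank levels at
#' start of perfusion and pre-perfusion background, intensity fractions of
#' full scale), `k` (intensity slope, 1/s), `duration` (s). Optional:
#' `channel_level` (default 0.8), `noise_sd`.
#'
#' @param spec a [synth_spec()] with `kind = "leak"`.
#' @return `list(stack, truth)`; `truth` carries `P_true` (cm/s), the
#'   constructed intensities, the slope and the channel geometry in px.
#' @export
generate_leak_series <- function(spec) {
  stopifnot(spec$kind == "leak")
  d_um <- spec_param(spec, "d")
  I0 <- spec_param(spec, "I0")
  Ib <- spec_param(spec, "Ib")
  k <- spec_param(spec, "k")
  duration <- spec_param(spec, "duration")
  ch_level <- spec_param(spec, "channel_level", SYNTH_HIGH)
  noise_sd <- spec_param(spec, "noise_sd", 0)
  if (I0 <= Ib) {
    stopf("I0 (%g) must exceed the background Ib (%g): permeability is undefined otherwise",
          I0, Ib)
  }
  if (is.na(spec$frame_interval) || spec$frame_interval <= 0) {
    stopf("leak spec requires a positive frame_interval")
  }
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  d_px <- d_um / spec$pixel_size
  if (d_px >= nc - 8) stopf("channel diameter %g um does not fit in the image", d_um)
  c0 <- round((nc - d_px) / 2) + 1L
  c1 <- round((nc + d_px) / 2)
  times <- seq(0, duration, by = spec$frame_interval)
  n_fr <- length(times) + 1L

  frames <- array(Ib, dim = c(nr, nc, n_fr))
  for (i in seq_along(times)) {
    f <- matrix(I0 + k * times[i], nr, nc)
    f[, c0:c1] <- ch_level
    frames[, , i + 1L] <- f
  }
  frames <- with_seed(spec$seed, {
    if (noise_sd > 0) {
      frames + array(stats::rnorm(length(frames), sd = noise_sd), dim(frames))
    } else frames
  })
  frames <- quantize16(frames)

  truth <- list(
    kind = "leak",
    P_true = (1 / (I0 - Ib)) * k * (um_to_cm(d_um) / 4),
    I0 = I0, Ib = Ib, slope = k, d_um = d_um,
    channel_cols = c(c0, c1), duration = duration
  )
  list(stack = image_stack(frames, pixel_size = spec$pixel_size,
                           frame_interval = spec$frame_interval),
       truth = truth)
}
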