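#' Generate a synthetic FRAP image series
#'
#' Simulates fluorescence recovery after photobleaching of a uniformly
#' bleached disk in an effectively infinite uniform fluorophore field, by
#' explicit finite-difference time stepping of the 2-D diffusion equation.
#' The finite-difference march is deliberately independent of the analysis
#' module's curve fitting, so it serves as an honest oracle for the FRAP
#' pipeline.
#'
#' Timeline: `pre_bleach` frames of the unbleached field, then the first
#' post-bleach frame captured immediately after the (instantaneous) bleach
#' pulse at `t = 0`, then recovery frames every `frame_interval` seconds.
#' The simulation domain is the image padded by `pad_px` on every side with a
#' far-field Dirichlet boundary at the pre-bleach level, approximating an
#' infinite reservoir.
#'
#' Required `params`: `D_true` (diffusion coefficient, um^2/s), `roi_radius`
#' (bleached-disk radius, um), `bleach_depth` in (0, 1], `pre_bleach`
#' (number of pre-bleach frames, >= 1), `n_frames` (post-bleach frames),
#' `noise_sd` (additive Gaussian noise sd, fraction of full scale).
#' Optional: `dt` (finite-difference time step, s). The explicit stencil is
#' stable only for `dt <= dx^2 / (4 D)`; a user-supplied `dt` violating the
#' bound is refused rather than silently substepped. When `dt` is omitted a
#' step of 0.8x the bound is used.
#'
#' @param spec a [synth_spec()] with `kind = "frap"`.
#' @return `list(stack, truth)`; `truth` carries `D_true`, the bleach
#'   geometry (ROI centre/radius in px and um), `bleach_depth`, the frame
#'   index of the first post-bleach frame, and the levels used.
#' @export
generate_frap_stack <- function(spec) {
  stopifnot(spec$kind == "frap")
  D <- spec_param(spec, "D_true")
  r_um <- spec_param(spec, "roi_radius")
  depth <- spec_param(spec, "bleach_depth")
  pre <- spec_param(spec, "pre_bleach", 1L)
  n_post <- spec_param(spec, "n_frames", 40L)
  noise_sd <- spec_param(spec, "noise_sd", 0)
  pad <- spec_param(spec, "pad_px", 48L)
  if (D < 0) stopf("D_true must be >= 0")
  if (depth <= 0 || depth > 1) stopf("bleach_depth must be in (0, 1]")
  if (pre < 1L) stopf("at least one pre-bleach frame is required")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (is.na(spec$frame_interval) || spec$frame_interval <= 0) {
    stopf("frap spec requires a positive frame_interval")
  }
  dx <- spec$pixel_size
  dt_bound <- if (D > 0) dx^2 / (4 * D) else Inf
  dt <- spec$params$dt
  if (!is.null(dt)) {
    if (dt > dt_bound) {
      stopf(paste0("explicit diffusion stencil unstable: dt = %g s exceeds the ",
                   "stability bound dx^2/(4D) = %g s; supply a smaller dt"),
            dt, dt_bound)
    }
  } else {
    dt <- 0.8 * dt_bound
  }

  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  NR <- nr + 2L * pad; NC <- nc + 2L * pad
  ctr <- c((NR + 1) / 2, (NC + 1) / 2)
  rows <- matrix(seq_len(NR), NR, NC)
  cols <- matrix(seq_len(NC), NR, NC, byrow = TRUE)
  disk <- (rows - ctr[1L])^2 + (cols - ctr[2L])^2 <= (r_um / dx)^2

  high <- SYNTH_HIGH
  u <- matrix(high, NR, NC)
  crop <- function(m) m[(pad + 1L):(pad + nr), (pad + 1L):(pad + nc)]

  frames <- array(0, dim = c(nr, nc, pre + 1L + n_post))
  for (i in seq_len(pre)) frames[, , i] <- crop(u)
  u[disk] <- high * (1 - depth)
  frames[, , pre + 1L] <- crop(u)  # t = 0+, straight after the bleach pulse

  if (D > 0) {
    nsub <- max(1L, ceiling(spec$frame_interval / dt))
    dts <- spec$frame_interval / nsub
    lam <- D * dts / dx^2
    for (f in seq_len(n_post)) {
      for (s in seq_len(nsub)) {
        un <- u
        un[2:(NR - 1), ] <- un[2:(NR - 1), ] +
          lam * (u[1:(NR - 2), ] - 2 * u[2:(NR - 1), ] + u[3:NR, ])
        un[, 2:(NC - 1)] <- un[, 2:(NC - 1)] +
          lam * (u[, 1:(NC - 2)] - 2 * u[, 2:(NC - 1)] + u[, 3:NC])
        un[1, ] <- high; un[NR, ] <- high; un[, 1] <- high; un[, NC] <- high
        u <- un
      }
      frames[, , pre + 1L + f] <- crop(u)
    }
  } else {
    for (f in seq_len(n_post)) frames[, , pre + 1L + f] <- crop(u)
  }

  frames <- with_seed(spec$seed, {
    if (noise_sd > 0) {
      frames + array(stats::rnorm(length(frames), sd = noise_sd), dim(frames))
    } else frames
  })
  frames <- quantize16(frames)

  ctr_img <- c((nr + 1) / 2, (nc + 1) / 2)
  truth <- list(
    kind = "frap", D_true = D, roi_radius_um = r_um,
    roi_radius_px = r_um / dx, roi_center_px = ctr_img,
    bleach_depth = depth, bleach_frame = pre + 1L,
    pre_bleach_level = high, post_bleach_level = high * (1 - depth)
  )
  list(stack = image_stack(frames, pixel_size = dx,
                           frame_interval = spec$frame_interval),
       truth = truth)
}
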