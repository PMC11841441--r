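#' Generate a synthetic SEM-like pore texture
#'
#' Dark non-overlapping disks (pores) on a bright background, emulating a
#' thresholded SEM image of a lyophilized hydrogel cross-section. Disk
#' centres are drawn by rejection sampling so that disks neither overlap nor
#' touch the image border; the packing attempt is capped and a failure is
#' reported rather than silently accepting overlaps.
#'
#' `params`: either `radii` (vector of disk radii, um) or `n_disks` +
#' `radius_range = c(lo, hi)` um (radii drawn uniformly). Optional:
#' `noise_sd` (default 0), `max_attempts` per disk (default 1e4).
#'
#' @param spec a [synth_spec()] with `kind = "pores"`.
#' @return `list(stack, truth)`; `truth` carries the exact radii (um), the
#'   centres (px) and the areal porosity computed in closed form as
#'   `sum(pi r_px^2) / (rows * cols)`.
#' @export
generate_pore_texture <- function(spec) {
  stopifnot(spec$kind == "pores")
  noise_sd <- spec_param(spec, "noise_sd", 0)
  max_att <- spec_param(spec, "max_attempts", 1e4)
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  px <- spec$pixel_size

  gen <- with_seed(spec$seed, {
    radii_um <- spec$params$radii
    if (is.null(radii_um)) {
      n <- spec_param(spec, "n_disks")
      rng <- spec_param(spec, "radius_range")
      radii_um <- stats::runif(n, rng[1L], rng[2L])
    }
    radii_px <- radii_um / px
    centers <- matrix(NA_real_, length(radii_px), 2L)
    # place large disks first: greatly improves packing success
    ord <- order(radii_px, decreasing = TRUE)
    for (i in ord) {
      r <- radii_px[i]
      placed <- FALSE
      for (a in seq_len(max_att)) {
        cand <- c(stats::runif(1, 1 + r, nr - r), stats::runif(1, 1 + r, nc - r))
        ok <- TRUE
        for (j in seq_len(nrow(centers))) {
          if (j != i && !is.na(centers[j, 1L])) {
            if (sum((cand - centers[j, ])^2) <= (r + radii_px[j] + 1)^2) { ok <- FALSE; break }
          }
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) {
        stopf("pore packing failed: could not place disk of radius %.1f um without overlap in %d attempts",
              radii_um[i], max_att)
      }
    }
    noise <- if (noise_sd > 0) {
      array(stats::rnorm(nr * nc, sd = noise_sd), c(nr, nc))
    } else 0
    list(radii_um = radii_um, radii_px = radii_px, centers = centers, noise = noise)
  })

  img <- matrix(SYNTH_HIGH, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_along(gen$radii_px)) {
    m <- (rows - gen$centers[i, 1L])^2 + (cols - gen$centers[i, 2L])^2 <=
      gen$radii_px[i]^2
    img[m] <- SYNTH_HIGH * 0.1
  }
  img <- quantize16(img + gen$noise)

  truth <- list(
    kind = "pores",
    radii_um = gen$radii_um,
    centers_px = gen$centers,
    porosity = sum(pi * gen$radii_px^2) / (nr * nc)
  )
  list(stack = image_stack(img, pixel_size = px), truth = truth)
}
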