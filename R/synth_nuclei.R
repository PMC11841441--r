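#' Generate a synthetic LIVE/DEAD nuclei field
#'
#' Three-channel snapshot stack (`live`, `dead`, `nuclei`) of Gaussian blobs
#' emulating a calcein-AM / propidium-iodide / pan-nuclear stain. Blob
#' centres are drawn with a minimum separation by rejection sampling; the
#' all-nuclei channel contains the union of live and dead positions.
#'
#' `params`: `n_live`, `n_dead` (counts), `blob_radius` (Gaussian sigma,
#' um), `min_separation` (um). Optional: `noise_sd`, `max_attempts`
#' (default 1e4).
#'
#' @param spec a [synth_spec()] with `kind = "nuclei"`.
#' @return `list(stack, truth)`; `truth` carries the exact counts, centres,
#'   and `viability = n_live / (n_live + n_dead)` (`NA` with `empty_field =
#'   TRUE` when both counts are zero).
#' @export
generate_nuclei_field <- function(spec) {
  stopifnot(spec$kind == "nuclei")
  n_live <- spec_param(spec, "n_live")
  n_dead <- spec_param(spec, "n_dead")
  sigma_um <- spec_param(spec, "blob_radius", 3)
  sep_um <- spec_param(spec, "min_separation", 6 * sigma_um)
  noise_sd <- spec_param(spec, "noise_sd", 0)
  max_att <- spec_param(spec, "max_attempts", 1e4)
  px <- spec$pixel_size
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  sigma <- sigma_um / px
  sep <- sep_um / px
  margin <- 3 * sigma + 1

  gen <- with_seed(spec$seed, {
    n_tot <- n_live + n_dead
    centers <- matrix(NA_real_, max(n_tot, 1L), 2L)
    if (n_tot > 0) {
      for (i in seq_len(n_tot)) {
        placed <- FALSE
        for (a in seq_len(max_att)) {
          cand <- c(stats::runif(1, margin, nr - margin),
                    stats::runif(1, margin, nc - margin))
          ok <- i == 1L || all(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
            matrix(cand, i - 1L, 2L, byrow = TRUE))^2) >= sep^2)
          if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
        }
        if (!placed) {
          stopf("nuclei packing failed: could not place blob %d of %d with separation %.1f um in %d attempts",
                i, n_tot, sep_um, max_att)
        }
      }
    }
    noise <- if (noise_sd > 0) {
      array(stats::rnorm(nr * nc * 3, sd = noise_sd), c(nr, nc, 3L))
    } else 0
    list(centers = centers, noise = noise)
  })

  render <- function(ctrs) {
    img <- matrix(0, nr, nc)
    if (nrow(ctrs) == 0) return(img)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(nrow(ctrs))) {
      img <- img + exp(-((rows - ctrs[i, 1L])^2 + (cols - ctrs[i, 2L])^2) /
                         (2 * sigma^2))
    }
    img
  }
  live_ctr <- gen$centers[seq_len(n_live), , drop = FALSE]
  dead_ctr <- gen$centers[n_live + seq_len(n_dead), , drop = FALSE]
  frames <- array(0, dim = c(nr, nc, 3L))
  frames[, , 1L] <- render(live_ctr)
  frames[, , 2L] <- render(dead_ctr)
  frames[, , 3L] <- frames[, , 1L] + frames[, , 2L]
  frames <- quantize16(SYNTH_HIGH * pmin(frames, 1) + gen$noise)

  viability <- if (n_live + n_dead == 0) NA_real_ else n_live / (n_live + n_dead)
  truth <- list(
    kind = "nuclei", n_live = n_live, n_dead = n_dead,
    viability = viability, empty_field = (n_live + n_dead == 0),
    live_centers_px = live_ctr, dead_centers_px = dead_ctr
  )
  list(stack = image_stack(frames, pixel_size = px,
                           channels = c("live", "dead", "nuclei")),
       truth = truth)
}
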