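#' LIVE/DEAD viability from a multi-channel nuclei stack
#'
#' Counts labelled cells per channel by blob detection: each channel is
#' Gaussian-smoothed, thresholded with Otsu's method, and local intensity
#' maxima above the threshold are taken as cell centres, with close maxima
#' merged under a minimum-separation rule. Viability is
#' `n_live / (n_live + n_dead)`.
#'
#' @param stack an [image_stack()] with 2 or 3 frames (live, dead and
#'   optionally all-nuclei). Channel roles come from `channels`; when the
#'   stack carries channel names they are used to locate each role, so a
#'   swapped acquisition order is handled by naming.
#' @param channels character vector mapping the stack's frames to roles;
#'   default `c("live", "dead", "nuclei")` truncated to the stack depth.
#' @param smooth_sigma Gaussian smoothing sigma, px.
#' @param min_separation minimum distance between detected centres, px.
#' @return A `viability_result`: `n_live`, `n_dead`, `n_nuclei` (`NA` if no
#'   nuclei channel), `viability` (`NA` with `empty_field = TRUE` when both
#'   marker channels are empty).
#' @export
compute_viability <- function(stack, channels = NULL, smooth_sigma = 2,
                              min_separation = 5) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (nf < 2L) stopf("viability needs at least live and dead channels (2 frames)")
  if (is.null(channels)) channels <- stack$channels %||% c("live", "dead", "nuclei")[seq_len(nf)]
  if (length(channels) != nf) stopf("channels must name all %d frames", nf)

  count_blobs <- function(img) {
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
    thr <- otsu_threshold(sm)
    if (is.na(thr)) return(0L)
    w <- 2L * ceiling(min_separation / 2) + 1L
    mx <- EBImage::imageData(EBImage::dilate(EBImage::Image(sm),
                                             EBImage::makeBrush(w, "box")))
    cand <- which(sm >= mx - 1e-12 & sm > thr, arr.ind = TRUE)
    if (nrow(cand) == 0L) return(0L)
    # greedy non-maximum suppression for plateau ties / close peaks
    ord <- order(sm[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    kept <- matrix(numeric(0), 0L, 2L)
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (nrow(kept) == 0L ||
          all((kept[, 1L] - p[1L])^2 + (kept[, 2L] - p[2L])^2 >= min_separation^2)) {
        kept <- rbind(kept, p)
      }
    }
    nrow(kept)
  }

  idx <- function(role) {
    i <- which(channels == role)
    if (length(i) == 0L) NA_integer_ else i[1L]
  }
  n_live <- count_blobs(get_frame(stack, idx("live")))
  n_dead <- count_blobs(get_frame(stack, idx("dead")))
  n_nuclei <- if (!is.na(idx("nuclei"))) count_blobs(get_frame(stack, idx("nuclei"))) else NA_integer_

  empty <- (n_live + n_dead) == 0L
  if (empty) warnf("no cells detected in either marker channel: viability undefined")
  structure(list(
    n_live = n_live, n_dead = n_dead, n_nuclei = n_nuclei,
    viability = if (empty) NA_real_ else n_live / (n_live + n_dead),
    empty_field = empty
  ), class = "viability_result")
}
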