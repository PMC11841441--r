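# Vascular-permeability working equation: intensity accrual beside the
# channel normalized by the initial step over background, times d/4.
# d enters in cm so P lands in cm/s.
eq3_permeability <- function(I0, Ib, dIdt, d_um) {
  (1 / (I0 - Ib)) * dIdt * (um_to_cm(d_um) / 4)
}

#' Vascular permeability from a dextran-leak image series
#'
#' Estimates the apparent permeability of the channel wall from the
#' intensity rise in regions flanking the channel during tracer perfusion:
#' `P = (1 / (I0 - Ib)) * ((It - I0) / t) * (d / 4)` in cm/s, with `I0` the
#' ROI mean at the start of perfusion, `Ib` the pre-perfusion background,
#' `It` the ROI mean at time `t`, and `d` the channel diameter (applied in
#' cm). When `t_index` is not given, `(It - I0)/t` is replaced by the
#' least-squares slope of the ROI mean over all perfusion frames
#' (`method = "slope"`), which is exact for a linear leak.
#'
#' @param series an [image_stack()] time series; frame `background_frame`
#'   is the pre-perfusion background and perfusion starts at
#'   `start_frame` (time 0).
#' @param roi measurement region adjacent to (not overlapping) the channel:
#'   a `list(rows =, cols =)` rectangle, a list of such rectangles
#'   (averaged), or a logical mask matrix.
#' @param d channel diameter, um.
#' @param t_index optional frame index at which to evaluate the two-point
#'   estimate; counted in the stack's frames, must be `> start_frame`.
#' @param background_frame,start_frame frame indices (defaults 1 and 2).
#' @return A `permeability_result`: `P` (cm/s), `I0`, `Ib`, `It`, `t` (s),
#'   `d_um`, `method`, `slope` (intensity/s), `frame_interval`.
#' @export
compute_permeability <- function(series, roi, d, t_index = NULL,
                                 background_frame = 1L, start_frame = 2L) {
  stopifnot(inherits(series, "image_stack"))
  nf <- n_frames(series)
  if (nf < start_frame + 1L) stopf("need at least two perfusion frames plus background")
  if (is.na(series$frame_interval)) stopf("series has no frame_interval")

  roi_mean <- function(frame) {
    if (is.matrix(roi) && is.logical(roi)) return(mean(frame[roi]))
    rects <- if (!is.null(roi$rows)) list(roi) else roi
    mean(vapply(rects, function(r) roi_mean_rect(frame, r), numeric(1)))
  }
  means <- vapply(seq_len(nf), function(i) roi_mean(get_frame(series, i)), numeric(1))
  Ib <- means[background_frame]
  I0 <- means[start_frame]
  if (I0 <= Ib) {
    stopf("I0 (%.4g) must exceed the background Ib (%.4g): permeability undefined", I0, Ib)
  }
  dt <- series$frame_interval
  perfusion <- start_frame:nf
  times <- (perfusion - start_frame) * dt

  if (!is.null(t_index)) {
    if (t_index <= start_frame || t_index > nf) {
      stopf("t_index must be a frame index after start_frame (%d)", start_frame)
    }
    It <- means[t_index]
    t_s <- (t_index - start_frame) * dt
    slope <- (It - I0) / t_s
    method <- "point"
  } else {
    fitd <- stats::lm(y ~ x, data = data.frame(x = times, y = means[perfusion]))
    slope <- stats::coef(fitd)[["x"]]
    It <- means[nf]
    t_s <- times[length(times)]
    method <- "slope"
  }
  P <- eq3_permeability(I0, Ib, slope, d)
  if (P < -1e-12) {  # beyond round-off of the slope arithmetic
    warnf("It < I0: negative permeability (%.3g cm/s) -- photobleaching artifact?", P)
  }
  structure(list(P = P, I0 = I0, Ib = Ib, It = It, t = t_s, d_um = d,
                 slope = slope, method = method, frame_interval = dt),
            class = "permeability_result")
}

#' Compare permeability with and without an endothelial lining
#'
#' Reports the fold-change and percent reduction in permeability due to the
#' endothelial barrier. Both measurements must come from the same channel
#' diameter and acquisition timing; a mismatch is an error rather than a
#' silent unit inconsistency.
#'
#' @param with_cells `permeability_result` for the endothelialized channel.
#' @param without_cells `permeability_result` for the bare channel.
#' @return A list: `ratio` (`P_bare / P_endothelialized`),
#'   `percent_reduction` (`100 (1 - P_endo / P_bare)`), and the two inputs.
#' @export
compare_permeability <- function(with_cells, without_cells) {
  stopifnot(inherits(with_cells, "permeability_result"),
            inherits(without_cells, "permeability_result"))
  if (!isTRUE(all.equal(with_cells$d_um, without_cells$d_um)) ||
      !isTRUE(all.equal(with_cells$frame_interval, without_cells$frame_interval))) {
    stopf("acquisition mismatch: both measurements must share channel diameter and frame interval")
  }
  ratio <- without_cells$P / with_cells$P
  list(ratio = ratio,
       percent_reduction = 100 * (1 - with_cells$P / without_cells$P),
       with_cells = with_cells, without_cells = without_cells)
}

# Default flanking measurement regions: two rectangles one channel radius
# away from each channel edge, each half a channel-diameter wide, spanning
# the full image height.
default_leak_rois <- function(stack, channel_cols, d_px) {
  nr <- dim(stack$frames)[1L]; nc <- dim(stack$frames)[2L]
  r_px <- d_px / 2
  w <- max(2L, round(d_px / 2))
  left1 <- max(1L, round(channel_cols[1L] - r_px - w))
  left2 <- max(1L, round(channel_cols[1L] - r_px))
  right1 <- min(nc, round(channel_cols[2L] + r_px))
  right2 <- min(nc, round(channel_cols[2L] + r_px + w))
  list(list(rows = 1:nr, cols = left1:left2),
       list(rows = 1:nr, cols = right1:right2))
}
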