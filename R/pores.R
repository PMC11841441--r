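#' Porosity and pore-size distribution of a matrix texture image
#'
#' Quantifies an SEM-like grayscale image of a porous hydrogel
#' cross-section: Otsu's threshold separates the (dark) pore phase from the
#' (bright) matrix, connected components are labelled, and each pore is
#' summarized by its equivalent-circle radius `r = sqrt(A / pi)`. Areal
#' porosity is the pore-pixel fraction of the image.
#'
#' @param image an [image_stack()] (first frame used) or a numeric matrix.
#' @param pixel_size micrometres per pixel; defaults to the stack's
#'   metadata when `image` is an [image_stack()].
#' @param bin_edges histogram bin edges for the radius distribution, um;
#'   default 1-um bins spanning 0-20 um.
#' @param min_area smallest component (px) counted as a pore; default 4.
#' @return A `pore_stats`: `porosity` (fraction), `radii_um`, `histogram`
#'   (counts per bin), `bin_edges`.
#' @export
compute_pore_stats <- function(image, pixel_size = NULL,
                               bin_edges = seq(0, 20, by = 1), min_area = 4) {
  if (inherits(image, "image_stack")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    img <- get_frame(image, 1L)
  } else {
    img <- image
    if (is.null(pixel_size)) stopf("pixel_size is required when image is a bare matrix")
  }
  thr <- otsu_threshold(img)
  if (is.na(thr)) {
    porosity <- if (mean(img) < 0.5) 1 else 0
    warnf("uniform image: porosity reported as %g, no pores resolved", porosity)
    return(structure(list(porosity = porosity, radii_um = numeric(0),
                          histogram = integer(length(bin_edges) - 1L),
                          bin_edges = bin_edges),
                     class = "pore_stats"))
  }
  pore <- img < thr
  porosity <- mean(pore)
  labm <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(pore)))
  areas <- tabulate(labm[labm > 0])
  areas <- areas[areas >= min_area]
  radii <- sqrt(areas / pi) * pixel_size
  h <- graphics::hist(radii[radii >= bin_edges[1L] & radii <= max(bin_edges)],
                      breaks = bin_edges, plot = FALSE)
  structure(list(porosity = porosity, radii_um = radii,
                 histogram = h$counts, bin_edges = bin_edges),
            class = "pore_stats")
}
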