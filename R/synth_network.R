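#' Generate a synthetic endothelial-network mask
#'
#' Rasterizes a planar graph (vertex coordinates in um, edge list) into a
#' binary mask of strokes, emulating a segmented tube-formation image. The
#' ground truth carries the exact total edge length and the graph's circuit
#' rank (number of independent closed meshes), both computed directly from
#' the generating primitives.
#'
#' `params`: `vertices` (n x 2 matrix, um, (row, col) order), `edges`
#' (m x 2 integer matrix of vertex indices), `stroke_width` (um).
#' Edges shorter than twice the stroke width are refused: their skeleton
#' would not be recoverable.
#'
#' @param spec a [synth_spec()] with `kind = "network"`.
#' @return `list(stack, truth)`; `truth` carries `total_length_um`,
#'   `n_meshes` (circuit rank `E - V + C`), and the generating graph.
#' @export
generate_network_mask <- function(spec) {
  stopifnot(spec$kind == "network")
  verts <- spec_param(spec, "vertices")
  edges <- spec_param(spec, "edges")
  stroke <- spec_param(spec, "stroke_width", 3)
  px <- spec$pixel_size
  verts <- as.matrix(verts); edges <- as.matrix(edges)
  if (ncol(verts) != 2L || ncol(edges) != 2L) {
    stopf("vertices must be n x 2 (um) and edges m x 2 (indices)")
  }
  elen <- sqrt(rowSums((verts[edges[, 1L], , drop = FALSE] -
                          verts[edges[, 2L], , drop = FALSE])^2))
  if (any(elen < 2 * stroke)) {
    stopf("edge(s) shorter than 2 x stroke width (%g um): skeleton unrecoverable", 2 * stroke)
  }
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  vpx <- verts / px
  if (any(vpx < 2) || any(vpx[, 1L] > nr - 1) || any(vpx[, 2L] > nc - 1)) {
    stopf("vertex coordinates fall outside the %dx%d px image", nr, nc)
  }

  img <- matrix(0, nr, nc)
  half <- stroke / (2 * px)
  for (e in seq_len(nrow(edges))) {
    a <- vpx[edges[e, 1L], ]; b <- vpx[edges[e, 2L], ]
    r0 <- max(1L, floor(min(a[1L], b[1L]) - half - 1))
    r1 <- min(nr, ceiling(max(a[1L], b[1L]) + half + 1))
    c0 <- max(1L, floor(min(a[2L], b[2L]) - half - 1))
    c1 <- min(nc, ceiling(max(a[2L], b[2L]) + half + 1))
    rows <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
    cols <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
    ab <- b - a
    L2 <- sum(ab^2)
    t <- ((rows - a[1L]) * ab[1L] + (cols - a[2L]) * ab[2L]) / L2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (rows - (a[1L] + t * ab[1L]))^2 + (cols - (a[2L] + t * ab[2L]))^2
    blk <- img[r0:r1, c0:c1]
    blk[d2 <= half^2] <- SYNTH_HIGH
    img[r0:r1, c0:c1] <- blk
  }
  img <- quantize16(img)

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(verts)) {
    g <- igraph::add_vertices(g, nrow(verts) - igraph::vcount(g))
  }
  n_meshes <- nrow(edges) - nrow(verts) + igraph::components(g)$no

  truth <- list(
    kind = "network",
    total_length_um = sum(elen),
    n_meshes = n_meshes,
    vertices_um = verts, edges = edges, stroke_width_um = stroke
  )
  list(stack = image_stack(img, pixel_size = px), truth = truth)
}
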