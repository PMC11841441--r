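# Morphological skeletonization by Guo-Hall thinning (vectorized).
# No installed package provides 2-D skeletonization, so it is implemented
# here; Guo-Hall preserves 8-connectivity and line endpoints and, unlike
# Zhang-Suen, reduces diagonal strokes to single-pixel-wide skeletons.
guo_hall_thin <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  nr <- nrow(img); nc <- ncol(img)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  repeat {
    changed <- FALSE
    for (it in 0:1) {
      z <- matrix(0L, nr + 2L, nc + 2L)
      z[ri, ci] <- img
      p2 <- z[ri - 1L, ci];      p3 <- z[ri - 1L, ci + 1L]
      p4 <- z[ri, ci + 1L];      p5 <- z[ri + 1L, ci + 1L]
      p6 <- z[ri + 1L, ci];      p7 <- z[ri + 1L, ci - 1L]
      p8 <- z[ri, ci - 1L];      p9 <- z[ri - 1L, ci - 1L]
      C <- ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
           ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (it == 0L) ((p6 | p7 | (!p9)) & p8) else ((p2 | p3 | (!p5)) & p4)
      cond <- img == 1L & C == 1L & N >= 2L & N <= 3L & m == 0L
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

# 8-neighbour count of each skeleton pixel
neighbor_count <- function(skel) {
  z <- matrix(0L, nrow(skel) + 2L, ncol(skel) + 2L)
  z[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- as.integer(skel)
  nr <- nrow(skel); nc <- ncol(skel)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  cnt <- z[ri - 1L, ci] + z[ri + 1L, ci] + z[ri, ci - 1L] + z[ri, ci + 1L] +
    z[ri - 1L, ci - 1L] + z[ri - 1L, ci + 1L] + z[ri + 1L, ci - 1L] + z[ri + 1L, ci + 1L]
  cnt * as.integer(skel)
}

# 8-connected component labels for a sparse pixel mask (EBImage::bwlabel is
# 4-connected, which would fragment diagonal skeleton chains)
label8 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  nr <- nrow(mask)
  id_of <- integer(length(mask))   # linear index -> compact pixel id
  id_of[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  el <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nrr <- rr + off[1L]; ncc <- cc + off[2L]
    ok <- nrr >= 1L & nrr <= nr & ncc >= 1L & ncc <= ncol(mask)
    nidx <- (ncc - 1L) * nr + nrr
    hit <- which(ok)[mask[nidx[ok]]]
    if (length(hit) > 0L) {
      el[[length(el) + 1L]] <- cbind(hit, id_of[nidx[hit]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(el) > 0L) g <- igraph::add_edges(g, t(do.call(rbind, el)))
  memb <- igraph::components(g)$membership
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[idx] <- memb
  out
}

# order the pixels of a degree-<=2 chain into a path (or cycle)
order_chain <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(px)
  key <- px[, 1L] * 1e6 + px[, 2L]
  adj <- lapply(seq_len(n), function(i) {
    d1 <- abs(px[, 1L] - px[i, 1L]); d2 <- abs(px[, 2L] - px[i, 2L])
    setdiff(which(d1 <= 1L & d2 <= 1L), i)
  })
  deg <- lengths(adj)
  start <- if (any(deg <= 1L)) which(deg <= 1L)[1L] else 1L
  path <- integer(n)
  path[1L] <- start
  used <- rep(FALSE, n); used[start] <- TRUE
  for (k in 2:n) {
    nxt <- adj[[path[k - 1L]]]
    nxt <- nxt[!used[nxt]]
    if (length(nxt) == 0L) { path <- path[seq_len(k - 1L)]; break }
    path[k] <- nxt[1L]
    used[nxt[1L]] <- TRUE
  }
  px[path, , drop = FALSE]
}

#' Quantify an endothelial network mask
#'
#' Simplified tube-formation readout: the binary mask is skeletonized
#' (Guo-Hall thinning), the skeleton is decomposed into a spatial graph
#' of junctions, endpoints and connecting branches, and the two quantities
#' the assay reports are extracted -- total sprout length (um) and the
#' number of closed meshes, computed as the graph's circuit rank
#' `edges - nodes + connected components`.
#'
#' Branch lengths are geodesic: each branch's pixel path is simplified
#' (Douglas-Peucker, 1 px) before measuring, which removes the raster
#' staircase bias. Junction pixels closer than 3 px are merged into one
#' node to avoid spurious micro-edges, and open branch ends are extended by
#' the local stroke half-width (distance transform at the endpoint), since
#' the medial axis of a round-capped stroke stops half a width short of its
#' tip.
#'
#' @param mask an [image_stack()] (first frame) or matrix; foreground is
#'   `> 0.5` (after binarizing at 0.5 of the intensity range).
#' @param pixel_size micrometres per pixel; defaults to the stack metadata.
#' @return A `network_graph`: `total_length_um`, `n_meshes`, `n_nodes`,
#'   `n_edges`, `edge_lengths_um`, `graph` (igraph), `skeleton` (logical
#'   matrix).
#' @export
analyze_network <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "image_stack")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    img <- get_frame(mask, 1L)
  } else {
    img <- mask
    if (is.null(pixel_size)) stopf("pixel_size is required when mask is a bare matrix")
  }
  bw <- img > (min(img) + max(img)) / 2
  if (!any(bw)) {
    warnf("empty mask: returning an empty network")
    return(structure(list(total_length_um = 0, n_meshes = 0L, n_nodes = 0L,
                          n_edges = 0L, edge_lengths_um = numeric(0),
                          graph = igraph::make_empty_graph(directed = FALSE),
                          skeleton = bw),
                     class = "network_graph"))
  }
  skel <- guo_hall_thin(bw)
  dmap <- EBImage::imageData(EBImage::distmap(EBImage::Image(bw * 1)))
  cnt <- neighbor_count(skel)

  junc <- which(skel & cnt >= 3L, arr.ind = TRUE)
  ends <- which(skel & cnt == 1L, arr.ind = TRUE)
  isolated <- which(skel & cnt == 0L, arr.ind = TRUE)

  # merge junction pixels within 3 px into supernodes
  node_id <- matrix(0L, nrow(skel), ncol(skel))
  next_id <- 0L
  if (nrow(junc) > 0L) {
    dmat <- as.matrix(stats::dist(junc))
    gj <- igraph::graph_from_adjacency_matrix(dmat <= 3, mode = "undirected",
                                              diag = FALSE)
    comp <- igraph::components(gj)$membership
    next_id <- max(comp)
    node_id[junc] <- comp
  }
  for (i in seq_len(nrow(ends))) {
    next_id <- next_id + 1L
    node_id[ends[i, , drop = FALSE]] <- next_id
  }
  for (i in seq_len(nrow(isolated))) {
    next_id <- next_id + 1L
    node_id[isolated[i, , drop = FALSE]] <- next_id
  }
  n_nodes <- next_id

  is_node <- node_id > 0L
  chain_mask <- skel & !is_node
  edges <- list()

  # node pixels 8-adjacent to a given pixel
  adjacent_nodes <- function(p) {
    rr <- max(1L, p[1L] - 1L):min(nrow(skel), p[1L] + 1L)
    cc <- max(1L, p[2L] - 1L):min(ncol(skel), p[2L] + 1L)
    ids <- node_id[rr, cc]
    unique(ids[ids > 0L])
  }

  connected_pairs <- character(0)   # dedupe tiny connectors around junctions
  if (any(chain_mask)) {
    labm <- label8(chain_mask)
    for (k in seq_len(max(labm))) {
      px <- which(labm == k, arr.ind = TRUE)
      path <- order_chain(px)
      a_nodes <- adjacent_nodes(path[1L, ])
      b_nodes <- adjacent_nodes(path[nrow(path), ])
      a <- if (length(a_nodes) > 0L) a_nodes[1L] else NA_integer_
      b <- if (length(b_nodes) > 0L) {
        bb <- setdiff(b_nodes, if (nrow(path) == 1L) a_nodes[1L] else integer(0))
        if (length(bb) > 0L) bb[1L] else b_nodes[1L]
      } else NA_integer_
      if (is.na(a) && is.na(b)) {
        # isolated chain: open filament or closed ring
        ring <- nrow(path) >= 4L &&
          all(abs(path[1L, ] - path[nrow(path), ]) <= 1L)
        L <- polyline_length(dp_simplify(path, 1), closed = FALSE)
        if (ring) {
          L <- polyline_length(dp_simplify_closed(path, 1), closed = TRUE)
          next_id <- next_id + 1L
          edges[[length(edges) + 1L]] <- list(from = next_id, to = next_id, len = L)
          n_nodes <- next_id
        } else {
          # open filament with eroded tips: two implicit endpoint nodes
          L <- L + dmap[path[1L, , drop = FALSE]] + dmap[path[nrow(path), , drop = FALSE]]
          edges[[length(edges) + 1L]] <- list(from = n_nodes + 1L, to = n_nodes + 2L, len = L)
          n_nodes <- n_nodes + 2L
          next_id <- n_nodes
        }
        next
      }
      # debris inside a junction region: a short chain re-entering the same
      # node is part of the junction, not a closed mesh
      if (!is.na(a) && !is.na(b) && a == b && nrow(path) <= 6L) next
      if (nrow(path) <= 2L && !is.na(a) && !is.na(b) && a != b) {
        key <- paste(sort(c(a, b)), collapse = "-")
        if (key %in% connected_pairs) next
        connected_pairs <- c(connected_pairs, key)
      }
      L <- polyline_length(dp_simplify(path, 1), closed = FALSE)
      # connection steps chain-end -> node pixel (~1 px each) and tip extension
      if (!is.na(a)) L <- L + 1 else L <- L + dmap[path[1L, , drop = FALSE]]
      if (!is.na(b)) L <- L + 1 else L <- L + dmap[path[nrow(path), , drop = FALSE]]
      # dangling side: attach a fresh endpoint node so the edge exists
      if (is.na(a)) { n_nodes <- n_nodes + 1L; a <- n_nodes }
      if (is.na(b)) { n_nodes <- n_nodes + 1L; b <- n_nodes }
      edges[[length(edges) + 1L]] <- list(from = a, to = b, len = L)
    }
  }

  # endpoint nodes: extend by local half-width (medial axis stops short of tips)
  if (nrow(ends) > 0L) {
    for (i in seq_len(nrow(ends))) {
      id <- node_id[ends[i, , drop = FALSE]]
      hit <- which(vapply(edges, function(e) e$from == id || e$to == id, logical(1)))
      if (length(hit) > 0L) {
        edges[[hit[1L]]]$len <- edges[[hit[1L]]]$len + dmap[ends[i, , drop = FALSE]] - 1
      }
    }
  }

  # direct junction-junction contacts with no chain between them
  if (nrow(junc) > 0L) {
    seen <- connected_pairs
    for (i in seq_len(nrow(junc))) {
      p <- junc[i, ]
      rr <- max(1L, p[1L] - 1L):min(nrow(skel), p[1L] + 1L)
      cc <- max(1L, p[2L] - 1L):min(ncol(skel), p[2L] + 1L)
      ids <- unique(node_id[rr, cc])
      ids <- ids[ids > 0L & ids != node_id[p[1L], p[2L]]]
      for (j in ids) {
        key <- paste(sort(c(node_id[p[1L], p[2L]], j)), collapse = "-")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          edges[[length(edges) + 1L]] <- list(from = node_id[p[1L], p[2L]], to = j, len = 1.5)
        }
      }
    }
  }

  n_edges <- length(edges)
  el <- if (n_edges > 0L) {
    do.call(rbind, lapply(edges, function(e) c(e$from, e$to)))
  } else matrix(integer(0), 0L, 2L)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n_nodes) g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  comp_no <- if (n_nodes > 0L) igraph::components(g)$no else 0L
  n_meshes <- max(0L, n_edges - n_nodes + comp_no)
  lens_um <- vapply(edges, function(e) e$len, numeric(1)) * pixel_size

  structure(list(
    total_length_um = sum(lens_um), n_meshes = n_meshes,
    n_nodes = n_nodes, n_edges = n_edges, edge_lengths_um = lens_um,
    graph = g, skeleton = skel
  ), class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> total length %.1f um, %d mesh(es), %d node(s), %d edge(s)\n",
              x$total_length_um, x$n_meshes, x$n_nodes, x$n_edges))
  invisible(x)
}

#' Sprouting time course from a series of network graphs
#'
#' Tabulates total sprout length and mesh count per timepoint together with
#' the successive differences, the quantities used to describe network
#' growth over culture time.
#'
#' @param graphs ordered list of `network_graph` objects (>= 2 timepoints).
#' @param timepoints optional numeric vector (e.g. culture day) of the same
#'   length; defaults to `1:n`.
#' @return A data.frame with columns `timepoint`, `total_length_um`,
#'   `n_meshes`, `delta_length_um`, `delta_meshes`.
#' @export
sprout_timecourse <- function(graphs, timepoints = seq_along(graphs)) {
  if (length(graphs) < 2L) stopf("a time course needs at least two timepoints")
  stopifnot(all(vapply(graphs, inherits, logical(1), "network_graph")))
  len <- vapply(graphs, `[[`, numeric(1), "total_length_um")
  msh <- vapply(graphs, function(g) as.numeric(g$n_meshes), numeric(1))
  data.frame(
    timepoint = timepoints,
    total_length_um = len,
    n_meshes = msh,
    delta_length_um = c(NA, diff(len)),
    delta_meshes = c(NA, diff(msh))
  )
}
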