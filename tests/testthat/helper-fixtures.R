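# Shared fixture builders. Everything is generated in code at test time.

# distance between two segments (used to keep generated networks resolvable)
point_seg_dist <- function(a, b, p) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 == 0) return(sqrt(sum((p - a)^2)))
  t <- min(max(sum((p - a) * ab) / L2, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}
seg_seg_dist <- function(p1, p2, q1, q2) {
  min(point_seg_dist(p1, p2, q1), point_seg_dist(p1, p2, q2),
      point_seg_dist(q1, q2, p1), point_seg_dist(q1, q2, p2))
}

# Random planar tree with n_vertices, edge lengths in [30, 150] um, at least
# `clearance` um between non-adjacent edges and `min_angle` degrees between
# edges sharing a vertex -- the conditions under which a stroke rendering of
# the tree is skeleton-recoverable (strokes neither merge nor overlap).
make_random_tree <- function(seed, n_vertices = 21, lim = c(20, 430),
                             clearance = 8, min_angle = 30) {
  set.seed(seed)
  pts <- matrix(stats::runif(2, lim[1], lim[2]), 1, 2)
  ed <- matrix(integer(0), 0, 2)
  guard <- 0
  while (nrow(pts) < n_vertices && guard < 20000) {
    guard <- guard + 1
    cand <- stats::runif(2, lim[1], lim[2])
    d <- sqrt(rowSums((pts - matrix(cand, nrow(pts), 2, byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] < 30 || d[j] > 150) next
    ok <- TRUE
    if (nrow(ed) > 0) for (e in seq_len(nrow(ed))) {
      if (ed[e, 1] != j && ed[e, 2] != j) {
        if (seg_seg_dist(pts[ed[e, 1], ], pts[ed[e, 2], ], pts[j, ], cand) < clearance) {
          ok <- FALSE; break
        }
      } else {
        other <- if (ed[e, 1] == j) ed[e, 2] else ed[e, 1]
        v1 <- cand - pts[j, ]; v2 <- pts[other, ] - pts[j, ]
        ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
        if (ang < min_angle) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    pts <- rbind(pts, cand)
    ed <- rbind(ed, c(j, nrow(pts)))
  }
  list(vertices = pts, edges = ed)
}

# FRAP spec with the standard acquisition protocol: the series ends about
# 10 diffusion times after the bleach (shortly after the recovery plateaus)
frap_spec <- function(D_true, seed = 1, roi_radius = 10, noise_sd = 0,
                      n_frames = 40L, shape = c(96L, 96L)) {
  tauD <- roi_radius^2 / (4 * D_true)
  synth_spec("frap", seed = seed, pixel_size = 1, shape = shape,
             frame_interval = round(10 * tauD / n_frames, 4),
             params = list(D_true = D_true, roi_radius = roi_radius,
                           bleach_depth = 0.8, pre_bleach = 2L,
                           n_frames = n_frames, noise_sd = noise_sd))
}

leak_spec <- function(seed = 1, k = 1e-4, d = 500, I0 = 0.35, Ib = 0.1,
                      duration = 1800, frame_interval = 30) {
  synth_spec("leak", seed = seed, pixel_size = 4, shape = c(128L, 192L),
             frame_interval = frame_interval,
             params = list(d = d, I0 = I0, Ib = Ib, k = k, duration = duration))
}

grid_spec <- function(shape_kind, seed = 1) {
  synth_spec("grid", seed = seed, pixel_size = 10, shape = c(420L, 420L),
             params = list(pore_shape = shape_kind, pore_size = 1000, wall = 200))
}

triangle_network_spec <- function(seed = 2) {
  synth_spec("network", seed = seed, pixel_size = 1, shape = c(200L, 200L),
             params = list(vertices = rbind(c(40, 40), c(40, 160), c(150, 100)),
                           edges = rbind(c(1, 2), c(2, 3), c(3, 1)),
                           stroke_width = 3))
}
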