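test_that("identical specs give bit-identical stacks and ground truth", {
  for (spec in list(frap_spec(13.2, seed = 7, noise_sd = 0.02, n_frames = 6L,
                              shape = c(48L, 48L)),
                    leak_spec(seed = 7, duration = 120),
                    synth_spec("pores", seed = 7, shape = c(96L, 96L),
                               params = list(n_disks = 8L, radius_range = c(5, 10),
                                             noise_sd = 0.02)),
                    synth_spec("nuclei", seed = 7, shape = c(96L, 96L),
                               params = list(n_live = 8L, n_dead = 2L,
                                             blob_radius = 2, min_separation = 10)))) {
    g1 <- generate_synthetic(spec)
    g2 <- generate_synthetic(spec)
    expect_identical(g1$stack$frames, g2$stack$frames)
    expect_identical(g1$truth, g2$truth)
  }
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  expected <- stats::runif(3)
  set.seed(123)
  invisible(generate_pore_texture(synth_spec("pores", seed = 99, shape = c(64L, 64L),
                                             params = list(radii = c(5)))))
  expect_identical(stats::runif(3), expected)
})

test_that("frap generator: no diffusion means no recovery, and dye returns at equilibrium", {
  # D = 0: every post-bleach frame identical to the first post-bleach frame
  sp0 <- synth_spec("frap", seed = 1, shape = c(48L, 48L), frame_interval = 0.5,
                    params = list(D_true = 0, roi_radius = 8, bleach_depth = 0.8,
                                  pre_bleach = 1L, n_frames = 5L, noise_sd = 0))
  g0 <- generate_frap_stack(sp0)
  bf <- g0$truth$bleach_frame
  for (i in (bf + 1):dim(g0$stack$frames)[3]) {
    expect_identical(g0$stack$frames[, , i], g0$stack$frames[, , bf])
  }

  # long-time limit: ROI mean returns to the pre-bleach level (within 2%)
  spL <- synth_spec("frap", seed = 1, pixel_size = 1, shape = c(48L, 48L),
                    frame_interval = 2,
                    params = list(D_true = 25, roi_radius = 6, bleach_depth = 0.8,
                                  pre_bleach = 1L, n_frames = 30L, noise_sd = 0,
                                  pad_px = 96L))
  gL <- generate_frap_stack(spL)
  last <- dim(gL$stack$frames)[3]
  roi_final <- perfuseR:::roi_mean_disk(gL$stack$frames[, , last],
                                        gL$truth$roi_center_px,
                                        gL$truth$roi_radius_px)
  expect_lt(abs(roi_final - gL$truth$pre_bleach_level) / gL$truth$pre_bleach_level, 0.02)
})

test_that("frap generator refuses an unstable explicit time step", {
  sp <- synth_spec("frap", seed = 1, shape = c(48L, 48L), frame_interval = 0.5,
                   params = list(D_true = 25, roi_radius = 8, bleach_depth = 0.8,
                                 pre_bleach = 1L, n_frames = 3L, noise_sd = 0,
                                 dt = 1))  # far above dx^2/(4D) = 0.01 s
  expect_error(generate_frap_stack(sp), "stability bound")
  expect_error(generate_frap_stack(
    synth_spec("frap", seed = 1, shape = c(48L, 48L), frame_interval = 0.5,
               params = list(D_true = 25, roi_radius = 8, bleach_depth = 0.8,
                             pre_bleach = 0L, n_frames = 3L, noise_sd = 0))),
    "pre-bleach")
})

test_that("leak ground truth follows the permeability equation", {
  # k = 0: no leak, P_true = 0
  g0 <- generate_leak_series(leak_spec(seed = 1, k = 0, duration = 120))
  expect_identical(g0$truth$P_true, 0)

  # worked arithmetic: I0-Ib = 100 units, It-I0 = 10 at t = 30 s, d = 1000 um
  # (intensities expressed as fractions of full scale; the ratio is what matters)
  g1 <- generate_leak_series(
    synth_spec("leak", seed = 1, pixel_size = 10, shape = c(64L, 192L),
               frame_interval = 30,
               params = list(d = 1000, I0 = 0.2, Ib = 0.1, k = 0.1 / 30 / 10,
                             duration = 60)))
  expect_equal(g1$truth$P_true, (1 / 0.1) * (0.01 / 30) * (0.1 / 4),
               tolerance = 1e-12)
  expect_equal(g1$truth$P_true, 8.333e-5, tolerance = 1e-3)

  # doubling d doubles P_true
  g2 <- generate_leak_series(leak_spec(seed = 1, d = 250, duration = 120))
  g3 <- generate_leak_series(leak_spec(seed = 1, d = 500, duration = 120))
  expect_equal(g3$truth$P_true / g2$truth$P_true, 2, tolerance = 1e-12)

  expect_error(generate_leak_series(leak_spec(seed = 1, I0 = 0.1, Ib = 0.2)),
               "permeability is undefined")
})

test_that("pore texture ground truth is the analytic disk-area fraction", {
  g0 <- generate_pore_texture(synth_spec("pores", seed = 1, shape = c(64L, 64L),
                                         params = list(radii = numeric(0))))
  expect_equal(g0$truth$porosity, 0)

  # one 10 um disk in a 100 x 100 um field: porosity = pi 100 / 1e4
  g1 <- generate_pore_texture(synth_spec("pores", seed = 1, shape = c(100L, 100L),
                                         params = list(radii = c(10))))
  expect_equal(g1$truth$porosity, pi * 100 / 1e4, tolerance = 1e-12)

  # unplaceable packing is a packing error, not an infinite loop
  expect_error(generate_pore_texture(
    synth_spec("pores", seed = 1, shape = c(64L, 64L),
               params = list(radii = rep(14, 30), max_attempts = 50))),
    "packing failed")
})

test_that("grid ground truth matches the analytic shape-fidelity values", {
  gs <- generate_grid_print(grid_spec("square"))
  expect_equal(unname(gs$truth$Pr), rep(1, 9), tolerance = 1e-12)
  gc <- generate_grid_print(grid_spec("circle"))
  expect_equal(unname(gc$truth$Pr), rep(pi / 4, 9), tolerance = 1e-12)
  gst <- generate_grid_print(grid_spec("star"))
  expect_true(all(gst$truth$Pr > 1))

  expect_error(generate_grid_print(
    synth_spec("grid", seed = 1, pixel_size = 10, shape = c(420L, 420L),
               params = list(pore_shape = "square", pore_size = 30, wall = 200))),
    "below 4 px")
})

test_that("nuclei ground truth carries counts and viability", {
  g <- generate_nuclei_field(synth_spec("nuclei", seed = 3, shape = c(128L, 128L),
                                        params = list(n_live = 18L, n_dead = 2L,
                                                      blob_radius = 2,
                                                      min_separation = 10)))
  expect_equal(g$truth$viability, 0.9)
  expect_equal(dim(g$stack$frames)[3], 3L)

  g1 <- generate_nuclei_field(synth_spec("nuclei", seed = 3, shape = c(128L, 128L),
                                         params = list(n_live = 10L, n_dead = 0L,
                                                       blob_radius = 2,
                                                       min_separation = 10)))
  expect_equal(g1$truth$viability, 1.0)

  g2 <- generate_nuclei_field(synth_spec("nuclei", seed = 3, shape = c(64L, 64L),
                                         params = list(n_live = 0L, n_dead = 0L,
                                                       blob_radius = 2,
                                                       min_separation = 10)))
  expect_true(g2$truth$empty_field)
  expect_true(is.na(g2$truth$viability))

  expect_error(generate_nuclei_field(
    synth_spec("nuclei", seed = 3, shape = c(32L, 32L),
               params = list(n_live = 200L, n_dead = 0L, blob_radius = 3,
                             min_separation = 20, max_attempts = 30))),
    "packing failed")
})

test_that("network ground truth: edge-length sum and circuit rank", {
  # single 100 um edge
  g1 <- generate_network_mask(
    synth_spec("network", seed = 1, shape = c(64L, 128L),
               params = list(vertices = rbind(c(32, 10), c(32, 110)),
                             edges = rbind(c(1, 2)), stroke_width = 3)))
  expect_equal(g1$truth$total_length_um, 100)
  expect_equal(g1$truth$n_meshes, 0L)

  # triangle: one closed mesh
  g2 <- generate_network_mask(triangle_network_spec())
  expect_equal(g2$truth$n_meshes, 1L)

  # random tree: 20 edges, rank 0, length = brute-force sum over the edge list
  tr <- make_random_tree(seed = 5)
  g3 <- generate_network_mask(
    synth_spec("network", seed = 5, shape = c(450L, 450L),
               params = list(vertices = tr$vertices, edges = tr$edges,
                             stroke_width = 3)))
  brute <- sum(sqrt(rowSums((tr$vertices[tr$edges[, 1], , drop = FALSE] -
                               tr$vertices[tr$edges[, 2], , drop = FALSE])^2)))
  expect_equal(g3$truth$total_length_um, brute, tolerance = 1e-12)
  expect_equal(g3$truth$n_meshes, 0L)

  expect_error(generate_network_mask(
    synth_spec("network", seed = 1, shape = c(64L, 64L),
               params = list(vertices = rbind(c(32, 30), c(32, 34)),
                             edges = rbind(c(1, 2)), stroke_width = 3))),
    "skeleton unrecoverable")
})
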