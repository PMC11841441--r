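test_that("printability scores the analytic shapes correctly", {
  pr_sq <- compute_printability(generate_grid_print(grid_spec("square"))$stack)
  expect_equal(pr_sq$n_pores, 9L)
  expect_lt(abs(pr_sq$mean_Pr - 1), 0.02)

  pr_ci <- compute_printability(generate_grid_print(grid_spec("circle"))$stack)
  expect_lt(abs(pr_ci$mean_Pr - pi / 4), 0.02)

  pr_st <- compute_printability(generate_grid_print(grid_spec("star"))$stack)
  expect_true(all(pr_st$Pr > 1))

  expect_error(compute_printability(matrix(0.9, 64, 64)), "no enclosed pore")
})

test_that("printability is scale-invariant under integer upscaling (< 3%)", {
  img <- generate_grid_print(grid_spec("square"))$stack$frames[, , 1]
  up <- img[rep(seq_len(nrow(img)), each = 2), rep(seq_len(ncol(img)), each = 2)]
  pr1 <- compute_printability(img)
  pr2 <- compute_printability(up)
  expect_lt(abs(pr2$mean_Pr - pr1$mean_Pr) / pr1$mean_Pr, 0.03)
})

test_that("porosity and pore radii are recovered from generated textures", {
  gen <- generate_pore_texture(synth_spec("pores", seed = 2, shape = c(256L, 256L),
                                          params = list(n_disks = 40L,
                                                        radius_range = c(5, 14))))
  st <- compute_pore_stats(gen$stack)
  expect_lt(abs(st$porosity - gen$truth$porosity), 0.02)
  expect_equal(length(st$radii_um), length(gen$truth$radii_um))
  err <- abs(sort(st$radii_um) - sort(gen$truth$radii_um))
  expect_lt(max(err), 1 * gen$stack$pixel_size)   # within one pixel-equivalent
  # the distribution occupies the generating 5-14 um regime
  occupied <- which(st$histogram > 0)
  expect_gte(st$bin_edges[min(occupied)], 4)
  expect_lte(st$bin_edges[max(occupied) + 1], 15)
})

test_that("degenerate textures report porosity 0 or 1 with a warning", {
  expect_warning(s0 <- compute_pore_stats(matrix(0.9, 64, 64), pixel_size = 1),
                 "uniform")
  expect_equal(s0$porosity, 0)
  expect_warning(s1 <- compute_pore_stats(matrix(0.05, 64, 64), pixel_size = 1),
                 "uniform")
  expect_equal(s1$porosity, 1)
})

test_that("viability counts generated fields exactly and respects channel naming", {
  gen <- generate_nuclei_field(synth_spec("nuclei", seed = 3, shape = c(256L, 256L),
                                          params = list(n_live = 90L, n_dead = 10L,
                                                        blob_radius = 2,
                                                        min_separation = 12)))
  v <- compute_viability(gen$stack)
  expect_equal(v$n_live, 90L)
  expect_equal(v$n_dead, 10L)
  expect_equal(v$viability, 0.90)
  expect_lte(v$n_live + v$n_dead, ceiling(1.05 * v$n_nuclei))

  # swapped channel roles complement the viability
  vs <- compute_viability(gen$stack, channels = c("dead", "live", "nuclei"))
  expect_equal(vs$viability, 0.10)

  g1 <- generate_nuclei_field(synth_spec("nuclei", seed = 4, shape = c(192L, 192L),
                                         params = list(n_live = 40L, n_dead = 0L,
                                                       blob_radius = 2,
                                                       min_separation = 12)))
  expect_equal(compute_viability(g1$stack)$viability, 1.0)

  empty <- image_stack(array(0, dim = c(64, 64, 2)), pixel_size = 1,
                       channels = c("live", "dead"))
  expect_warning(ve <- compute_viability(empty), "undefined")
  expect_true(ve$empty_field)
  expect_true(is.na(ve$viability))
})

test_that("permeability estimator is exact on noise-free linear leak series", {
  gen <- generate_leak_series(leak_spec(seed = 5))
  rois <- perfuseR:::default_leak_rois(gen$stack, gen$truth$channel_cols,
                                       500 / gen$stack$pixel_size)
  p <- compute_permeability(gen$stack, rois, d = 500)
  expect_identical(p$method, "slope")
  # linear series, flat ROI: slope regression is exact up to 16-bit rounding
  expect_lt(abs(p$P - gen$truth$P_true) / gen$truth$P_true, 1e-3)

  # static series: P identically 0, and no spurious negativity warning
  g0 <- generate_leak_series(leak_spec(seed = 5, k = 0, duration = 300))
  expect_no_warning(p0 <- compute_permeability(g0$stack, rois, d = 500))
  expect_equal(p0$P, 0, tolerance = 1e-12)

  # a fading series (photobleaching) reports a negative estimate with a warning
  gneg <- generate_leak_series(leak_spec(seed = 5, k = -5e-5, duration = 300))
  expect_warning(pneg <- compute_permeability(gneg$stack, rois, d = 500),
                 "photobleaching")
  expect_lt(pneg$P, 0)
})

test_that("permeability point estimate reproduces the worked equation value", {
  # I0-Ib = 0.1, It-I0 = 0.01 at t = 30 s, d = 1000 um -> 8.33e-5 cm/s
  gen <- generate_leak_series(
    synth_spec("leak", seed = 1, pixel_size = 10, shape = c(64L, 192L),
               frame_interval = 30,
               params = list(d = 1000, I0 = 0.2, Ib = 0.1, k = 0.01 / 30,
                             duration = 60)))
  rois <- perfuseR:::default_leak_rois(gen$stack, gen$truth$channel_cols, 100)
  p <- compute_permeability(gen$stack, rois, d = 1000, t_index = 3L)
  expect_equal(p$P, 8.333e-5, tolerance = 1e-2)
  expect_identical(p$method, "point")

  expect_error(compute_permeability(gen$stack, rois, d = 1000, t_index = 2L),
               "t_index")
})

test_that("the endothelial barrier comparison recovers the constructed reduction", {
  g_bare <- generate_leak_series(leak_spec(seed = 6, k = 1e-4))
  g_endo <- generate_leak_series(leak_spec(seed = 7, k = 2e-5))
  rois <- perfuseR:::default_leak_rois(g_bare$stack, g_bare$truth$channel_cols, 125)
  p_bare <- compute_permeability(g_bare$stack, rois, d = 500)
  p_endo <- compute_permeability(g_endo$stack, rois, d = 500)

  cmp <- compare_permeability(p_endo, p_bare)
  expect_equal(cmp$ratio, 5, tolerance = 0.05)
  expect_lt(abs(cmp$percent_reduction - 80), 5)

  # identical inputs: ratio 1, zero reduction
  cmp0 <- compare_permeability(p_bare, p_bare)
  expect_equal(cmp0$ratio, 1)
  expect_equal(cmp0$percent_reduction, 0)

  # acquisition mismatch is an error
  p_alt <- p_endo; p_alt$d_um <- 400
  expect_error(compare_permeability(p_alt, p_bare), "mismatch")
})
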