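test_that("a stack without a bleach is rejected", {
  const <- image_stack(array(0.5, dim = c(48, 48, 6)), pixel_size = 1,
                       frame_interval = 0.5)
  expect_error(extract_recovery_curve(const, c(24, 24), 8, bleach_frame = 2),
               "no bleach detected")
})

test_that("noise-free recovery curves are nondecreasing and saturate at 1", {
  gen <- generate_frap_stack(frap_spec(13.2, seed = 1, n_frames = 60L))
  curve <- extract_recovery_curve(gen$stack, gen$truth$roi_center_px,
                                  gen$truth$roi_radius_px,
                                  gen$truth$bleach_frame)
  expect_equal(curve$F[1], 0)
  expect_true(all(diff(curve$F) >= -1e-3))   # 16-bit quantization jitter only
  # long-run: the curve approaches the full-recovery plateau within a few %
  expect_gt(max(curve$F), 0.9)
})

test_that("half-time of an exact exponential is tau log(2), covariant under time scaling", {
  mk <- function(dt) {
    structure(list(times = seq(0, 60, by = dt),
                   F = 1 - exp(-seq(0, 60, by = dt) / 10),
                   roi_radius_um = 10, pre_bleach_level = 1,
                   post_bleach_level = 0), class = "recovery_curve")
  }
  th <- fit_tau_half(mk(0.5))
  expect_equal(as.numeric(th), 10 * log(2), tolerance = 1e-6)
  expect_identical(attr(th, "method"), "exponential_fit")

  # t -> 2t doubles the half-time
  c2 <- mk(0.5); c2$times <- 2 * c2$times
  expect_equal(as.numeric(fit_tau_half(c2)), 2 * as.numeric(th), tolerance = 1e-6)
})

test_that("curves that never approach a plateau are rejected", {
  slow <- structure(list(times = seq(0, 5, by = 0.5),
                         F = 0.1 * seq(0, 5, by = 0.5) / 5,
                         roi_radius_um = 10, pre_bleach_level = 1,
                         post_bleach_level = 0), class = "recovery_curve")
  expect_error(fit_tau_half(slow), "plateau")
})

test_that("diffusion relation arithmetic: D = c r^2 / tau_half", {
  est <- diffusion_coefficient(7.0922, r = 10, prefactor = 2)
  expect_equal(est$D, 28.2, tolerance = 1e-4)
  # quadratic in r
  est2 <- diffusion_coefficient(7.0922, r = 20, prefactor = 2)
  expect_equal(est2$D / est$D, 4, tolerance = 1e-12)
  # identity case
  expect_equal(diffusion_coefficient(1, r = 1, prefactor = 1)$D, 1)
  expect_error(diffusion_coefficient(-1, r = 10), "positive")
  expect_equal(frap_prefactor("printed"), 2)
  expect_equal(frap_prefactor("soumpasis"), 0.224)
})

test_that("larger diffusivity gives strictly faster recovery on generated stacks", {
  taus <- vapply(c(5, 13.2, 28.2), function(D) {
    gen <- generate_frap_stack(frap_spec(D, seed = 2))
    curve <- extract_recovery_curve(gen$stack, gen$truth$roi_center_px,
                                    gen$truth$roi_radius_px,
                                    gen$truth$bleach_frame)
    as.numeric(fit_tau_half(curve))
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("the end-to-end pipeline recovers the generating diffusivity", {
  gen <- generate_frap_stack(frap_spec(13.2, seed = 3))
  est <- frap_pipeline(gen$stack, gen$truth$roi_center_px,
                       gen$truth$roi_radius_px, gen$truth$bleach_frame,
                       prefactor = frap_prefactor("soumpasis"))
  expect_lt(abs(est$D - 13.2) / 13.2, 0.10)
  expect_identical(est$provenance$fit_method, "exponential_fit")

  # a frozen field has no recovery: pipeline refuses
  sp0 <- synth_spec("frap", seed = 1, shape = c(48L, 48L), frame_interval = 0.5,
                    params = list(D_true = 0, roi_radius = 8, bleach_depth = 0.8,
                                  pre_bleach = 1L, n_frames = 8L, noise_sd = 0))
  g0 <- generate_frap_stack(sp0)
  expect_error(frap_pipeline(g0$stack, g0$truth$roi_center_px,
                             g0$truth$roi_radius_px, g0$truth$bleach_frame),
               "plateau")
})

test_that("estimates from stacks differing only in noise seed agree within 10%", {
  ests <- vapply(c(11, 12), function(s) {
    gen <- generate_frap_stack(frap_spec(13.2, seed = s, noise_sd = 0.02))
    frap_pipeline(gen$stack, gen$truth$roi_center_px, gen$truth$roi_radius_px,
                  gen$truth$bleach_frame,
                  prefactor = frap_prefactor("soumpasis"))$D
  }, numeric(1))
  expect_lt(abs(ests[1] - ests[2]) / mean(ests), 0.10)
})
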