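geom <- channel_geometry()
por <- porous_domain_params()

poiseuille_tau <- function(Q_ulmin, R, mu) {
  4 * mu * (Q_ulmin * 1e-9 / 60) / (pi * R^3)
}

test_that("zero flow gives identically zero fields and zero wall shear", {
  fr <- solve_channel_flow(geom, por, flow_conditions(flow_rate = 0))
  expect_equal(fr$wall_shear_stress, 0)
  expect_true(all(fr$u == 0))
})

test_that("wall shear matches the analytic Poiseuille value within 3%", {
  cond <- flow_conditions(flow_rate = 10)
  fr <- solve_channel_flow(geom, por, cond)
  tau_p <- poiseuille_tau(10, geom$radius, cond$fluid_viscosity)
  expect_lt(abs(fr$wall_shear_stress - tau_p) / tau_p, 0.03)
})

test_that("wall shear converges under grid refinement (< 2% change on halving h)", {
  cond <- flow_conditions(flow_rate = 30)
  t32 <- solve_channel_flow(channel_geometry(n_r = 32L), por, cond)$wall_shear_stress
  t64 <- solve_channel_flow(channel_geometry(n_r = 64L), por, cond)$wall_shear_stress
  expect_lt(abs(t64 - t32) / t32, 0.02)
})

test_that("channel volumetric flux is conserved along the channel within 1%", {
  cond <- flow_conditions(flow_rate = 30)
  fr <- solve_channel_flow(geom, por, cond)
  Q_target <- 30 * 1e-9 / 60
  # fully developed profile: flux through each z cross-section from u(r, z)
  for (j in c(1L, ncol(fr$u))) {
    idx <- seq_len(fr$i_wall)
    flux <- 2 * pi * sum(diff(fr$r[idx]) *
                           (fr$u[idx, j][-1] * fr$r[idx][-1] +
                              fr$u[idx, j][-length(idx)] * fr$r[idx][-length(idx)]) / 2)
    expect_lt(abs(flux - Q_target) / Q_target, 0.01)
  }
})

test_that("shear scales linearly with flow rate through the origin", {
  sw <- sweep_flow_rates(geom, por, seq(10, 90, by = 10))
  expect_gt(sw$r_squared, 0.999)
  expect_equal(sw$table$tau_w[9] / sw$table$tau_w[1], 9.0, tolerance = 1e-6)

  # doubling every Q doubles every tau (Stokes linearity)
  sw2 <- sweep_flow_rates(geom, por, 2 * seq(10, 90, by = 10))
  expect_equal(sw2$table$tau_w / sw$table$tau_w, rep(2, 9), tolerance = 1e-9)

  # singleton sweep: one row, slope = tau/Q
  sw1 <- sweep_flow_rates(geom, por, 30)
  expect_equal(nrow(sw1$table), 1L)
  expect_equal(sw1$slope, sw1$table$tau_w / 30, tolerance = 1e-12)

  expect_error(sweep_flow_rates(geom, por, numeric(0)), "nonempty")
})

test_that("radius calibration inverts the shear relation", {
  cond <- flow_conditions()
  # fixed point: target set to the solver's own output at a known radius
  known <- channel_geometry(radius = 4e-4)
  tau_known <- solve_channel_flow(known, por,
                                  flow_conditions(flow_rate = 20))$wall_shear_stress
  g <- calibrate_radius(tau_known, Q = 20, cond = cond, porous = por)
  expect_equal(g$radius, 4e-4, tolerance = 0.01)

  # printed operating point: 0.89e-3 Pa at 10 uL/min -> R ~ (4 mu Q/(pi tau))^(1/3)
  g2 <- calibrate_radius(0.89e-3, Q = 10, cond = cond, porous = por)
  R_oracle <- (4 * cond$fluid_viscosity * (10 * 1e-9 / 60) / (pi * 0.89e-3))^(1 / 3)
  expect_equal(g2$radius, R_oracle, tolerance = 0.02)

  # halving Q at fixed target scales R by 2^(-1/3)
  g3 <- calibrate_radius(0.89e-3, Q = 5, cond = cond, porous = por)
  expect_equal(g3$radius / g2$radius, 2^(-1 / 3), tolerance = 0.02)

  expect_error(calibrate_radius(1e6, Q = 10), "unreachable")
})

test_that("parameter constructors validate the modelling constants", {
  expect_error(porous_domain_params(porosity = 1.2), "porosity")
  expect_error(porous_domain_params(permeability = -1), "positive")
  expect_error(channel_geometry(radius = 2e-3, matrix_outer_radius = 1e-3),
               "exceed")
  expect_error(flow_conditions(flow_rate = -5), "flow_rate")
  p <- porous_domain_params()
  expect_equal(p$porosity, 0.7)
  expect_equal(p$permeability, 1e-7)
  expect_equal(p$species_diffusivity, 3e-9)
})
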