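#' Porous-domain (GelMA matrix) parameters
#'
#' Constants describing the crosslinked GelMA bulk as a porous medium.
#' Defaults are the modelling constants for 8% GelMA used throughout the
#' package: density 1150 kg/m^3, water content 1058 kg/m^3, Young's modulus
#' 8 kPa, matrix dynamic viscosity 100 Pa s, porosity 0.7, Darcy
#' permeability 1e-7 m^2, species (oxygen) diffusivity 3e-9 m^2/s.
#'
#' The matrix viscosity enters the porous momentum balance as the viscosity
#' of the fluid phase inside the gel (Darcy drag `mu_g / kappa`); the
#' Brinkman effective viscous term uses the perfusing-fluid viscosity by
#' default (configurable via `brinkman_viscosity` in [solve_channel_flow()]).
#'
#' @param density kg/m^3.
#' @param water_content kg/m^3.
#' @param youngs_modulus kPa.
#' @param matrix_viscosity dynamic viscosity of the gel phase, Pa s.
#' @param porosity dimensionless, in (0, 1).
#' @param permeability Darcy permeability, m^2.
#' @param species_diffusivity free diffusivity of the transported species,
#'   m^2/s.
#' @return A `porous_domain_params` object (named list).
#' @export
porous_domain_params <- function(density = 1150, water_content = 1058,
                                 youngs_modulus = 8, matrix_viscosity = 100,
                                 porosity = 0.7, permeability = 1e-7,
                                 species_diffusivity = 3e-9) {
  vals <- c(density = density, water_content = water_content,
            youngs_modulus = youngs_modulus, matrix_viscosity = matrix_viscosity,
            porosity = porosity, permeability = permeability,
            species_diffusivity = species_diffusivity)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stopf("all porous-domain parameters must be finite and strictly positive")
  }
  if (porosity >= 1) stopf("porosity must be < 1")
  structure(as.list(vals), class = "porous_domain_params")
}

#' Channel-in-matrix geometry
#'
#' A straight cylindrical channel of radius `R` running axially through a
#' porous annulus of outer radius `R_out`, length `L`, discretized on an
#' axisymmetric `(r, z)` grid.
#'
#' @param radius channel radius R, m.
#' @param length channel length L, m.
#' @param matrix_outer_radius outer radius of the porous annulus, m
#'   (> `radius`).
#' @param n_r,n_z grid resolution (radial cells in channel and in matrix
#'   each get `n_r`; axial nodes `n_z`); both at least 16.
#' @return A `channel_geometry` object.
#' @export
channel_geometry <- function(radius = 5.5e-4, length = 1e-2,
                             matrix_outer_radius = 3e-3, n_r = 32L, n_z = 24L) {
  if (radius <= 0 || length <= 0) stopf("radius and length must be positive")
  if (matrix_outer_radius <= radius) {
    stopf("matrix_outer_radius (%g m) must exceed the channel radius (%g m)",
          matrix_outer_radius, radius)
  }
  if (n_r < 16L || n_z < 16L) stopf("n_r and n_z must be at least 16")
  structure(list(radius = radius, length = length,
                 matrix_outer_radius = matrix_outer_radius,
                 n_r = as.integer(n_r), n_z = as.integer(n_z)),
            class = "channel_geometry")
}

#' Perfusion conditions
#'
#' @param flow_rate volumetric flow rate through the channel, uL/min (>= 0).
#' @param fluid_viscosity perfusing medium dynamic viscosity, Pa s (default
#'   0.7e-3, aqueous culture medium at 37 C).
#' @param fluid_density perfusing medium density, kg/m^3.
#' @return A `flow_conditions` object.
#' @export
flow_conditions <- function(flow_rate = 30, fluid_viscosity = 0.7e-3,
                            fluid_density = 1000) {
  if (flow_rate < 0) stopf("flow_rate must be >= 0")
  if (fluid_viscosity <= 0) stopf("fluid_viscosity must be positive")
  structure(list(flow_rate = flow_rate, fluid_viscosity = fluid_viscosity,
                 fluid_density = fluid_density),
            class = "flow_conditions")
}

# geometric node sequence from a to b with n intervals, first spacing ~ h0
geom_grid <- function(a, b, n, h0) {
  L <- b - a
  if (h0 * n >= L) return(seq(a, b, length.out = n + 1L))
  g <- stats::uniroot(function(g) h0 * (g^n - 1) / (g - 1) - L,
                      c(1 + 1e-9, 50))$root
  h <- h0 * g^(0:(n - 1L))
  a + c(0, cumsum(h)) / sum(h) * L
}

# Fully developed axial velocity profile: solves
#   (1/r) d/dr(r mu(r) du/dr) - drag(r) u = -G,   u'(0) = 0, u(R_out) = 0
# with mu = mu_f, drag = 0 in the channel (r < R) and mu = mu_e,
# drag = mu_g/kappa in the matrix. The matrix sub-grid is geometrically
# stretched from ~delta/4 at the interface so the Brinkman screening layer
# delta = sqrt(mu_e kappa / mu_g) is resolved rather than smeared into
# artificial slip. Linear in G: solved at G = 1 and rescaled to the target
# channel flux.
solve_radial_profile <- function(R, R_out, n_ch, n_mat, mu_f, mu_e, drag) {
  delta <- sqrt(mu_e / drag)
  r <- c(seq(0, R, length.out = n_ch + 1L),
         geom_grid(R, R_out, n_mat, min(delta / 4, (R_out - R) / n_mat))[-1L])
  n <- length(r)
  mu_face <- function(rf) ifelse(rf < R, mu_f, mu_e)
  dragv <- ifelse(r > R, drag, 0)
  lo <- mid <- up <- rhs <- numeric(n)
  h1 <- r[2L] - r[1L]
  mid[1L] <- -4 * mu_f / h1^2; up[1L] <- 4 * mu_f / h1^2; rhs[1L] <- -1
  for (i in 2:(n - 1L)) {
    hm <- r[i] - r[i - 1L]; hp <- r[i + 1L] - r[i]
    rfm <- (r[i] + r[i - 1L]) / 2; rfp <- (r[i] + r[i + 1L]) / 2
    am <- rfm * mu_face(rfm) / hm
    ap <- rfp * mu_face(rfp) / hp
    fac <- 1 / (r[i] * (hm + hp) / 2)
    lo[i] <- fac * am; up[i] <- fac * ap
    mid[i] <- -fac * (am + ap) - dragv[i]
    rhs[i] <- -1
  }
  mid[n] <- 1; rhs[n] <- 0
  # Thomas algorithm
  for (i in 2:n) {
    w <- lo[i] / mid[i - 1L]
    mid[i] <- mid[i] - w * up[i - 1L]
    rhs[i] <- rhs[i] - w * rhs[i - 1L]
  }
  u <- numeric(n)
  u[n] <- rhs[n] / mid[n]
  for (i in (n - 1L):1L) u[i] <- (rhs[i] - up[i] * u[i + 1L]) / mid[i]
  list(r = r, u = u, i_wall = n_ch + 1L)
}

# trapezoid flux 2 pi int u r dr over channel nodes
channel_flux <- function(r, u, i_wall) {
  idx <- seq_len(i_wall)
  2 * pi * sum(diff(r[idx]) *
                 (u[idx][-1L] * r[idx][-1L] + u[idx][-i_wall] * r[idx][-i_wall]) / 2)
}

#' Solve steady flow in a channel embedded in a porous matrix
#'
#' Reduced-order model of perfusion through a printed vascular channel:
#' fully developed laminar (Stokes) flow in the free cylindrical channel,
#' coupled at the wall to Brinkman-Darcy seepage in the porous GelMA
#' annulus, with continuity of velocity and shear stress at the interface.
#' The axial momentum balance reduces to a radial two-point boundary-value
#' problem solved by second-order finite differences; the pressure gradient
#' is scaled so the channel carries the prescribed flow rate. Wall shear
#' stress is `tau_w = mu_f |du/dr|` at `r = R` (second-order one-sided
#' difference on the channel side).
#'
#' With the default parameters (high matrix viscosity, the 8% GelMA constants)
#' the porous annulus is nearly quiescent and the channel profile is
#' Poiseuille to well within 3%.
#'
#' @param geom a [channel_geometry()].
#' @param porous a [porous_domain_params()].
#' @param cond a [flow_conditions()].
#' @param brinkman_viscosity effective viscosity of the Brinkman viscous
#'   term, Pa s; default the perfusing-fluid viscosity.
#' @return A `flow_result` with the radial profile (`r`, `u_r`), the fields
#'   `u` and `p` on the `(r, z)` grid, `wall_shear_stress` (Pa),
#'   `pressure_gradient` (Pa/m), `reynolds`, and the grid metadata.
#' @export
solve_channel_flow <- function(geom, porous, cond,
                               brinkman_viscosity = cond$fluid_viscosity) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(porous, "porous_domain_params"),
            inherits(cond, "flow_conditions"))
  R <- geom$radius; R_out <- geom$matrix_outer_radius
  mu_f <- cond$fluid_viscosity
  drag <- porous$matrix_viscosity / porous$permeability
  Q <- ul_min_to_m3s(cond$flow_rate)

  prof <- solve_radial_profile(R, R_out, geom$n_r, geom$n_r, mu_f,
                               brinkman_viscosity, drag)
  z <- seq(0, geom$length, length.out = geom$n_z)

  if (Q == 0) {
    u <- numeric(length(prof$r))
    G <- 0
    tau_w <- 0
  } else {
    Q1 <- channel_flux(prof$r, prof$u, prof$i_wall)
    G <- Q / Q1              # unit-G solution rescaled to the target flux
    u <- prof$u * G
    iw <- prof$i_wall
    h <- R / geom$n_r
    dudr <- (3 * u[iw] - 4 * u[iw - 1L] + u[iw - 2L]) / (2 * h)
    tau_w <- mu_f * abs(dudr)
  }

  u_mean <- if (R > 0) Q / (pi * R^2) else 0
  reynolds <- cond$fluid_density * u_mean * 2 * R / mu_f
  if (reynolds >= 100) {
    warnf("Re = %.1f: outside the creeping-flow regime this model assumes", reynolds)
  }

  structure(list(
    r = prof$r, z = z, u_r = u,
    u = matrix(u, length(u), geom$n_z),                 # fully developed: z-invariant
    p = outer(rep(1, length(prof$r)), G * (geom$length - z)),
    wall_shear_stress = tau_w, pressure_gradient = G,
    reynolds = reynolds, i_wall = prof$i_wall,
    geometry = geom, conditions = cond, porous = porous
  ), class = "flow_result")
}

#' Wall-shear-stress sweep over flow rates
#'
#' Runs [solve_channel_flow()] for each flow rate and summarizes the
#' shear-flow relation with a through-origin linear fit.
#'
#' @param geom a [channel_geometry()].
#' @param porous a [porous_domain_params()].
#' @param Q_list flow rates to sweep, uL/min (nonempty, nonnegative).
#' @param cond base [flow_conditions()]; its `flow_rate` is replaced by each
#'   element of `Q_list` in turn.
#' @return A list with `table` (data.frame of `Q`, `tau_w`), `slope`
#'   (Pa per uL/min, through origin) and `r_squared` of the through-origin
#'   fit.
#' @export
sweep_flow_rates <- function(geom, porous, Q_list, cond = flow_conditions()) {
  if (length(Q_list) == 0L || any(Q_list < 0)) {
    stopf("Q_list must be a nonempty vector of nonnegative flow rates (uL/min)")
  }
  tau <- vapply(Q_list, function(q) {
    ci <- cond; ci$flow_rate <- q
    solve_channel_flow(geom, porous, ci)$wall_shear_stress
  }, numeric(1))
  slope <- sum(Q_list * tau) / sum(Q_list^2)
  ss_res <- sum((tau - slope * Q_list)^2)
  ss_tot <- sum(tau^2)
  list(table = data.frame(Q = Q_list, tau_w = tau),
       slope = slope,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Calibrate the channel radius to a target wall shear stress
#'
#' Inverts the shear-flow relation: finds the channel radius at which the
#' numerical solver reproduces `target_tau` at flow rate `Q`, by bisection
#' on `R` in `[10 um, 5 mm]`. Wall shear falls monotonically with radius
#' (`~ 4 mu Q / (pi R^3)` in the Poiseuille limit), so bisection is exact.
#'
#' @param target_tau target wall shear stress, Pa (> 0).
#' @param Q flow rate, uL/min.
#' @param cond a [flow_conditions()].
#' @param porous a [porous_domain_params()].
#' @param geom template [channel_geometry()] providing length, outer radius
#'   and resolution; its `radius` is ignored.
#' @param tol relative tolerance on the matched shear (default 0.5%).
#' @return A [channel_geometry()] with the calibrated radius.
#' @export
calibrate_radius <- function(target_tau, Q, cond = flow_conditions(),
                             porous = porous_domain_params(),
                             geom = channel_geometry(), tol = 5e-3) {
  if (target_tau <= 0) stopf("target_tau must be positive")
  tau_at <- function(R) {
    g <- geom; g$radius <- R
    if (g$matrix_outer_radius <= R * 1.2) g$matrix_outer_radius <- R * 2
    ci <- cond; ci$flow_rate <- Q
    solve_channel_flow(g, porous, ci)$wall_shear_stress
  }
  lo <- 1e-5; hi <- 5e-3
  f_lo <- tau_at(lo) - target_tau   # small R -> large tau: f_lo > 0 expected
  f_hi <- tau_at(hi) - target_tau
  if (f_lo < 0 || f_hi > 0) {
    stopf("target shear %.3g Pa unreachable for R in [10 um, 5 mm] at Q = %g uL/min",
          target_tau, Q)
  }
  for (it in seq_len(200L)) {
    mid <- sqrt(lo * hi)             # bisect in log space: tau ~ R^-3
    fm <- tau_at(mid) - target_tau
    if (abs(fm) <= tol * target_tau) {
      g <- geom; g$radius <- mid
      if (g$matrix_outer_radius <= mid * 1.2) g$matrix_outer_radius <- mid * 2
      return(g)
    }
    if (fm > 0) lo <- mid else hi <- mid
  }
  stopf("radius calibration did not converge to %.2g%% after 200 bisections", tol * 100)
}
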