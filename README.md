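# perfuseR

Quantitative backbone for studies of bioprinted, perfusable vascularized
hydrogel constructs: a GelMA matrix with a sacrificially printed vascular
channel, perfused with medium, optionally lined with endothelial cells. The
package is aimed at tissue-engineering groups who need the numbers such a
system is characterized by — wall shear stress on the channel lining,
solute equilibration time in the gel, matrix diffusivity from FRAP, print
fidelity, porosity, viability, vascular permeability, and endothelial
network growth — together with synthetic ground-truth data that makes every
estimator testable end to end without any raw microscopy.

## What it computes

**Flow.** Fully developed laminar flow in a cylindrical channel of radius
*R* coupled to Brinkman–Darcy seepage in the porous annulus, solved as a
radial boundary-value problem with continuity of velocity and stress at the
wall. Wall shear stress is τ_w = μ_f |du/dr| at r = R; in the
high-matrix-viscosity regime the channel reduces to Poiseuille flow,
τ_w ≈ 4μQ/(πR³). Includes a flow-rate sweep with a through-origin linear
fit and radius calibration against a target shear.

**Transport.** Transient advection–diffusion of a diluted species from the
channel into the matrix (effective diffusivity ε·D_s), reporting the bulk
matrix concentration c̄(t) and the time t\* to reach a target fraction of
the inlet value.

**FRAP.** Recovery-curve extraction, half-time τ₁/₂ from a single
exponential fit (with interpolation fallback), and D = c·r²/τ₁/₂ with the
prefactor convention explicit (c = 2 printed form, c = 0.224 uniform-disk
Soumpasis constant).

**Image metrics.** Printability Pr = p²/(16A) per enclosed grid pore (1 for
a perfect square); areal porosity and equivalent-radius pore-size
distribution; LIVE/DEAD viability by blob counting; vascular permeability
P = (1/(I₀−I_b))·((I_t−I₀)/t)·(d/4) in cm/s from dextran-leak series, plus
endothelialized-vs-bare barrier comparison.

**Networks.** Skeleton-based tube-formation readout: total sprout length
and closed-mesh count (circuit rank E − V + C).

**Synthetic data.** Deterministic generators for all six input kinds (FRAP
stacks by finite-difference diffusion, leak series, pore textures, grid
prints, nuclei fields, network masks), each emitting a 16-bit TIFF, a JSON
sidecar, and exact ground truth.

## Worked example

```r
library(perfuseR)

# Wall-shear sweep over the perfusion operating range
geom <- channel_geometry()            # R = 0.55 mm, L = 10 mm, R_out = 3 mm
por  <- porous_domain_params()        # GelMA constants: porosity 0.7, kappa 1e-7 m^2, ...
sw   <- sweep_flow_rates(geom, por, seq(10, 90, by = 10))
head(sw$table, 3)
#>    Q        tau_w
#> 1 10 0.0008876282
#> 2 20 0.0017752564
#> 3 30 0.0026628846
sw$slope; sw$r_squared
#> [1] 8.876e-05      # Pa per uL/min, through the origin
#> [1] 1

# FRAP on a synthetic stack with known diffusivity
spec <- synth_spec("frap", seed = 1, pixel_size = 1, shape = c(96L, 96L),
                   frame_interval = 0.47,
                   params = list(D_true = 13.2, roi_radius = 10,
                                 bleach_depth = 0.8, pre_bleach = 2L,
                                 n_frames = 40L, noise_sd = 0.01))
gen <- generate_frap_stack(spec)
est <- frap_pipeline(gen$stack, gen$truth$roi_center_px,
                     gen$truth$roi_radius_px, gen$truth$bleach_frame,
                     prefactor = frap_prefactor("soumpasis"))
est
#> <diffusion_estimate> D = 14 um^2/s (tau_1/2 = 1.6 s, r = 10 um, c = 0.224)
```

The sweep is linear through the origin (R² = 1 to machine precision): at
10 µL/min the wall shear is 0.89 mPa, at 90 µL/min 8.0 mPa — the mechanical
stimulus band felt by channel-lining endothelial cells. The FRAP estimate
(14.0 µm²/s, exponential-fit R² = 0.96) recovers the generating diffusivity
13.2 µm²/s within 6%, inside the pipeline's 10% validation tolerance.

A full demonstration that regenerates every synthetic experiment, runs all
analyses and both simulations, and writes a report comparing each estimate
to its ground truth:

```r
run_demo(seed = 42, out_dir = "demo_out")   # ~5 s; byte-identical per seed
```

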