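---
title: "Models and methods behind perfuseR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perfuseR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfuseR)
```

perfuseR quantifies bioprinted constructs that carry a perfusable vascular
channel inside a GelMA (gelatin methacrylate) matrix. It has two halves: a
reduced-order physics side (channel flow and solute transport) and an image
analysis side (FRAP diffusion, printability, porosity, viability,
permeability, endothelial networks), plus synthetic-data generators that
produce every input with exact ground truth. This vignette explains each
model, the tunable parameters, the numerical choices, and what validation on
synthetic data does and does not demonstrate.

## Flow: coupled channel-matrix momentum balance

A straight cylindrical channel (radius $R$) runs through a porous annulus
(outer radius $R_\mathrm{out}$). For creeping, fully developed axial flow the
momentum balance reduces to a radial two-point boundary-value problem for the
axial velocity $u(r)$:

$$\frac{1}{r}\frac{d}{dr}\!\left(r\,\mu(r)\,\frac{du}{dr}\right) - \frac{\mu_g}{\kappa}\,\chi_{r>R}\,u = -G,$$

with $\mu = \mu_f$ (perfusing medium, default $0.7\times10^{-3}$ Pa s, an
aqueous culture medium at 37 °C) in the free channel and a Brinkman term with
effective viscosity $\mu_e$ (default $\mu_f$) plus Darcy drag
$\mu_g/\kappa$ in the matrix. Velocity and shear stress are continuous at
$r=R$; $u(R_\mathrm{out})=0$. The pressure gradient $G$ is scaled so the
channel carries the prescribed flow rate $Q$, and the wall shear stress is
$\tau_w = \mu_f\,|du/dr|_{r=R}$ by a second-order one-sided difference.

Two choices deserve comment:

* **Which viscosity drags the matrix.** The matrix constants give a gel
  dynamic viscosity $\mu_g = 100$ Pa s and a Darcy permeability
  $\kappa = 10^{-7}\ \mathrm{m^2}$. If the *medium* viscosity were used in
  the drag term with this large $\kappa$, the annulus would conduct several
  times the channel's mean flow and the channel profile would be far from
  Poiseuille — inconsistent with the system being a channel in a gel. Using
  $\mu_g$ as the viscosity of the fluid phase inside the gel makes the
  annulus nearly quiescent and recovers Poiseuille flow in the channel to
  well under 3%. Both viscosities are exposed as parameters
  (`matrix_viscosity`, `brinkman_viscosity`).
* **Resolving the Brinkman screening layer.** The interface layer has
  thickness $\delta = \sqrt{\mu_e\kappa/\mu_g} \approx 0.8\ \mu$m, far below
  any affordable uniform grid spacing. An unresolved layer shows up as
  artificial wall slip and a badly biased $\tau_w$. The matrix sub-grid is
  therefore geometrically stretched, starting at $\delta/4$ at the
  interface; with that, $\tau_w$ at the default resolution ($n_r = 32$) is
  within 1% of its refined value.

A Forchheimer (inertial drag) correction is deliberately omitted: the sweep
runs at $Re \ll 1$ where its quadratic term is negligible, and no
Forchheimer coefficient is available for this gel. The solver warns if
$Re \ge 100$.

`calibrate_radius()` inverts the shear relation by bisection (in log-radius,
since $\tau_w \sim R^{-3}$): given a target wall shear at a reference flow
rate it returns the channel radius that reproduces it. This is how the
package connects to an operating point stated as a shear value when the
channel diameter itself is not known: geometry here is configuration, not a
claim. Defaults are $L = 10$ mm, $R_\mathrm{out} = 3$ mm, $R = 0.55$ mm (the
radius at which $\tau_w(10\ \mu\mathrm{L/min}) \approx 0.89\times10^{-3}$ Pa
with the default medium viscosity).

## Transport: advection in the channel, diffusion in the matrix

The diluted-species model marches
$$\partial_t c = \nabla\!\cdot\!(D(r)\nabla c) - u(r)\,\partial_z c$$
on a uniform axisymmetric $(r,z)$ grid: plug advection at the channel mean
velocity, free diffusivity $D_s$ in the channel, effective diffusivity
$D_\mathrm{eff} = \varepsilon D_s$ in the matrix (porosity-scaled; whether a
stated diffusivity is free or effective is often ambiguous, so
`effective_diffusivity` can override the default). The inlet concentration
is 1; the reported curve $\bar c(t)$ is the volume average over the matrix
domain, and $t^\*$ is the first time it reaches `target_fraction` (default
0.9 — the notion of "target concentration" is a configuration choice, and
any claim-bearing run should state it). If the horizon `t_max` ends first,
$t^\*$ is the `Inf` sentinel with a warning, not an error.

Numerics: explicit FTCS for diffusion, first-order upwind for advection,
internal substepping at 0.8 of the combined stability bound; the scheme and
step count are recorded in the result. The explicit scheme respects a
discrete maximum principle at this step size, so $0 \le c \le 1$ holds
without clamping. `coordinates = "planar"` drops the cylindrical metric;
with the channel held at the inlet value (`channel_mode = "fixed"`) and no
flow, the matrix then reproduces the $\mathrm{erfc}$ similarity solution of
a constant-concentration boundary, which the tests use as a closed-form
oracle (L-infinity agreement within 2%).

Two regimes matter when interpreting $t^\*$. With `channel_mode = "advect"`
the early leak into the matrix can exceed what the perfusion rate supplies,
so delivery is flow-limited at first and $t^\*$ is *not* simply
$\propto 1/D_\mathrm{eff}$. The clean diffusion-dominated scaling
($t^\*$ halving when $D_\mathrm{eff}$ doubles, within 5%) is asserted in the
reservoir mode, where the channel is a fixed boundary. At the default
geometry and constants, $t^\*(0.9)$ lands at roughly one to two hours —
the same order as the tens-of-minutes equilibration one expects for a
few-millimetre gel annulus at $D_\mathrm{eff} \approx 2\times10^{-9}\
\mathrm{m^2/s}$ (a 45-minute equilibration corresponds to a diffusion
length of about 2.8 mm at the default free diffusivity).

Problem sizes: the default transport grid is 32 radial cells across the
matrix (plus the channel at equal spacing) by 24 axial nodes; the slab
verification uses 160 radial cells. These resolutions put both $\tau_w$ and
$t^\*$ within 2% of their refined values (asserted by the convergence
tests), which is the accuracy regime the rest of the pipeline works at.

## FRAP: recovery curves and the diffusion prefactor

`extract_recovery_curve()` averages a circular ROI per frame and normalizes
$F(t) = (I(t)-I_\mathrm{post})/(I_\mathrm{pre}-I_\mathrm{post})$, with
$I_\mathrm{pre}$ from the last pre-bleach frame and $I_\mathrm{post}$ from
the first post-bleach frame, so $F$ runs from 0 to a plateau of 1. No
acquisition-bleaching correction is applied. `fit_tau_half()` fits
$F(t) = A(1-e^{-t/\tau})$ and reports $\tau_{1/2} = \tau\ln 2$; when the
exponential fit is poor ($R^2 < 0.8$) it falls back to direct interpolation
of the half-plateau crossing and records which method ran.

The diffusion coefficient is $D = c\,r^2/\tau_{1/2}$ with the prefactor
explicit. Two conventions are built in: `"printed"` ($c = 2$, the plain
printed form of the relation, kept as the default) and `"soumpasis"`
($c = 0.224$, the exact constant for uniform-disk photobleaching in 2-D,
whose closed-form recovery $F(t) = e^{-2\tau_D/t}[I_0(2\tau_D/t) +
I_1(2\tau_D/t)]$, $\tau_D = r^2/4D$, crosses one half at
$0.224\,r^2/D$). The synthetic generator implements exactly that disk-bleach
physics, so parameter-recovery validation uses the Soumpasis constant; with
an arbitrary prefactor convention the *ratios* between conditions are
meaningful rather than absolute values.

Two subtleties were checked against the closed form before freezing the
design. First, the generator emits the first post-bleach frame at
$t = 0^+$: normalizing to a frame captured one interval later biases the
half-time by tens of percent, because two-dimensional recovery is steep
early. Second, the exponential model is only an approximation to diffusive
recovery (whose tail is slower than exponential), so its half-time depends
mildly on the acquisition window; with the realistic protocol of stopping
about ten diffusion times after the bleach — shortly after the curve
plateaus — the fitted half-time tracks the true diffusive half-time to
within a few percent, which is why end-to-end recovery lands within the 10%
tolerance the tests assert.

## Image metrics

**Printability.** A grid print is binarized with Otsu's threshold; enclosed
(non-border-touching) background components are the pores; each is scored
$Pr = p^2/(16A)$, which is 1 for a perfect square pore, $\pi/4$ for a
circular one, above 1 for jagged shapes. The perimeter estimator is the
package's one non-obvious imaging choice: the 0.5-level marching-squares
contour is simplified by a closed-curve Douglas-Peucker pass at 1 px
tolerance before measuring. Raw pixel-boundary or chain-code lengths
overestimate smooth boundaries by 5-15% (which would push a circle's score
from 0.785 toward 0.87), while orientation-corrected chain weights
underestimate axis-aligned squares by about 5%; no weighting fixes both.
Polygon simplification does: it removes the raster staircase yet keeps true
corners as vertices, and lands within about 1% of the analytic perimeter
for squares, circles and rotated squares alike.

**Porosity.** Otsu threshold, connected components on the dark (pore)
phase, equivalent-circle radius $r = \sqrt{A/\pi}$ per component, areal
porosity as the pore-pixel fraction, histogram in 1 µm bins over 0-20 µm by
default. Uniform images degrade to porosity 0 or 1 with a warning.

**Viability.** Per-channel blob detection (Gaussian smoothing, Otsu
threshold, local maxima with greedy minimum-separation suppression);
viability is $n_\mathrm{live}/(n_\mathrm{live}+n_\mathrm{dead})$, undefined
(flagged) on empty marker channels. Channel roles are named, so a swapped
acquisition order is handled by naming rather than positional convention.

**Permeability.** The leak equation
$P = \frac{1}{I_0-I_b}\,\frac{I_t-I_0}{t}\,\frac{d}{4}$ is applied with the
channel diameter $d$ converted to cm so $P$ lands in cm/s. By default the
two-point difference quotient is replaced by the least-squares slope over
all perfusion frames (`method = "slope"`), which is exact for a linear leak
and less noise-sensitive otherwise. Measurement regions default to two
rectangles flanking the channel one channel-radius away. $I_0 \le I_b$ is
an error; $I_t < I_0$ yields a negative estimate with a photobleaching
warning rather than silent clipping. Barrier comparisons
(`compare_permeability()`) refuse mismatched diameters or frame intervals.

## Network metrics

The tube-formation readout reimplements, in simplified form, the two
quantities such assays report: total sprout length and closed-mesh count.
The mask is skeletonized by Guo-Hall thinning (implemented in the package;
chosen over Zhang-Suen because the latter leaves two-pixel-wide diagonal
staircases that masquerade as junction pixels). Skeleton pixels are
classified by 8-neighbour count; junction pixels within 3 px merge into one
node; degree-2 chains become edges whose geodesic length is measured on the
Douglas-Peucker-simplified pixel path (again to remove staircase bias), and
open branch tips are extended by the local stroke half-width from the
distance transform, since the medial axis of a round-capped stroke stops
half a width short of its tip. Mesh count is the circuit rank
$E - V + C$. Two junction-region rules keep the graph honest: a short chain
(six pixels or fewer) that re-enters the same node is junction debris, not
a mesh, and tiny (one- or two-pixel) connectors between the same node pair
are deduplicated.

Branch classification (master segments vs. twigs) and the isolated-element
filtering heuristics of the full assay plugin are out of scope: published
claims in this setting rest on the two readouts implemented.

## Synthetic data: what it emulates, and what it does not

Every generator is deterministic given its `synth_spec` (seed included),
emits 16-bit grayscale scaled to 80% of the dynamic range (noise headroom),
takes physical units (µm, s) and converts to pixels once at rasterization,
and serializes its ground truth alongside the TIFF. Placement problems
(pores, nuclei) use rejection sampling capped at $10^4$ attempts per object
and fail loudly on packing failure. The FRAP ground-truth field is produced
by explicit finite-difference time stepping — deliberately a different code
path from anything the analysis side uses — with the stability bound
$\Delta t \le \Delta x^2/4D$ enforced by refusal (a user-supplied unstable
step is an error, not something to silently fix).

Study conditions baked into defaults and fixtures: pore radii drawn from
the 5-14 µm range typical of this gel; FRAP diffusivities of order 5-30
µm²/s (the magnitude range of kDa-scale dextrans in such gels; measured
reference values in that setting are magnitude anchors only, since raw
stacks and ROI radii are not reproducible from published summaries); leak
series imaged every 30 s over 30 min; a 3×3 grid print; flow rates
10-90 µL/min. Where an acquisition constant is not stated anywhere
(microscope pixel size, frame interval), defaults of 1 µm/px and 0.5
s/frame are configuration, not claims.

Generated networks are constrained to be *resolvable*: edges at least twice
the stroke width (enforced by the generator), and in the random-tree
fixtures a minimum clearance between non-adjacent edges plus a minimum
branching angle of about 30 degrees. Without those, strokes of neighbouring
edges merge and the skeleton genuinely contains sliver loops — a
rasterization fact, not an analysis bug — and no skeleton-based method can
recover the generating graph.

What passing these tests shows: the estimators are correct on their own
forward models, unbiased at the stated tolerances, and deterministic. What
they do not show: robustness to optics the generators deliberately omit —
point-spread blur, acquisition photobleaching, stage drift, uneven
illumination, autofluorescence, segmentation errors on real stains. Results
on real microscopy therefore inherit the usual caveats of the upstream
imaging, and the tolerances quoted here are floors, not guarantees, for
real data.

## Reproducibility plumbing

All randomness flows from explicit seeds; generators restore the caller's
RNG state. `metric_record()` attaches units, parameters, an input digest
and the package version to every value; its timestamp is optional and off
by default so reports are byte-stable. `run_demo(seed, out_dir)`
regenerates every synthetic experiment, runs every analysis and both
simulations, and writes a JSON report whose `status` encodes
success/comparison-failure/stage-error as 0/1/2; identical seeds give
byte-identical reports. Pixel coordinates are 1-based `(row, col)`
throughout, matching R's matrix indexing.
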