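---
title: "Methods: intra-voxel contrast-agent kinetics and parameterization error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-voxel contrast-agent kinetics and parameterization error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Quantitative DCE-MRI fits compartmental pharmacokinetic models to the
signal-intensity time course of each voxel during the passage of a
gadolinium-based contrast agent.  The standard (Tofts) model,

$$C_t(t) = K^{trans}\int_0^t C_p(\tau)\,
  e^{-\frac{K^{trans}}{v_e}(t-\tau)}\,d\tau,$$

and its extended form, $C_t(t) = C_t^{std}(t) + v_p\,C_p(t)$, assume the
extravascular extracellular space (EES) is *well mixed*: contrast agent that
crosses a vessel wall is instantly distributed over the whole compartment.
Inside a real voxel the agent must *diffuse* from the vessel periphery
through a crowded, cell-obstructed EES.  When the diffusion coefficient $D$
of the agent is finite, the concentration field is heterogeneous, the voxel
signal deviates from the compartmental prediction, and the fitted
$K^{trans}$, $v_e$ and $v_p$ are biased.  `dcevox` quantifies that bias by
simulating the full intra-voxel physics and then analyzing the synthetic
signal exactly as a standard DCE-MRI pipeline would.

## Forward model

**Geometry.** A voxel is a square tile (side $L$, default 250 µm, a typical
preclinical voxel) containing three compartments defined *geometrically*:
elliptical cells (the extravascular intracellular space, impermeable to
gadolinium chelates; area-equivalent diameter lognormal with mean 14 µm,
CV 0.15, axis ratio uniform in $[0.7, 1]$), circular vessels (8 µm
diameter), and the EES between them.  The achieved area fractions match the
requested $v_e$ and $v_p$: the vessel count is
$\mathrm{round}(v_p L^2/\pi r^2)$ and the drawn cell areas are rescaled so
the intracellular area is exact.  Vessels are placed by farthest-point
sampling (perfusion sources spread across the tile, no two centres closer
than twice the vessel diameter); cells are seeded on a randomly assigned,
jittered hexagonal lattice and relaxed by deterministic pairwise push-apart
moves (SAT minimum-translation vectors on halo-inflated polygons) until
every pair of shapes keeps a clearance `gap` (default 1 µm; the tile border
keeps `gap/2` so periodic copies also respect it).  Plain random sequential
addition cannot reach the required intracellular packing fractions (up to
0.74 at the densest grid point, well past the ~0.55 RSA jamming limit), and
the study's conclusions depend on the fractions and length scales rather
than on the packing algorithm — hence the relaxation scheme.  All randomness
derives from one integer seed; the same seed reproduces the geometry
bit-for-bit.

To avoid imposing sealed walls on the voxel of interest, the tile is
surrounded by eight identical copies (`tile_extended_domain()`); voxel
summaries are computed only on the central tile $[L,2L]^2$.

**Meshing.** Only the EES is meshed; cells and vessels are holes.  Hole
boundaries are polygonized with chord error at most `target_edge/4` and the
polygon is scaled so its area equals the analytic shape area, which makes
the mesh area sum match the analytic EES area to rounding precision at any
resolution.  The triangulation is an in-package Bowyer–Watson Delaunay of
the boundary samples plus a jittered hexagonal interior lattice, followed by
Ruppert-style refinement (circumcenter insertion with diametral-circle
protection of boundary segments) to a minimum interior angle of 20° and a
maximum element area of $1.3\cdot\frac{\sqrt 3}{4}h^2$.  The study-fidelity
edge target is $h = 2$ µm; the test suite uses 4–10 µm meshes, where
refinement around the 8–14 µm holes dominates and the realized mean edge sits
below the target (this is reported by the `tri_mesh` object rather than
hidden).

**Transport.**  Within the EES the concentration obeys the diffusion
equation $\partial C/\partial t = D\,\nabla^2 C$.  Cell boundaries and the
outer boundary of the extended domain are zero-flux; at vessel walls the
normal flux is Robin-type, $D\,\partial C/\partial n = P\,(C_p(t) - C)$,
with the plasma concentration uniform inside all vessels.  The transfer
coefficient is tied to the volume transfer constant by
$P = K^{trans} V/S$ (with $S$ the vessel boundary length of one voxel and
$V = L^2$), which makes the well-mixed limit of the simulation reproduce the
standard model at the nominal $K^{trans}$ — the permeability-limited regime,
where $K^{trans}$ is the permeability–surface-area product.  We evaluate $S$
from the *meshed* vessel polygons rather than $2\pi r\,n$ so that the
discrete influx matches the nominal $K^{trans}$ exactly at every mesh
resolution (the two differ by <1%).

**Discretization.**  Galerkin weighted residuals with linear (P1) Lagrange
elements — consistent mass matrix $M$, stiffness $K$, vessel boundary mass
$B$ and load $b$ — and a $\theta$-scheme in time,

$$(M + \theta\,\Delta t\,A)\,C^{k+1} =
  (M - (1-\theta)\,\Delta t\,A)\,C^{k} + \Delta t\,
  [\theta f^{k+1} + (1-\theta) f^{k}], \qquad A = D K + P B,$$

with $\theta = \tfrac12$ (Crank–Nicolson: trapezoidal, second order,
unconditionally stable).  The constant left-hand matrix is factorized once
(sparse Cholesky) and reused across all steps.  The default step is
$\Delta t = \mathrm{clamp}(h^2/D,\ 10^{-3},\ 0.1)$ s with a 0.25 s cap so
the bolus peak is always resolved; because the implicit scheme has no
stability constraint, long parameter sweeps may override $\Delta t$ with the
equivalent rule evaluated at the nominal edge target (the refined boundary
edges otherwise drag the realized mean edge, and hence $\Delta t$, down by
~3x with no accuracy gain — the temporal-convergence test pins the scheme's
second order independently).  Small Crank–Nicolson undershoots are tolerated
to $10^{-6}$ mM.

**Arterial input.**  The measured population input function behind the
original study is not published, so the default $C_p(t)$ is a surrogate: a
gamma-variate bolus ($\alpha = 3$) plus a biexponential washout tail, with
the construction self-calibrated so the dense-grid argmax sits exactly at
the documented population peak time of 0.88 min and the peak amplitude at
3.0 mM (a typical preclinical bolus; the true amplitude is not documented
either).  Every parameter is exposed, and a measured AIF can be substituted
from a two-column CSV (`load_aif()`; time in minutes, concentration in mM).
Consequences of the surrogate are discussed under *Limitations*.

**Signal model.**  A fast-exchange-limit composite relaxation rate is
computed per time step: each EES element contributes
$(R_{10,elm} + r_1 C_{elm})\,A_{elm}/V$, blood contributes
$v_p (R_{10,blood} + r_1 C_p)$, and the intracellular space $v_{eis} R_{1,eis}$.
Because every term is linear in concentration, the elemental sum reduces to
the area-weighted voxel-mean form used internally; the elemental weights are
normalized to total exactly $v_e$, so the baseline composite rate is exactly
the common $R_{10} = 0.5$ s⁻¹ for every domain.  Signal follows the spoiled
gradient echo equation $S = S_0 \sin\alpha\,(1-E)/(1-\cos\alpha\,E)$,
$E = e^{-TR\,R_1}$, with TR = 5 ms, $\alpha$ = 25°, $r_1$ = 4.7 mM⁻¹s⁻¹,
$S_0 = 1$, and echo-time/T2* effects out of scope.  Scan sampling is
point-sampling (nearest stored step) at $t = 0, \Delta, 2\Delta, \dots$ for
$\Delta \in \{1.6, 3.2, 6.4, 12.8, 25.6\}$ s — the pre-bolus baseline sample
is included, and no interval averaging is applied, mirroring how a scanner
grid samples a continuous signal.

**Analysis pipeline.**  The sampled signal is converted back to
concentration by inverting the SPGR equation with the known voxel baseline
$R_{10} = 0.5$ s⁻¹, and the extended Tofts model is fitted by bounded
Levenberg–Marquardt least squares (`minpack.lm`) in concentration space,
from the conventional initial guess $[0.1\ \mathrm{min}^{-1}, 0.1, 0.01]$
with bounds $K^{trans} \in [0,10]$ min⁻¹, $v_e \in (0,1]$,
$v_p \in [0,1]$.  The constraint $v_e + v_p \le 1$ is deliberately *not*
enforced: the interesting failure mode is precisely the unconstrained-style
overestimation of $v_p$.  The model convolution is evaluated on a grid ten
times finer than the data by default (`supersample = 10`): with the
convolution quadrature restricted to the sample grid itself, the trapezoid
error at 12.8–25.6 s resolutions grows with the curve amplitude — and hence
with $D$ — and dominates $\chi^2$, masking the physical lack-of-fit ordering
($\chi^2$ decreasing in $D$) that the accurate convolution recovers;
`supersample = 1` restores the strictly sample-grid analysis for comparison.
$\chi^2$ is the residual sum of squares in mM².  Percent parameterization
error is
$100\,(\mathrm{fitted}-\mathrm{true})/\mathrm{true}$ per parameter.

## Verification strategy

Every stage has an independent reference:

* **Analytic:** cosine-mode decay on a hole-free square
  ($e^{-D\pi^2 t/L^2}$), with measured spatial order ≈ 2 (P1) and temporal
  order ≈ 2 (Crank–Nicolson); exact mass conservation in sealed domains;
  constant-input closed forms of both Tofts models.
* **Masked-grid finite differences:** a 5-point-stencil solver of the same
  continuous problem on a pixel rasterization of the geometry, with
  per-vessel flux corrected for the staircase-to-circle perimeter ratio.
  At 0.5 µm pixels and finer, the FD voxel mean matches the FEM within 2% of
  peak across fixture domains and $D \in [10^{-4}, 10^{-3}]$ mm²/s.  1 µm
  pixels are sufficient for the *area fractions* but pinch off the ~1 µm
  inter-cell channels and block flux, so the dynamic oracle uses 0.3–0.5 µm.
* **Well-mixed limit:** at $D = 3\times10^{-3}$ mm²/s the simulated voxel
  EES mean matches the closed-form standard-Tofts solution within 3% of
  peak, and the full signal-fit pipeline recovers all three parameters
  within 5% at 1.6 s resolution.
* **Self-consistency:** fitting extended-Tofts data generated by
  extended-Tofts recovers the parameters to <1% (the fitter's
  identifiability floor).

## Problem sizes used by the tests

The shipped suite scales the study down so the full verification battery
runs in minutes: fixture voxels of 60–100 µm (same cell/vessel sizes and
fractions as the 250 µm reference, fewer shapes), 4–10 µm meshes, and a
reduced experiment grid (one domain at $v_e = 0.39, v_p = 0.03$ on a 150 µm
voxel, $K^{trans} = 0.4$ min⁻¹, $D \in \{1, 2, 4, 30\}\times10^{-4}$ mm²/s,
all five temporal resolutions).  The full grid —
$K^{trans} \in \{0.1, 0.4, 0.7\}$ min⁻¹, $v_e \in \{0.25, 0.39, 0.55\}$,
$v_p \in \{0.01, 0.03, 0.06\}$, 8 log-spaced $D$ values in
$[3\times10^{-5}, 3\times10^{-3}]$ mm²/s, five resolutions (1080 rows) — is
what `experiment_config()` defaults to and runs unattended via the `dcevox
grid` CLI.

## What the synthetic conditions do and do not establish

The generator emulates: realistic cell/vessel length scales and volume
fractions, spatially spread vasculature, a bolus-plus-washout plasma input
with the documented peak time, noiseless scanner sampling at realistic
temporal resolutions.  It does not emulate: measured-AIF amplitude or exact
shape (so headline *numeric* error ranges here are indicative, not
reproductions — quantities that depend on the AIF's height and wash-in slope,
notably the magnitude of $v_p$ and $K^{trans}$ errors at coarse sampling,
shift with the surrogate), vascular clustering, flow-limited delivery,
three-dimensional topology (2-D cell cross-sections obstruct diffusion
differently from 3-D packings), thermal noise, or T2*/water-exchange
effects.  The bound-style checks the package asserts (the $v_e$ error band,
$\chi^2$ monotonicity in $D$, near-zero error in the well-mixed limit) were
chosen because they are robust to the surrogate input.

## Numerical choices and degenerate inputs

* Tie-break/degeneracy in the Delaunay predicates is avoided by a
  deterministic ~$10^{-6}$ relative radial wobble on hole polygon vertices
  (circle vertices are otherwise exactly cocircular) and a 4% lattice
  jitter; predicates use long-double arithmetic with relative tolerances.
* Boundary-segment splits stop below 2% of the edge target, capping
  refinement cascades in narrow inter-cell channels.
* `ve + vp = 1` is accepted (a cell-free domain); `ve + vp > 1` is an error.
  Packing that cannot meet the fraction tolerances (±0.01 on $v_e$, ±0.005
  on $v_p$) raises a packing-failure error after restarts rather than
  returning a degraded domain; at very high intracellular fractions the
  clearance is halved once before giving up.
* The step-count is rounded so the time grid lands exactly on the requested
  duration; the AIF is clamped at its final sample for the half-step beyond.
* Fits report a `converged` flag from the optimizer; degenerate inputs
  (all-zero curves, pure-plasma voxels) fit to the expected corners of the
  bounded parameter space.

## Limitations

Beyond the synthetic-data caveats above: the mesher is a quality refiner,
not a guaranteed-minimal one — for coarse targets around fine geometry the
element count is set by the geometry, not the target; the FD oracle is
first-order accurate at vessel staircases and needs sub-micron pixels; and
clinically sized (1 mm) voxels are out of scope for direct simulation —
the intended use is the preclinical voxel scale, with trends extrapolated.
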