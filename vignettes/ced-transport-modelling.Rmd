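---
title: "Modelling convection-enhanced intraputamenal drug delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling convection-enhanced intraputamenal drug delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cedflow)
```

## The problem

Convection-enhanced delivery (CED) infuses drug directly into brain
parenchyma through a catheter, using the pressure-driven bulk flow at the
tip to push molecules much farther than diffusion alone would carry them.
`cedflow` models one clinically motivated instance of this problem: a short
intraputamenal infusion of the ~30.4 kDa neurotrophic factor r-metHuGDNF, a
Parkinson's disease drug candidate, into the posterior dorsal putamen. The
package answers four linked questions:

1. How does the infused concentration field develop around the catheter at
   different infusion rates (the transport solver)?
2. How fast is GDNF cleared from striatal tissue (the elimination module)?
3. How much drug is lost to clearance while the pump is still running (the
   infusion-loss closed form)?
4. What distribution shapes fit the anatomical target, and how well does an
   MRI tracer predict the drug's distribution volume (geometry and
   tracer-comparison modules)?

## Transport model

Treating tissue as a rigid porous medium with porosity $\phi$ and assuming
an isotropic target (gray-matter structures such as the putamen have low
fractional anisotropy), macromolecular binding neglected, the normalised
interstitial concentration $C(r,t)$ around a spherical source obeys

$$\frac{\partial C}{\partial t}
  = \frac{D}{\lambda^2}\,\frac{1}{r^2}\frac{\partial}{\partial r}
    \!\left(r^2 \frac{\partial C}{\partial r}\right)
  - v_r \frac{\partial C}{\partial r} - kC, \qquad
  v_r = \frac{Q}{4\pi\phi r^2},$$

where $D$ is the free-medium diffusivity, $\lambda \ge 1$ the tortuosity of
the extracellular space (so $D/\lambda^2$ is the effective tissue
diffusivity), $Q$ the volumetric infusion rate, and $k$ a first-order
elimination rate constant. The radial velocity comes from continuity of the
divergence-free interstitial flow with the flux condition
$Q = 4\pi r_0'^2 \phi v_r$ at the source sphere. Concentrations are scaled
to the infusate concentration $C_0$, so $C \in [0, 1]$.

The infusion is simulated from a source sphere of radius $r_0' = 0.2$ cm
rather than from the physical catheter tip: the $1/r^2$ velocity diverges
at small radii and the continuum description breaks down within a couple of
millimetres of the tip. After the pump stops the velocity field collapses
and the deposited drug evolves by diffusion (optionally with elimination),
with a zero-flux inner boundary.

### Key parameters

| Parameter | Symbol | Default | Units | Meaning |
|---|---|---|---|---|
| Porosity | $\phi$ | 0.3 | – | extracellular volume fraction (edema-adjusted; ~0.2 in normal tissue) |
| Elimination rate | $k$ | 3.72e-2 | h$^{-1}$ | fitted striatal clearance of GDNF |
| Vd/Vi ratio | – | 3.87 | – | empirical distribution-to-infusion volume ratio (NHP putamen) |
| GDNF diffusivity | $D$ | 1.3e-6 | cm$^2$/s | free-medium value, Stokes–Einstein extrapolation |
| GDNF tortuosity | $\lambda$ | 2.2 | – | macromolecule hindrance in brain ISF |
| Gd-DTPA diffusivity | $D$ | 4.1e-6 | cm$^2$/s | cube-root MW scaling from GDNF, stored rounded to 2 s.f. |
| Gd-DTPA tortuosity | $\lambda$ | 1.6 | – | small-molecule value (1.5–1.6 range) |
| Source radius | $r_0'$ | 0.2 | cm | simulated source sphere |
| Infusion volume | $V_i$ | 0.105 | mL | simulated delivery volume |

The internal unit system is cgs (cm, s); constructors accept the practical
units above and convert once at the boundary, which avoids the silent bugs
that arise when cm²/s, µL/min and h⁻¹ are mixed in one expression.

The Stokes–Einstein chain for GDNF itself is not re-derived (the source
diffusivity of the NGF-conjugate measurement it rests on is not available);
$D_{\mathrm{GDNF}}$ is a stored constant, while
`scale_diffusivity_by_mw()` exposes the inverse cube-root molecular-weight
scaling for deriving other species, e.g. the Gd-DTPA value. The preset
stores the conventional rounded 4.1e-6 rather than the unrounded 4.14e-6 so
that tabulated downstream quantities (Peclet numbers in particular) are
reproduced at their printed precision.

## Numerical scheme

The solver (`solve_infusion()`, `solve_post_infusion()`) uses a
conservative finite-volume discretisation on a uniform radial grid from
$r_0'$ to $R_\max$ (default 3 cm, checked at run time to be beyond the
front). Because the flow is divergence-free, the advective solute flux
through *any* spherical face equals $Q \cdot C_{\mathrm{face}}$ exactly;
face concentrations are reconstructed with a van Leer flux limiter. This
matters: at the highest infusion rate the Peclet number reaches ~150, where
centred differences oscillate and first-order upwinding smears the front
with numerical diffusion comparable to the physical one. The limited scheme
is TVD — the front stays monotone and in $[0,1]$ — while staying second
order where the solution is smooth.

Time stepping is strong-stability-preserving RK2 with a fixed step bounded
by the advective CFL limit and the explicit diffusion limit (safety factor
0.4), plus an accuracy cap of $0.02/k$ when the reaction term dominates.
An implicit integrator was considered and rejected: it would either destroy
the TVD property or require a nonlinear solve per step, and at the problem
sizes used here (about 1100 cells, a few thousand steps for the longest
17.5-h infusion) the explicit march completes in seconds. For the same
reason the grid is uniform rather than refined near the source: the source
sphere radius (0.2 cm) is already two orders of magnitude larger than the
default cell (0.0025 cm).

Verification tests hold the scheme to its analytic limits: the
pure-convection front lands at the mass-balance radius
$(r_0'^3 + 3V_i/4\pi\phi)^{1/3}$ within one cell; with $Q = 0$ a thin
Gaussian shell matches the spherical diffusion kernel to better than 1% in
L2; a uniform field decays as $e^{-kt}$; total mass follows
$dM/dt = Q - kM$; and the half-maximum crossing radius moves by less than
0.5% when the grid is halved.

### The inner boundary, and why printed distribution magnitudes are not targets

The physical source condition at $r_0'$ is genuinely ambiguous. The default
`"flux"` mode imposes the total solute flux $Q C_0$ through the source
sphere, which conserves mass exactly: at the end of a 0.105 mL infusion
into $\phi = 0.3$ tissue the advected front must sit near 0.451 cm, and it
does. An alternative `"fixed"` mode clamps the source surface at the
infusate concentration (a stronger source), and a `source_strength` factor
is exposed for calibration studies. Published simulations of this protocol
report half-maximum radii of 0.553–0.558 cm for the same $V_i$ — a value
that advective mass balance cannot produce with this velocity field and
porosity, implying an effective source stronger than $Q C_0$ whose exact
form is not recoverable. `cedflow` therefore does **not** tune its defaults
toward those magnitudes; distribution-volume *orderings* and rate
dependences are asserted instead, and the analytically checkable quantities
(Peclet numbers, loss volumes, geometry) are reproduced exactly. One
pointwise claim is knowingly not met: the 3 and 5 µL/min end-of-infusion
profiles, though they share front position to 0.2%, differ by up to ~0.07
in $C_{\mathrm{norm}}$ in the thin front region, because the slower
infusion runs 14 min longer and its front is diffusionally wider (the same
width difference is implied by the published high/low-threshold volume
pairs). "Nearly identical" is true of a profile plot, not of a pointwise
supremum.

## Elimination kinetics

Two independent estimates of $k$:

**Compartmental fit.** `fit_two_compartment()` fits the bolus-input
two-compartment model (central = brain extracellular space; elimination
$k_{10}$, exchange $k_{12}$, $k_{21}$) to whole-striatum amount–time data
by least squares on log amounts — a proportional-error assumption, the
standard surrogate when the original assay's error model is unknown. Rates
are log-parameterised (positivity for free), optimised by
Levenberg–Marquardt from five log-spaced starts, with standard errors from
the Gauss–Newton $\sigma^2 (J^{\top}J)^{-1}$ at the optimum. The two dose
groups (15 and 3 µg) are fit jointly with shared rate constants and initial
amounts fixed at the dose — dose-proportionality is an assumption, made
explicit here. With the default generating values
($k_{10} = 3.72\times10^{-2}$, $k_{12} = 7.12\times10^{-4}$,
$k_{21} = 3.81\times10^{-3}$ h$^{-1}$), $k_{12} \ll k_{10}$ and the
single-rate approximation $k \approx k_{10}$ holds, giving a striatal
half-life of about 19 h.

**ISF bulk flow.** Independently, if clearance is dominated by the slow
bulk outflow of interstitial fluid (~0.17 µL g$^{-1}$ min$^{-1}$), then for
any brain mass $k = Q_{\mathrm{ISF}}/V_{\mathrm{ISF}}$ — the mass cancels —
which with $\phi = 0.3$ gives $3.40\times10^{-2}$ h$^{-1}$, agreeing with
the fit and supporting ISF flux as the clearance mechanism.

## Loss during infusion

While the pump runs, tissue near the catheter sits at $C_0$ and loses drug
at rate $k$. Under a lumped approximation (concentration $C_0$ throughout
the growing $V_d$, $V_d/V_i$ constant, diffusion and binding neglected) the
cleared amount has the closed form

$$A_{\mathrm{Loss}}(t) = Q C_0 \frac{V_d}{V_i}
 \left(t - \frac{1 - e^{-kt}}{k}\right),$$

implemented with the analytic $k \to 0$ limit (zero loss) rather than the
indeterminate $0/0$. `loss_numeric()` integrates the underlying ODE pair
with `deSolve` and agrees to 1e-8 relative — a deliberate dual route that
keeps the closed form checkable. For the projected 0.13 mL per-catheter
infusion volume, the lost infusate-volume equivalents are 0.020, 0.007 and
0.004 mL at 1, 3 and 5 µL/min: about 1% of the target $V_d$ at the
CED-capable rates, growing as infusions slow.

## Target geometry

The planning target is a 0.5 mL per-catheter distribution volume in the
posterior dorsal putamen (modelled as a 1.92 × 1.15 × 1.12/0.90 cm box; the
two widths are measured at different levels of the tapering structure). A
reflux-free catheter gives a sphere, $V_d = \frac{4}{3}\pi r^3$, whose
0.98 cm diameter overflows the narrow width level. Controlled reflux gives
a capsule — hemisphere below the tip plus cylinder above,
$V_d = \frac{2}{3}\pi r^3 + \pi r^2 h$ — whose length and diameter trade
off inversely; `solve_cylinder()` inverts the volume for either fixed
dimension (to 1e-9 mL) and `check_roi_fit()` reports per-dimension margins.
The catheter's own displaced volume (~8 µL) is negligible against 0.5 mL
and is not subtracted. Catheter inclination is out of scope: the capsule
axis is assumed aligned with the ROI's long axis, a documented limitation.

## Synthetic data

`generate_pk_dataset()` emulates the rat striatal study design the
elimination fit rests on — two CED doses (15 and 3 µg), whole-striatum
amounts at 3, 7, 14, 21 and 28 days — from the two-compartment solution
plus measurement noise. The default noise model is lognormal proportional
error with CV 10% (mean-preserving on the natural scale), the conventional
choice for ELISA-type assays; the true assay error of the original study is
unpublished, so this is an assumption, not a calibration. The generator
reproduces exact draws for a fixed seed without disturbing the caller's RNG
stream. What it deliberately does not emulate: inter-animal variability
(single pooled error level), below-limit-of-quantification censoring, and
any infusion-phase kinetics (the dose appears as a bolus in the central
compartment). Passing recovery tests therefore demonstrate estimator
correctness under the assumed error structure, not robustness to real-assay
pathologies.

The recovery properties verified in the test suite: noise-free
generate-then-fit round trips recover all three rates to better than 1e-4
relative; under 10% proportional noise across 100 seeded replicates the
$k_{10}$ estimator is biased by well under 5% and its 2-SE interval covers
the truth in ≥ 90% of replicates.

## Problem sizes and run times

Default solver resolution is $\Delta r = 0.0025$ cm on a 3 cm domain
(~1100 cells). The full four-rate comparison (including the 17.5-h
0.1 µL/min infusion) runs in a few seconds; the tracer comparison
(two infusions plus 2 h of post-infusion diffusion for each species) in a
few more. The test suite, including the 100-replicate fitting study, runs
in well under a minute. These sizes were chosen because halving the grid
changes reported crossing radii by ~0.02% — far inside the 0.5% convergence
criterion — so finer grids buy nothing.

## Known limitations

- One-dimensional spherical symmetry: no anisotropy, no white-matter
  preferential flow, no DTI-informed geometry, no tissue segmentation.
- No catheter-track fluid mechanics: reflux appears only as the capsule
  *shape* model, not as a simulated flow.
- No poroelasticity; edema is folded into the single porosity value.
- The effective source condition near the catheter is under-determined (see
  above); absolute distribution volumes from the solver are conservative
  (mass-conserving) and smaller than published magnitudes obtained with a
  stronger effective source.
- Single-subject (pooled) PK fitting only; no mixed-effects modelling.
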