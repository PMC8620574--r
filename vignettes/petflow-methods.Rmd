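---
title: "petflow: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petflow: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What petflow models

petflow simulates how an intravenously injected PET radiotracer (FDG)
distributes through a two-dimensional slab of tissue containing a solid
tumor, resolving the microvasculature explicitly. Three physical layers are
coupled:

1. **Intravascular blood flow.** The capillary network is a centreline graph
   with per-edge radii. Each edge carries Poiseuille flow, so the network is
   a resistor circuit with conductance $g = \pi r^4 / (8 \mu L)$ and
   Kirchhoff balance at every interior node; boundary nodes (the ends of the
   four parent vessels) carry prescribed pressures. Transmural leak appears
   as a lumped conductance per edge draining toward the local interstitial
   pressure corrected by the reflected osmotic difference.
2. **Interstitial fluid flow.** Tissue is a porous medium: $v_i = -\kappa
   \nabla P_i$ (Darcy), and continuity with distributed sources and sinks
   gives $-\kappa \nabla^2 P_i = \phi_b - \phi_L$ with Starling filtration
   $\phi_b = L_p (S/V)(P_b - P_i - \sigma_s(\pi_b - \pi_i))$ and lymphatic
   drainage $\phi_L = L_{pL}(S/V)_L (P_i - P_L)$, the latter present only in
   normal tissue (tumors lack functional lymphatics). Both $\phi$ terms are
   linear in $P_i$, so the interstitial problem is a single symmetric
   positive-definite solve per outer iteration.
3. **Tracer transport.** Three tissue compartments: free extracellular
   $C_i$, free intracellular $C_e$, phosphorylated (trapped) $C_m$:
   $$\partial_t C_i = \nabla\!\cdot\!(D_{\mathrm{eff}} \nabla C_i)
     - v_i \!\cdot\! \nabla C_i - L_3 C_i + L_4 C_e + \Phi_{bt} - \Phi_{Lt},$$
   $$\partial_t C_e = L_3 C_i - (L_4 + L_5) C_e, \qquad
     \partial_t C_m = L_5 C_e,$$
   with the Patlak transvascular flux
   $\Phi_{bt} = \phi_b (1-\sigma_f) C_p + (P S/V)(C_p - C_i)
   \,\mathrm{Pe}/(e^{\mathrm{Pe}}-1)$,
   $\mathrm{Pe} = \phi_b (1-\sigma_f)/(P S/V)$, and lymphatic solute loss
   $\Phi_{Lt} = \phi_L C_i$. $C_p(t)$ is the arterial input function (AIF).
   There is no dephosphorylation: $C_m$ is monotone non-decreasing.

The phosphorylated pool is what a PET scanner predominantly sees at late
times; the spatial pattern of $C_\mathrm{total} = C_i + C_e + C_m$ reflects
both the kinetics and the vascular geometry.

# Parameters

All internal quantities are SI; converters (`mmHg_to_Pa`,
`per_min_to_per_s`, `cm_per_mmHg_s_to_SI`) accept the units customary in the
tissue-transport literature. `default_params()` carries the literature
values: per-region osmotic pressures ($\pi_b$ = 20 mmHg; $\pi_i$ = 10 / 15
mmHg normal/tumor), reflection coefficients ($\sigma_s$ = 0.91 / 0.82,
$\sigma_f$ = 0.9), wall conductivities ($L_p$ = 0.36e-7 / 2.8e-7
cm/(mmHg s)), interstitial conductivities ($\kappa$ = 6.41e-15 / 30e-15
m^2/(Pa s)), lymphatic coefficient (1.33e-5 1/(mmHg s) normal, 0 tumor),
permeabilities ($P$ = 3.75e-7 / 3.0e-6 m/s) and kinetic rates
($L_3$ = 8.2e-4, $L_4$ = 6.7e-4, $L_5$ = 5.3e-4 1/min).

Three sourcing caveats, all config-exposed:

* **Effective diffusivity.** The source table prints $D_{\mathrm{eff}}$ as
  "0.37e-9 (normal)" and "2.5e-3 (tumor)", both labelled mm^2/s — mutually
  inconsistent by seven orders of magnitude. We adopt $3.7\times10^{-10}$
  m^2/s for normal tissue (reading the printed number as m^2/s, the
  physically plausible scale for a small solute in tissue) and
  $2.5\times10^{-9}$ m^2/s for tumor (converting mm^2/s).
* **Tumor cell-uptake rates.** $L_3, L_4$ are published for normal tissue
  only. The fixture default sets tumor rates to 10x normal — a convention
  standing in for the elevated glucose avidity of tumor cells, not a
  measured value.
* **Unprinted physical scales.** $S/V$ (2.0e4 1/m), blood viscosity
  (3e-3 Pa s), parent/capillary radii (40 / 5 um), and parent inlet/outlet
  pressures (25 / 10 mmHg) are not given by the source; the defaults are
  standard microcirculation numbers.

# The synthetic vasculature: what it emulates and what it does not

The reference geometry's capillary image is not available, so
`generate_network()` builds a stand-in with the stated layout: a
6.72 cm x 6.09 cm rectangle, a 2.3 cm tumor disc at the centre, and four
parent vessels spanning the width (bottom, top, and two mid-height vessels
that cross the tumor), their end nodes on the domain boundary carrying the
pressure boundary conditions. Capillaries grow as seeded random polylines
rooted on the existing network — every capillary is connected to a parent —
steered toward whichever region still lacks centreline length. Growth stops
when the realized length density per region is within 10% of target
(book-kept exactly; the final segment is trimmed to land on target).
Defaults: 8000 m/m^2 in the tumor, 3000 m/m^2 outside, i.e. mean inter-vessel
spacings of roughly 0.13 and 0.33 mm. These give a densely vascularized
tumor whose interstitial pressure plateaus, which is the regime the
reference results describe ("IFP proportional to microvascular density").

The generator is deliberately *not* a mechanistic angiogenesis model: no
chemotaxis, no anastomosis loops beyond chance contact, no radius
adaptation. A green test on this fixture establishes that the solvers
reproduce the physics on a network with the stated density, topology
(tree-on-parents) and calibre — not that the geometry is biologically
faithful. Likewise `render_image()` emulates only the features of a
micrograph that the extraction pipeline consumes (green-channel contrast,
background level, Gaussian sensor noise); it has no uneven illumination,
no out-of-focus blur, no staining artifacts.

# Numerical choices

**Grids.** Cell-centred structured grid, `nx x ny` chosen from
`grid_spacing`; fields are `nx x ny` matrices with y increasing upward.
Region-dependent coefficients are harmonically averaged at cell faces
(flux-conservative, so the tumor/normal interface continuity conditions hold
discretely); the outer boundary is Dirichlet gauge $P_i = 0$ for pressure
and zero diffusive flux (open boundary) for concentration.

**Vessel source localization.** Exchange is localized to the vasculature
through a vessel-weight field built at a *fixed physical scale*: the network
is rasterized on ~0.11 mm subpixels, the coverage is aggregated into fixed
0.9 mm blocks — a local microvascular density — and the block field is
sampled onto the solver grid, then normalized so its mean over each region
equals the configured $S/V$. Blood pressure is mapped the same way
(coverage-weighted mean of nearest-edge pressures per block). Two
alternatives were tried and rejected. Rasterizing at the solver resolution
makes the source an indicator that sharpens indefinitely under refinement,
so the maximum interstitial velocity never becomes grid-independent (~25%
change per refinement level in trials). Rasterizing at a fixed 0.1 mm
resolution fixes the field but leaves features no affordable grid can
resolve — max |IFV| still changed ~25% between successive levels. With the
0.9 mm block density the source field is a fixed property of the network
that every study grid resolves. The price is stated plainly: exchange is
distributed over a ~1 mm perivascular neighbourhood rather than a 5 um
vessel wall — the desk-scale analogue of the reference's fully resolved
finite-element vasculature. Heterogeneity at and above the millimetre scale
(the scale of the reported IFP-MVD correlation and probe contrasts) is
preserved.

**Interface treatment and the velocity maximum.** The material coefficients
$\kappa$ and $D_{\mathrm{eff}}$ are antialiased at the circular tumor
interface by subcell (4x4) coverage fractions with harmonic blending — the
structured-grid analogue of a body-fitted mesh. Without it the staircase
interface carries corner singularities in $\nabla P$ and the pointwise
maximum of $|v|$ never settles under refinement. Even with it, the
interstitial pressure has an intrinsic screening layer
$\ell = \sqrt{\kappa/(L_p S/V)} \approx 0.3$ mm at the tumor rim, where the
velocity maximum lives; grid independence of that maximum requires
$h \lesssim 30$ um at the finest level. The packaged grid-independence
study therefore runs on a quarter-scale domain where such a level is
affordable (600 x 544 cells at the top); the max-IFP and
median-concentration metrics converge one to two orders of magnitude more
tightly than the velocity maximum.

**Coupled flow solve.** Fixed-point iteration between the network solve and
the interstitial solve. Both linear operators are iteration-invariant, so
each is assembled and Cholesky-factorized once; iterations only swap
right-hand sides. Convergence is declared at a relative L2 change of `P_i`
below 1e-6 (observed contraction rate ~ 0.78 on the default fixture, i.e.
50-60 iterations, a few seconds at 300 x 270).

**Transport integrator.** Operator splitting per `dt` (default 1 s):
vectorized RK4 for the pointwise kinetics/exchange (4 substeps; the
dominant local rate is $P S/V \approx 0.06$ 1/s in tumor, so
$\lambda h \approx 0.015$ and the local error is negligible), explicit
first-order upwind convection (CFL-checked; interstitial speeds of order
1e-7 m/s make this constraint vacuous at any sensible `dt`), and backward
Euler diffusion with a cached sparse Cholesky factor. The convection term is
the advective form $v\cdot\nabla C_i$ — the divergence part of
$\nabla\cdot(v C)$ corresponds to the filtration/drainage volume exchange
already represented by the $\Phi$ source terms; a conservative flux-form
option (`sim_config(conservative = TRUE)`) is provided, conserves mass to
machine precision, and is what the solute-balance acceptance check uses.
Roundoff-level negative concentrations are clipped to zero; negatives beyond
1e-6 of the field maximum abort the run as a scheme error.

**AIF.** Default is a bolus-plus-washout biexponential
$C_p(t) = A(e^{-t/\tau_w} - e^{-t/\tau_r})$ with $A$ = 100 mol/m^3,
$\tau_r$ = 30 s, $\tau_w$ = 1800 s — a curve with the canonical shape
(fast rise, slow clearance) since the reference input exists only as a
figure. Any tabulated curve can be supplied as CSV. Absolute concentration
scales in this package are therefore only meaningful relative to the AIF
amplitude; all qualitative and property-based results are invariant to it.

**Oracles.** Two independent closed forms back the solvers. The well-mixed
kinetic system is solved exactly by augmenting the 3x3 compartment matrix
with the AIF modes (exponentials for the parametric AIF; a linear-in-time
state per segment for tabulated ones) and propagating with `Matrix::expm` —
a different route than the production RK4/splitting integrator, and
cross-checked in the tests against a third route (fine-step RK4). The
axisymmetric pressure problem with uniform source on a disc has the
modified-Bessel solution $P(r) = P_e(1 - I_0(\alpha r/R)/I_0(\alpha))$,
$\alpha = R\sqrt{L_p(S/V)/\kappa}$, evaluated with exponentially scaled
Bessel functions; the test imposes the disc-edge Dirichlet condition through
a stiff penalty sink antialiased by subcell coverage fractions. The plateau
$P_e = P_b - \sigma_s(\pi_b - \pi_i)$ ("effective filtration pressure") also
serves as the maximum-principle bound on any computed IFP field.

**Segmentation.** CLAHE uses 8x8 tiles, 256 bins and a normalized clip limit
of 0.01 by default; the binarization threshold is a *required* argument
because the reference procedure chose it by trial and error per image (an
optional Otsu mode is provided as an extension). Despeckling removes
8-connected components below `min_component_px`. Contours are marching
squares at level 0.5 on a 3x3 box-blurred indicator — the blur gives
subpixel boundary localization and removes the staircase perimeter bias
(a hard indicator overestimates a disc's perimeter by ~6%). Skeletons come
from Zhang–Suen thinning; traced chains become edges with length equal to
the traced centreline length plus one radius per free end (thinning retracts
about one radius at vessel tips) and radius equal to the mean Euclidean
distance transform along the chain.

# Scale-down policy in the packaged checks

The test suite exercises most physics on a 10x-reduced domain (6.72 mm x
6.09 mm, same proportions) so the default run completes in minutes; the
acceptance-criterion tests that prescribe the full scale (maximum tumor IFP
at ~300 x 270, its mass balance and velocity bracket) run at full scale. The
in-suite grid-independence study uses a half-scale domain with a coarse base
level; the acceptance script runs the full-domain study. These are runtime
scalings, not tolerance changes.

# Known limitations

* Strictly 2D; no tumor growth, vessel remodelling, or red-blood-cell
  rheology; vessels are static resistors with Newtonian blood.
* The intravascular model is a 1D Poiseuille reduction of lumen flow — exact
  for the pressure-drop physics at capillary Reynolds numbers but blind to
  in-lumen concentration gradients.
* Tracer kinetics are linear (no saturable transport, no Warburg-type
  dependence of rates on the microenvironment) and parameters are uniform
  per region.
* Printed concentration tables from the reference depend on its unavailable
  source image and figure-only AIF; petflow reproduces their qualitative
  structure (tumor ≫ normal uptake, early $C_i$ dominance, MVD-ranked
  probes), not their absolute numbers.
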