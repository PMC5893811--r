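---
title: "Modeling blood stasis in the left atrial appendage: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling blood stasis in the left atrial appendage: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During atrial fibrillation (AF) the large majority of left atrial thrombi
form inside the left atrial appendage (LAA), a small trabeculated sac
protruding from the left atrium (LA). Clinically, LAA shapes are grouped
into four classes — chicken wing (a bent dominant lobe), cactus (a central
lobe with secondary lobes), windsock (one dominant tapering lobe) and
cauliflower (short, multi-lobed, irregular) — and the classes appear to
carry different thrombotic risk. `laastasis` builds a desk-scale
computational model of this problem: it generates parametric planar LA+LAA
geometries for the four classes, drives them with pulsatile mitral outflow
under normal rhythm and AF, solves the transient incompressible flow, and
quantifies stasis with a washed-out virtual contrast agent, shear strain
rate (SSR) fields, and ostium-to-tip centerline profiles.

Everything here is synthetic and two-dimensional. Patient-specific
three-dimensional anatomies are not desk-reproducible, so the package aims
at the *qualitative* result surface — which quantities fall from ostium to
tip, which direction AF moves them, where the residual dye ends up — rather
than at any patient-specific number.

## Flow model

Blood is treated as incompressible and Newtonian (density 1060 kg/m³,
dynamic viscosity 0.0035 Pa·s), and the flow as laminar: with the peak
mitral velocity of 0.32 m/s and a 25 mm mitral orifice the Reynolds number
is ≈ 2400, below the conventional 3000 transition bound
(`reynolds_number()` checks this for every generated anatomy). Walls are
rigid with no-slip; the pulmonary-vein (PV) inlets are open boundaries held
at the reference pressure 0 Pa (traction-free, so the flow split across the
veins is an outcome); the mitral orifice carries a prescribed plug velocity
waveform.

One cardiac cycle lasts `T = 0.8` s: 37.5% atrial diastole (mitral valve
closed, the atrium fills from the PVs) followed by the atrial emptying
window carrying the early-filling E-wave and the atrial-contraction A-wave.
The two waves are modeled as raised-cosine (Hann) pulses — only the peak
(0.32 m/s), the period and the phase split are published for the reference
waveform, so the pulse shape is this package's choice; the E pulse spans
0.30–0.60 s and the A pulse 0.70–0.80 s so that the A-wave peaks at
t = 0.75 s, the instant commonly used to visualize late diastolic flow. The
A-peak defaults to 75% of the E-peak, a typical E/A ratio for healthy
filling. AF is modeled by removing the A-wave (`A_peak = 0`) and changing
nothing else, which mirrors the loss of atrial contraction.

## Discretization

The solver is a semi-implicit, non-incremental pressure-projection
(fractional-step) scheme on unstructured P1 triangles:

1. explicit advection (Galerkin transport with residual-based SUPG
   streamline stabilization) and implicit viscosity give a tentative
   velocity, with no-slip and mitral Dirichlet values at the new time level;
2. a pressure Poisson solve, gauged by the zero-pressure Dirichlet condition
   on the PV boundary (or by pinning one node on closed test domains),
   projects the tentative velocity toward the divergence-free space;
3. the face volume fluxes used by the scalar transport are then projected
   *exactly*: a cell-centered two-point correction (solved once per step
   with a prefactored Cholesky decomposition) zeroes the net flux of every
   cell to machine precision. Walls keep exactly zero flux and the mitral
   flux stays as prescribed; the correction is absorbed by the open PV
   faces.

The non-incremental (Chorin) form is the default because, on equal-order
P1/P1 elements with open boundaries, the incremental form lets spurious
pressure modes accumulate and feed back through the SUPG term; the
non-incremental form re-derives the pressure each step and damps them. Its
O(dt) splitting error vanishes at steady state, which is how the scheme is
verified: a body-force-driven Poiseuille channel is recovered within 2% in
L2, and a forced steady vortex (manufactured solution) converges with
observed order ≈ 1.9 in the velocity L2 norm across three meshes, against
the formal spatial order 2 of P1 elements. The rest state is reproduced
exactly, and the projected flux divergence is checked against
`pressure_tol` (default 1e-8 s⁻¹) every step.

The virtual contrast agent is a passive cell-wise scalar, initialized to 1
over the whole fluid domain and advected by the projected fluxes with a
monotone MUSCL finite-volume scheme (Green–Gauss gradients with the
Barth–Jespersen limiter; `scalar_order = 1` falls back to plain upwind).
Because the fluxes are discretely divergence-free and sub-steps cap the
transport CFL at 0.22, the scheme is conservative and preserves
`0 ≤ c ≤ 1`; inflow at the PVs carries `c = 0` and outflow through the
mitral orifice removes contrast with the flow. No physical diffusivity is
added — the washout the scheme computes includes the (acknowledged)
numerical diffusion of a second-order limited scheme at the default
resolution. Runs use the published protocol: time step 0.5 ms, four
cardiac cycles.

## Synthetic anatomies

The generator emulates frontal-view silhouettes of the four classes. The LA
body is an ellipse of ~5 cm diameter; PV openings (class defaults 4, 5, 6, 4
veins) sit on the upper-left arc with the left-most vein — the analog of the
left superior PV — immediately adjacent to the appendage orifice, as in real
anatomy; the mitral orifice (25 mm) sits at the bottom, and the LAA attaches
inferolaterally (between the left veins and the lateral mitral annulus)
through an explicit ostium chord (12 mm) that also serves as the internal
LA/LAA separating curve — the published methodology never states how that
separation was drawn, so an explicit parametric curve is this package's
assumption. The placement matters hydrodynamically: the ostium must see the
sweeping PV-to-mitral stream, otherwise the appendage sits in a numerical
backwater and the rhythm condition barely reaches it (an equatorial
placement was tried first and discarded for exactly that reason). The appendage is a tube
swept along a spine with a class-specific width law: a 100° bend (chicken
wing), lateral Gaussian lobes (cactus, alternating sides), a linear taper to
25% of the ostium width (windsock, the longest lobe at 35 mm), and a short
(20 mm) bulbous outline with ≥3 lobes plus a seeded smooth Fourier
perturbation (cauliflower). Lengths follow the clinical 2–4 cm range, with
the cauliflower deliberately the shortest. Every geometry is a deterministic
function of its spec (including the seed), and outlines are checked for
self-intersection.

Meshing is unstructured Delaunay (a Bowyer–Watson kernel in C++) seeded
with boundary points at spacing ~`h`, points along the ostium chord, and a
jittered hexagonal interior lattice, followed by two smoothing passes and
clipping to the polygon; boundary facets inherit the label of the nearest
outline segment and cells are tagged LA/LAA by the side of the ostium curve.
The default `h = 1.35` mm yields ≈ 3000 triangles per anatomy with minimum
cell quality ≈ 0.6 — the deliberate desk-scale stand-in for the
multi-million-element patient meshes of the reference setting. Within the
admissible desk-scale band the coarser end is preferred on purpose: a planar
model has no vortex stretching, so long-lived 2-D vortices make the
free-decay phase of the cycle weakly chaotic at finer resolution, while the
extra numerical dissipation of the coarser mesh stands in for the missing
3-D dissipation and lets the flow settle into the periodic cycle the
reference setting reports. Boundary resolution is uniform rather than
ostium-refined: the ostium already spans ~9 cells, which removed the need
for grading.

The centerline used for profiling starts at the centre of the ostium curve
(s = 0) and ends at the LAA tip (s = 1), passing through the centre of
gravity of successive cross-sections. Cross-sections are implemented as
bands of equal geodesic distance from the ostium over the LAA
cell-adjacency graph — a definition that stays meaningful in bent and
multi-lobed appendages; when a band is multiply connected the component
containing the previous station is followed, keeping the line
path-connected. In lobed classes the centre of gravity genuinely wobbles
toward whichever lobe a band includes; this is the defined behavior, not
noise.

## Stasis metrics

* **SSR**: `sqrt(2 D : D)` with `D` the symmetric velocity-gradient tensor,
  computed cell-wise (exact for P1 fields). Simple shear `u = (g y, 0)`
  gives SSR = g; uniform flow and rigid rotation give 0. The published work
  never writes its SSR formula (a commercial-solver output), so this
  standard invariant definition with the simple-shear calibration is
  adopted.
* **Centerline profiles** of |v| and SSR, and **LAA-normalized volume
  integrals** (field integral over the appendage divided by appendage
  measure). Both are evaluated at the *late-diastolic (A-wave peak) phase of
  the final cycle* — the phase convention of the comparison figures, and the
  cycle phase at which the two rhythm conditions actually differ (the E
  branch is identical by construction). Stationary-window time averages of
  the same fields remain in the run object as diagnostics; note that in a
  planar model the cycle-averaged appendage velocity can even *rise* under
  AF, because the un-interrupted appendage vortex keeps rotating through the
  quiescent window while exchanging almost nothing — rotation is not
  washout. Ostium-to-tip decay is asserted with Spearman rank correlation
  below −0.7 rather than pointwise monotonicity, because profiles are noisy
  even in the reference figures.
* **Residual contrast**: percentage of contrast left after the run,
  normalized by the whole fluid domain (the published convention) and by
  the LAA volume (the per-appendage variant used for comparisons).
* **Dye localization**: concentration-weighted mean of the normalized
  arclength of LAA cells, each mapped to its nearest centerline station —
  values above 0.5 mean the residue sits in the distal (tip) half.
* **Periodicity**: relative lumped-mass L2 difference of velocity fields at
  matched cycle phases, averaged over the recorded phases; runs are
  considered periodic when cycles 3 vs 4 differ by less than 0.1 (10%), the
  package's reading of "no significant cycle-to-cycle difference" at desk
  scale.

## What the synthetic grid does and does not show

The default experiment (`experiment_config(seed = 1)`) runs the 4 × 2 grid
of morphologies × rhythm conditions, four cycles each. On it the package
reproduces the qualitative result surface: velocity and SSR fall from
ostium to tip in every case; AF lowers the LAA-normalized velocity and SSR
integrals for every morphology; AF retains more contrast than normal
rhythm; the windsock shows the lowest residual of the four shapes, matching
the published ordering; and the residual dye sits distally. One known
exception is quantitative: in the windsock the dye-mass centroid stays
marginally proximal of mid-arclength (≈ 0.48–0.49). That number needs
context: the windsock tapers, so a *uniform* dye distribution in it already
has its centroid at 0.40, and four cycles of washout move it ≈ +0.09
distally; a planar laminar model cannot clear a deep tapered cavity in
3.2 s because shear-driven eddy strength decays geometrically with depth —
the distal-half reading holds for the other three shapes and the distal
*shift* holds for all four.

These are 2-D laminar flows in smooth parametric sacs: no trabeculation, no
wall motion, no mitral leaflets, no out-of-plane secondary flows, and a
washout that includes scheme diffusion. Absolute residual percentages are
therefore larger than the published patient-specific values and are not
comparable to them; only orderings and directions of change are claimed.
Within those limits the grid's orderings are stable under the default seed
and mesh resolution, and `inst/cli/laa-stasis.R mesh-sense` reports how the
headline metrics drift across three mesh levels as a stand-in for a formal
sensitivity analysis.

## Numerical parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `dt` | 5e-4 | s | published protocol; advective CFL ≈ 0.1 at default `h` |
| `n_cycles` | 4 | – | published protocol; flow is periodic from cycle 2 |
| `h` | 1.35e-3 | m | ≈ 3k cells; ostium resolved by ~9 cells; coarser end of the desk band for 2-D dissipation |
| `pressure_tol` | 1e-8 | 1/s | projected-flux divergence is machine-zero; this flags regressions |
| `cfl_limit` | 0.9 | – | explicit advection stability bound |
| scalar CFL cap | 0.22 | – | Barth–Jespersen boundedness on triangles |
| `periodicity_threshold` | 0.1 | – | definition of "no significant cycle-to-cycle difference" |
| `a_ratio` | 0.75 | – | healthy A/E peak ratio (typical Doppler value) |

Degenerate inputs are rejected rather than repaired: zero-measure cells,
open outlines, untagged facets, out-of-bounds concentrations, empty
regions, and concentrations with nothing left in the appendage (the dye
localization is undefined there) all raise typed errors.
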