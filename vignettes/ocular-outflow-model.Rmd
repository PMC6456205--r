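---
title: "The oculoflow model: Darcy flow and pressure-dependent outflow in the human eye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oculoflow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoflow)
```

## The physical model

Aqueous humor is produced by the ciliary body at a few microlitres per
minute, fills the chambers and percolates through the ocular tissues, and
leaves the eye through several outflow routes. `oculoflow` treats the eye as
a rigid, saturated porous medium at steady state:

$$\nabla \cdot v_d = 0, \qquad v_d = -k \, \nabla p,$$

where $v_d$ is the Darcy velocity (volumetric flux per unit gross area,
m/s), $p$ the tissue fluid pressure (Pa) and $k$ the hydraulic conductivity
(m²/Pa·s), assumed isotropic per tissue. The true interstitial velocity is
$v_t = v_d / n_f$ with $n_f$ the fluid porosity. Note the sign: flow runs
down the pressure gradient; the minus sign is required for outflow from the
pressurised globe towards the low-pressure optic nerve and is implied by
every reported result.

Outflow surfaces do not drain at a fixed facility. The outflow facility
declines exponentially with pressure, which integrates to the boundary flux

$$v_{dn}(p) = \frac{C^{SL}}{A\,\alpha}\left(e^{-\alpha p_T} -
  e^{-\alpha (p - p_{back})}\right),$$

a nonlinear Robin condition with surface conductivity $C^{SL}$
(µL/min/mmHg), decay constant $\alpha$ (1/mmHg), no-flow pressure $p_T$ and
an all-round venous backpressure $p_{back}$ that shifts every driving
pressure uniformly (posture acts through it). Two such surfaces are used:
the lumped anterior pathways (trabecular + uveoscleral + pseudofacility,
$C^{SL}_{ap}$) at the limbus, and the retinal pigment epithelium
($C^{SL}_{pre}$) behind the retina. Across the pia mater the optic nerve
leaks linearly towards the cerebrospinal fluid,
$v_{dON} = h_{ON}(p - p_{CSF})$, where $p_{CSF}$ has an orbital "floor" of
about 3 mmHg upright. Integrated over a surface at uniform pressure the
exponential law gives the closed-form 0D model in `pathway_outflow()` /
`solve_iop()`, which serves both as a standalone calculator and as the
independent oracle for the finite-element anterior-chamber pressure.

All computation is carried out in SI units; the reporting layer converts to
mmHg and µL/min (1 mmHg = 133.322 Pa, so $p_T$ = 3 mmHg ≈ 400 Pa).

## Parameters

`default_normal_eye()` returns the calibrated normal upright eye: production
6.14 µL/min, $C^{SL}_{ap} = C^{SL}_{pre} = 0.5$, $\alpha = 0.075$,
$p_T = 3$, $p_{back} = 0$, $p_{CSF} = 3$ mmHg, chamber conductivity
$10^{-5}$ (effectively equipotential chambers), vitreous $8.4\times10^{-11}$,
retina $5\times10^{-14}$, optic nerve $1.6\times10^{-11}$, retrolaminar
$9.1\times10^{-13}$, lamina cribrosa $7.7\times10^{-14}$, prelaminar
$8.3\times10^{-13}$ m²/Pa·s, pial conductivity $1.5\times10^{-11}$ m/Pa·s,
and lamina cribrosa porosity 0.70 (electron micrographs suggest 0.70–0.75;
0.70 is the value consistent with the reported true-velocity figures).
Parameter sets are plain lists with YAML serialization
(`write_params()`/`read_params()`) carrying a units block.

## Geometry and its reconstruction

The globe is a sphere of internal diameter 23.6 mm with the optic nerve
moved onto the symmetry axis (about 2.7 mm from its true position) so the
problem is axisymmetric in $(r, z)$. The optic disc is 1.6 mm across, the
myelinated nerve 3.2 mm; the lamina cribrosa is 0.38 mm thick; about 6 mm of
optic nerve is modeled behind a 0.5 mm retrolaminar expansion.

The full reference geometry table is not available, so several dimensions
are reconstructions, deliberately kept in configuration
(`eye_geometry()`) rather than code:

* **retina thickness 0.16 mm and ora serrata at z = +3.4 mm** — chosen
  together so that, with the retinal conductivity $5\times10^{-14}$ and
  roughly half of a 6.14 µL/min production crossing the retina, the
  trans-retinal pressure drop is ~143 Pa (≈1.07 mmHg), the drop the
  calibrated model attributes to an intact retina;
* **prelaminar 0.3 mm and retrolaminar 0.5 mm** — consistent with the span
  of the published depth-pressure profiles;
* **anterior segment as cylindrical blocks** — the chambers are
  equipotential (conductivity $10^{-5}$ m²/Pa·s), so their exact shape
  cannot influence the solution; the lens and iris are impermeable separator
  slabs, the ciliary inflow a uniform band on the posterior chamber wall
  (the tissue is anatomically a torus; its exact extent is immaterial), and
  the anterior outflow a limbal annulus. The prescribed-total inflow and the
  area-normalised outflow law make all chamber boundary areas cancel.

`build_geometry()` reports exact half-section areas per region; the mesh
tiling test checks the triangulation against them.

## Meshing

`generate_mesh()` is a structured multi-block mesher: each tissue is meshed
as a mapped quadrilateral grid split into linear (P1) triangles, with
coordinates on shared interfaces generated from the same numeric vectors on
both sides so that a merge by exact coordinate key produces a conforming
mesh. The vitreous, which is star-shaped about the globe centre, is meshed
in polar fashion with its boundary ring anchored to canonical interface
points (disc face, retina sphere, hyaloid plane). The default edge-length
target yields ≈6,000 elements with local refinement in the optic nerve head
(at least 4 elements across the lamina cribrosa at any resolution).

Linear elements with refinement replace higher-order interpolation: the
converged fields are identical, assembly stays simple, and the refinement
study (IOP changes <0.5 % under h → h/2) plus the analytic annulus and
spherical-shell fixtures (`make_fixture()`, exact log-radial and $1/\rho$
solutions matched to 0.1 %) enforce adequacy.

## Solver

The axisymmetric weak form weights all integrals by $2\pi r$; with P1
elements the element stiffness $2\pi k A \bar r\,(\nabla\phi_i \cdot
\nabla\phi_j)$ is exact using the centroid radius, and boundary line
integrals (with $r$ linear along each edge) are exact in closed form. The
exponential outflow condition is linearized about the previous boundary
pressure with its tangent slope and the sparse symmetric system re-solved
(Picard with tangent slope — effectively a Newton step on the boundary
nonlinearity); convergence is declared when the largest nodal update falls
below 0.01 Pa, which the mild, monotone nonlinearity reaches in 3–6
iterations from a uniform 15 mmHg start. Relaxation starts at 1 and halves
on oscillation. A solve with no Robin-type condition anywhere is singular
and rejected explicitly. Per-boundary fluxes are evaluated through the
converged boundary laws (consistent fluxes); global mass balance closes to
well under 0.1 % of production — about $10^{-7}$ in practice.

"IOP" always means the pressure at a fixed probe node in the mid anterior
chamber, where it is measured clinically; the equipotential chambers make
the probe position uncritical. Fixed-pressure conditions (used by the
calibration workflows and the analytic fixtures) are penalty Robin
conditions with a conductance ~8 orders of magnitude above any tissue
conductance, keeping one assembly path for everything.

## Postprocessing conventions

The axial profile is interpolated along $r = 0$ from the distal nerve face
to the hyaloid plane. The TLPG is the lamina cribrosa face-to-face drop on
the axis divided by 0.38 mm. The *laminar fraction* needs a denominator
convention: here it is the drop from the globe centre (mid-vitreous) to the
nerve 4 mm behind the lamina — the published reporting points — giving
≈0.84 for the normal eye against the 0.82/0.85 reported from model and dog
data. "Centreline" velocities are sampled on elements touching the axis;
"periphery" at 95 % of the disc radius (the source reports a 3.3 %
centreline-periphery difference without defining the radius).

Two safety factors against axonal-transport failure are computed:
30 mmHg/mm (the acute axoplasmic-interruption threshold in peripheral
nerve) divided by the predicted TLPG, and 0.6 µm/s (the time-weighted mean
retrograde fast-transport speed) divided by the true fluid velocity in the
lamina; the mean dynein velocity relative to the membrane is
$0.6 - v_t$ µm/s and stalls at zero. Both thresholds are configuration
constants, not literals, since both are literature-derived with appreciable
uncertainty. The drag relation $F_D = f\,v_r$ is provided as the trivial
product with a user-supplied friction factor; no friction model is fitted.

## Calibration workflows

* `calibrate_production()`: secant iteration on the inflow until the probe
  IOP matches a target (15 mmHg for the normal eye → 6.14 µL/min).
* `calibrate_onh_conductivities()`: with the nerve surface temporarily held
  at 5 mmHg (penalty Robin), Nelder–Mead in log-space fits the prelaminar /
  laminar / retrolaminar conductivities to target layer-drop fractions of
  the axial profile. The published depth profiles constrain three layer
  drops, so three fractions (not only the 85 % laminar share) are used as
  targets — the package's resolution of an otherwise underdetermined
  two-target fit. A validation mode instead checks that the shipped triple
  keeps the laminar fraction in 0.80–0.88. Parameter-recovery from ×3
  perturbed starts returns the triple within ×1.1.
* `calibrate_pial_conductivity()`: bracketed root-find on $h_{ON}$ so the
  nerve pressure is ≈4 mmHg when $p_{CSF} = 0$; the shipped value
  $1.5\times10^{-11}$ then yields ≈3.8 mmHg retrolaminar pressure at zero
  CSF pressure (reported: 3.5; measured in dogs: 3.7 ± 0.2).

## Scenarios

Scenarios are pure parameter transformations (`scenario()` objects) —
applying one never mutates the baseline. The library covers: supine posture
($p_{back}$ 0→3, $p_{CSF}$ 3→9 mmHg); the nocturnal eye (production to 65 %
of the 5.78 µL/min daytime rate, $C^{SL}_{ap}$ 0.5→0.325, $\alpha$
0.075→0.10 — the production change is implemented as the 65 % factor, which
agrees with the alternative "−2 µL/min" phrasing to 0.03 µL/min);
normal-tension glaucoma ($\alpha = 0.10$ with $p_{CSF}$ −4 or −7 mmHg);
silicone-oil tamponade (RPE conductivity scaled by the uncovered retinal
fraction, with the fill-to-coverage map interpolated piecewise-linearly
between the four measured points and extended to (0,0) and (100,100));
and Schwartz–Matsuo syndrome (anterior conductivity reduced to 0.148 or
0.12; the variant with production +4.5 % is an optional argument, not a
default). `sensitivity_scan()` and `outflow_split_scan()` reproduce the
one-at-a-time sensitivity table (the backpressure row is stepped by 10 % of
15 mmHg, since its baseline of zero admits no relative step) and the
outflow-split table; `sequential_resistance_study()` replays the model
build-up from the uniform-conductivity 0D-equivalent state.

On the nocturnal facility bookkeeping: the quoted facility reduction
0.233→0.185 at 19 mmHg follows from $C^{SL} = 0.5$ with $\alpha$ 0.075→0.10,
while the scenario also reduces $C^{SL}_{ap}$ to 0.325; the order of
operations in that bookkeeping is ambiguous in the source, so
`tonographic_facility()` simply exposes both computations. Similarly, the
nocturnal upright TLPG is quoted both as 16.6 and 13.4 mmHg/mm in different
places of the source; the Results value (16.6) is taken as authoritative.

## What the model does and does not capture

The model is rigid (no poroelastic deformation), steady (no circadian
dynamics), isotropic, and its oil-tamponade scenario only rescales the RPE
outflow area — no oil-interface physics. The geometry reconstruction means
absolute pressures in the nerve carry a few tenths of a mmHg of geometric
uncertainty (the acceptance tolerances of ±10 %, and ±0.5 mmHg on
pressures, reflect that). One internal tension in the source record is
worth noting: its own pCSF = 3 solution implies, by linear extrapolation of
the identical resistance network, a retrolaminar pressure of ≈4.3 mmHg at
zero CSF pressure, while 3.5 mmHg is printed for the calibration step; this
package reports what its network computes (≈3.8 mmHg), which is consistent
with the 4.0 mmHg mean-nerve-pressure anchor actually used to fit
$h_{ON}$.

Problem sizes: the default mesh is ≈5,900 elements (solves in well under a
second); the test-suite fixtures use a ≈950-element coarse mesh for the
iterative calibration experiments and 12–20-interval annulus/shell meshes
for the analytic comparisons.

## A worked run

```{r, eval = FALSE}
mesh <- generate_mesh(eye_geometry())
params <- calibrate_production(default_normal_eye(), 15, mesh)
sol <- solve_eye(params, mesh)
summarise_solution(sol)
autoplot(extract_axial_profile(sol))
```
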