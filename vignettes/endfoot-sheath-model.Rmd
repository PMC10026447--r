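---
title: "Modelling the astrocyte endfoot sheath: geometry, permeability and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the astrocyte endfoot sheath: geometry, permeability and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endfeet)
```

## The model

Astrocyte endfoot processes cover brain microvessels in a mosaic of
cells separated by narrow fluid-filled gaps. `endfeet` treats this mosaic
as a random tessellation of the vessel surface and propagates the
resulting gap geometry into membrane transport coefficients.

The sheath surface of a vessel with outer radius $r_o$ is unrolled into a
rectangle of width $2\pi r_o$ and height $L$, periodic in **both**
directions. Circumferential periodicity is physically required — the
pattern must wrap consistently around the vessel. Axial periodicity is a
modelling choice: it removes boundary effects from edge statistics, so
every bisector edge is counted exactly once, shared by exactly two cells.

Endfoot centres are drawn by **sequential hard-core sampling**: uniform
proposals on the torus are rejected when closer than
$0.3\sqrt{1/\varrho}$ (toroidal metric) to an accepted point, where
$\varrho = 1/A$ is the target density for mean cell area $A$. The hard
core suppresses vanishingly small endfeet while perturbing large-scale
statistics only mildly; the proposal loop aborts after $10^4 \times n$
attempts (at the default hard-core radius the packing fraction is ~7%,
far from jamming, so this never triggers in practice). The Voronoi
tessellation of the pattern is then built exactly: each cell is clipped
from half-planes against the 3×3 ghost-replicated generator set,
processed in order of increasing distance with a security-radius
stopping rule. Cell areas conserve the domain area to ~$10^{-15}$
relative error and a planar Voronoi library on the replicated pattern
reproduces the per-cell areas, which the test suite uses as an
independent oracle. Two further analytic anchors guard the geometry: the
Poisson limit (hard core disabled), whose edge-length intensity is
exactly $2\sqrt{\lambda}$, and the regular triangular lattice, whose
hexagonal cells give $\phi_g = d_g\sqrt{2\sqrt{3}/A}$ in closed form.

With gap width $d_g$ the tessellation yields the **gap area fraction**
$\phi_g = d_g\, l_\Sigma/(2\pi r_o L)$, the cross-sectional **gaps/ring**
$= l^\perp_\Sigma/L$ and the reduced fraction
$\phi^\perp_g = d_g\, l^\perp_\Sigma/(2\pi r_o L)$, where $l_\Sigma$ is
total edge length and $l^\perp_\Sigma$ the total axial projection of the
edges. For isotropic patterns $l^\perp_\Sigma/l_\Sigma \to 2/\pi$ (the
mean $|\cos\theta|$ of uniformly oriented segments), which is why
cross-section-based gap estimates systematically understate the true gap
fraction by ~36%. The finite gap width is *not* subtracted from cell
areas: at the sub-percent gap fractions of interest the correction is
negligible, and `sheath_metrics()` refuses gap widths large enough
(estimated $\phi_g > 5\%$) to break that assumption.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `d_g` | 20 | nm | inter-endfoot gap width (EM measurements in capillaries) |
| `h_ES` | from $r_v$ | µm | sheath thickness, $\max(1, 1 + 0.15(r_v-3))$ |
| `l_g` | $1.5\,h_{ES}$ | µm | tortuous gap path length (capillary ratio 0.45/0.3 µm, extrapolated linearly) |
| `alpha` | 1 | — | hindrance factor; Renkin polynomial for large solutes |
| `mu` | $0.7\times10^{-3}$ | Pa s | water viscosity at 37 °C (a preset $0.69\times10^{-3}$ matches the coefficient-sweep figures) |
| `rho` | $1/A$ | µm⁻² | generator density |
| `L` | $500A/(2\pi r_o)$ | µm | axial extent (see below) |

The axial length $L$ is not physically constrained (the metrics are
intensive), so it is chosen to put ~500 cells in each realization. This
keeps the per-realization Monte-Carlo error of $\phi_g$ around the
percent level while keeping a 200-realization ensemble to seconds of
compute. `surface_domain()` exposes both `L` and the cell-count target.

All lengths enter in µm/nm and are converted to SI exactly once, at the
formula boundary: $L_p = \phi_g d_g^2/(12\mu l_g)$ (m Pa⁻¹ s⁻¹) and
$C_M = \alpha\phi_g/l_g$ (m⁻¹). The ratio $C_M/L_p = 12\mu\alpha/d_g^2$
is constant by construction — with a uniform gap width, differences in
permeability between vessels arise from $\phi_g$, not from gap anatomy.

The gap Péclet number is exposed as
$\mathrm{Pe}_g = \Delta p\, d_g^2/(12\mu\alpha D)$. With the default
parameters and a generous 100 Pa trans-sheath pressure drop it evaluates
to $4.8\times10^{-3}$; a bound of ~0.003 is sometimes quoted for this
configuration, which the formula with these exact defaults does not
quite reproduce — the package reports the formula value and leaves the
inputs alone. Either way transport through the gaps is firmly
diffusion-dominated.

## Radius–area relations and their calibration

Mean endfoot area grows with vessel caliber: quadratically on the
arterial side, linearly on the venous side, with both branches agreeing
at capillary caliber where the distinction disappears. The packaged
coefficients are anchored to the corrected reference areas
(2.9 µm, 50 µm²), (15 µm, 490 µm²) arterial and (2.9, 50), (15, 110)
venous, giving $A^A(r) = 2.032r^2 + 32.91$ and
$A^V(r) = 4.959r + 35.62$. The exact regression coefficients behind the
published diameter–area data are not recoverable from text, so these
anchored surrogates are the package default and every coefficient is
overridable for users with their own digitization.

Sweeping radii with these relations, simulating the tessellation at each
radius and fitting $\phi_g(r_o) = c_1 e^{-c_2 r_o} + c_3$ yields the
packaged exponential calibrations
($0.00704\,e^{-0.1668 r_o}+0.00124$ arterial on [2.5, 15] µm;
$0.00468\,e^{-0.0716 r_o}+0.00226$ venous on [2.5, 20] µm). The test
suite closes this loop: refitting from fresh simulations reproduces the
packaged curves within 10% pointwise over their ranges. The refit uses
10 radii × 20 realizations per vessel kind — enough for coefficient
stability at a few seconds' cost.

## Projection correction

Published endfoot areas from 2D micrographs underestimate true surface
areas: orthographic projection foreshortens the curved surface, and the
far half of the vessel is hidden. The package emulates the measurement
geometrically: cells are mapped to the cylinder, the visible arc is
$\theta\in(-\pi/2, \pi/2)$, a cell is measured when its **generator**
lies on the visible arc, and its measured area is the image-plane area
($x = r_o\sin\theta$, $y = z$) of its visible clipped part. The original
measurement protocol's exact inclusion and clipping rules are not
documented in available sources, so this reconstruction is deliberately
explicit and every element is a switch in `projection_convention()`; the
capillary check (true 50 µm² measuring near 25 µm²) is therefore a soft,
convention-dependent property rather than an exact identity. In the
flat-surface limit the convention measures cells at the $2/\pi$
foreshortening ratio, an analytic anchor the tests assert.

`build_area_correction()` tabulates the measured mean per $(r_o,
A_{true})$ node (isotonic post-processing absorbs Monte-Carlo
monotonicity violations; genuine violations raise an error) and
`correct_measured_area()` inverts the table by monotone interpolation in
area and linear interpolation in radius. Corrections are tabulated
rather than closed-form because wrapping makes the mapping
radius-dependent.

## Microvascular networks

The network module maps the coefficients onto a vessel graph. The
bundled generator builds a **synthetic** cortical block — labelled as
such in its metadata — with penetrating arterioles and venules (lumen
radii tapering from ~10–12 µm to 3 µm over an 1100 µm depth) coupled
into a jittered, randomly pruned capillary lattice (radii 1.5–2.9 µm,
spacing 75 µm). The spacing targets the observed cortical
surface-to-volume ratio of order $10^4\,$m²/m³ and yields a
capillary-dominated surface (>5× the larger vessels), both asserted in
tests. It does **not** reproduce real network topology: no dive/ascend
asymmetry, no tortuous polylines, no measured radius distributions —
conclusions about absolute network totals belong to real datasets, and a
CSV/JSON loader (`read_network()`) accepts them.

Pressures solve the nodal Poiseuille system with conductance
$g = \pi r_v^4/(8\mu_{app} l_v)$; the apparent viscosity follows the
empirical in-vivo diameter/hematocrit law with tube diameters rescaled
by $(V_{ref}/55\,\mathrm{fL})^{1/3}$ to transfer the human red-blood-cell
calibration to mouse cells (reference volume configurable, default
92 fL). At zero hematocrit the in-vivo law retains its endothelial
surface-layer factor $(D/(D-1.1))^2$; the in-vitro variant, which tends
to exactly 1, and a constant-viscosity mode are provided for comparison
and for analytically checkable tests. Boundary conditions on the
synthetic block are 8000 Pa at arteriole inlets and 2000 Pa at venule
outlets — classification depends only on the pressure ordering, not on
absolute values. Segments are arterial when their pressure strictly
exceeds the mean pressure of small segments ($r_v \le 4.5$ µm), venous
otherwise (ties fall to venous); capillaries ($r_v < 3$ µm) form the
reporting category C. Arterial segments take the arterial $\phi_g(r_o)$
fit, venous segments the venous one, capillaries the fit of their
pressure label.

The lumen-to-sheath map $r_o(r_v)$ is deliberately discontinuous at
$r_v = 3$ µm (a smooth-muscle/pericyte layer appears on larger vessels);
no smoothing is applied. $h_{ES}$ is clamped at 1 µm below capillary
caliber so the linear relation cannot drop under the observed in-vivo
range. Because penetrating radii reach $r_o$ values near the upper end
of the exponential fit ranges, network evaluation allows extrapolation;
the exponential tends to its constant $c_3$ and stays well-behaved.

Depth aggregation uses 6 layers (200 µm each, 100 µm for the deepest),
assigning segments by midpoint depth; per layer and category the module
reports $\sum S$, filtration capacity $\sum S L_p$, diffusion capacity
$\sum S C_M$ and surface-weighted means. Layer capacities sum exactly to
network totals (asserted), and the outer volume fraction always exceeds
the lumen fraction since $r_o > r_v$.

## Numerical choices

* Half-plane clipping uses a signed-distance tolerance of
  $10^{-12}\times$ the domain scale; degenerate (lattice) inputs produce
  exact vertices where three bisectors meet, and spurious edges shorter
  than $10^{-9}\times$ the mean spacing are dropped.
* Edge deduplication keys on the sorted cell pair plus the edge midpoint
  reduced to the fundamental domain, quantized at $10^{-7}$ of the
  domain scale.
* Determinism: all samplers run on R's RNG under `set.seed()`;
  per-realization seeds are `seed + realization - 1`, so ensembles are
  reproducible and extendable.
* Projected cell edges are subdivided at 0.02 rad before the $\sin$
  mapping, keeping the curvature error of measured areas far below
  Monte-Carlo noise.
* The exponential refit runs Levenberg–Marquardt with starts derived
  from the sample range and positivity bounds; noiseless inputs recover
  coefficients to 4 significant digits.
* The linear nodal system is solved sparsely; interior mass imbalance is
  reported and stays near machine precision (asserted below $10^{-8}$).

## Limitations

The model assumes complete, static endfoot coverage with a uniform gap
width; gap-junction constrictions, dynamic volume changes and partial
coverage all modulate real permeability and enter here only through
$d_g$, $\alpha$ or $\phi_g$ scalings ($L_p \propto d_g^3$,
$C_M \propto d_g$, so gap-width uncertainty dominates). The Voronoi
construction is geometric, not a cell-growth simulation, and in-plane
endfoot overlap affects only the path length $l_g$. Passing the packaged
tests demonstrates internal consistency and agreement with the analytic
oracles and calibration anchors — not fidelity to any particular animal:
the synthetic network is a structural stand-in, and absolute
network-level totals should be recomputed on measured vessel graphs.
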