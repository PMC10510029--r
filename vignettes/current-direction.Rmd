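---
title: "Quantifying tDCS current direction at the cortical surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tDCS current direction at the cortical surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcsdir)
```

## The model

Transcranial direct current stimulation (tDCS) polarises cortical neurons
according to the component of the induced electric field along the
somatodendritic axis of pyramidal neurons. Because that axis points toward
the cortical surface, the angle between the *inner* surface normal
$\vec{S}$ of a grey-matter mesh and the local field vector $\vec{EF}$ is a
geometric proxy for the neural effect of the current:

$$\theta_{SEF} = \arccos\!\left(\frac{\vec{S}\cdot\vec{EF}}
{\lVert\vec{S}\rVert\,\lVert\vec{EF}\rVert}\right),$$

with the convention that $0^\circ$ is absolute radial-inward current (into
the cortex, toward white matter), $90^\circ$ tangential, and $180^\circ$
radial-outward. Because cortex is folded, one montage produces radically
different $\theta_{SEF}$ on a sulcal bank and on the neighbouring gyral
crown; the pipeline quantifies this per vertex and summarises it in
bank/crown regions of interest (ROIs) of the hand-knob region of the
primary motor (M1) and somatosensory (S1) cortices.

The per-subject chain is:

1. **Mid-grey surface** — pial and white-matter meshes sharing topology are
   averaged vertex-wise (`build_midsurface()`). Sampling the field on this
   mid surface keeps lookups inside grey matter rather than adjacent CSF or
   white matter. World offsets baked into surface files (e.g. a
   centre-voxel-to-RAS shift) are removed with `translate_surface()`.
2. **Inner normals** — per-vertex normals are the normalized area-weighted
   average of incident face normals, negated so they point toward white
   matter (`compute_inner_normals()`).
3. **ROIs** — each seed coordinate snaps to its nearest vertex
   (`nearest_vertex()`); the ROI is the $k$-ring neighbourhood on the
   face-edge graph (default $k = 5$, the centre counting as ring 0), with
   faces wholly inside the vertex set (`build_roi()`). Vertices claimed by
   both the bank and the crown ROI of a gyrus are kept by the ROI whose
   centre is closer along the mesh (`resolve_overlaps()`).
4. **Field sampling** — the volumetric field image is sampled at each
   vertex by nearest voxel centre in world millimetres, no interpolation
   (`sample_nearest()`).
5. **Angles and summaries** — `compute_direction()`, `summarize_roi()`,
   and across subjects `run_cohort()` / `summarize_cohort()`.

An electrode-location proxy $\theta_{ELM}$ (`proxy_angle()`) replaces the
field model with the unit anode-to-cathode vector, compared against either
the mean inner normal of the target ROI (`mean_roi_normal()`) or the
direction orthogonal to the motor strip (`motor_strip_target()`). When
electrodes flank the target, this proxy closely tracks the model-based
angle — `correlate_proxy()` quantifies that agreement.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| ring depth `k` | 5 | hops | ROI radius of the bank/crown patches |
| conductivity `sigma` | 0.276 | S/m | grey-matter conductivity used by the field stand-in |
| current | 2 | mA | standard tDCS intensity |
| electrode radius / height | 17 / 2 | mm | disc electrode geometry (informational) |
| classification edges | 45 / 135 | degrees | presentational three-way map (inward / tangential / outward) |
| `exclusion_radius` | 2 | voxels | zero out singular voxels next to point sources |

"Extending by five vertices" is interpreted topologically (5 edge hops),
not metrically (5 mm): the construction counts vertices, and ring growth on
mesh connectivity is what a k-nearest-neighbour/adjacency implementation
operates on. Geodesic distances used for overlap resolution are graph
geodesics (shortest edge paths weighted by Euclidean edge length), not
exact polyhedral geodesics; at ROI scale the difference is far below the
inter-vertex spacing, and the graph form is directly checkable against an
exhaustive path-enumeration oracle.

## The synthetic cohort

Real inputs for this analysis are MRI-derived surface reconstructions and
finite-element field solutions. The generator replaces them with a
desk-scale stand-in whose every quantity has a closed form:

* **Geometry** — a folded sheet $z = A\sin(2\pi x/\lambda + \phi)$ with
  analytic inner normals
  $\propto (A\,\tfrac{2\pi}{\lambda}\cos(2\pi x/\lambda+\phi),\,0,\,-1)$.
  Defaults: $A = 15$ mm, $\lambda = 60$ mm, $\phi = -\pi/2$, grid
  $x \in [-45, 45]$, $y \in [-15, 15]$ mm at 1 mm spacing, thickness
  2.5 mm. With this phase the "central sulcus" trough lies at $x = 0$,
  banks (maximal slope, $\approx 57^\circ$ from vertical) at
  $x = \mp 15$ (M1-like / S1-like) and crowns at $x = \mp 30$. The grid
  boundary columns sit on inflection lines of the fold, where the one-sided
  normal stencils of boundary vertices are second-order accurate; this
  keeps the worst-case mesh-normal error below $2^\circ$ at 1 mm spacing
  while leaving a genuine first-order boundary term (at the crown/trough
  rows) whose halving under refinement the tests verify.
* **Fields** — a point current source/sink pair in an infinite homogeneous
  conductor, $E(r) = \frac{I}{4\pi\sigma}\left(\frac{r-r_a}{|r-r_a|^3} -
  \frac{r-r_c}{|r-r_c|^3}\right)$, evaluated at voxel centres
  (`make_point_pair_field()`), plus exact uniform fields
  (`make_uniform_field()`). The PA-like montage places the pair at
  $(\pm 75, 0, 10)$ mm so current crosses the sulcus with only a few
  degrees of vertical tilt at the banks; the ML-like pair sits at
  $(0, \pm 75, 10)$ parallel to the sulcus; the conventional-like anode
  sits 20 mm above the subject's M1 crown with a distant frontal cathode.
  In this frame the fold axis is $x$, so the across-sulcus
  ("posterior-to-anterior") direction is $-x$ and subjects carry
  `anterior_axis = c(-1, 0, 0)` for the motor-strip construction.
* **Cohort variability** — per subject, normal jitter on the fold phase
  (sd 0.2 rad) and amplitude (sd 1.5 mm, about 10% of $A$), 20 subjects by
  default, fully reproducible from one seed. Seeds and the conventional
  anode track each subject's own fold, mirroring per-subject anatomical
  placement.

What this emulates: bank/crown geometry with known normals, realistic
field magnitudes (a few tenths of a V/m at the cortex), montage-dependent
direction patterns, and inter-subject variation that drives both
$\theta_{SEF}$ and $\theta_{ELM}$. What it does not: skull/CSF conductivity
contrasts (the homogeneous conductor has no current shunting, so
*intensity* ordering across montages is not faithful — the conventional-like
montage here delivers the strongest field at the crown rather than the
weakest), secondary folds, curvature along the sulcus, and hemispheric
asymmetry. Passing tests therefore validate the computational pipeline and
its geometric logic, not the physiological magnitudes of any real montage.
Because the sheet is invariant along $y$, the ML-like electrode axis is
exactly orthogonal to every bank normal: $\theta_{ELM}$ for ML is a
constant $90^\circ$ across subjects, and the proxy-vs-model correlation is
evaluated on the PA montage (and on PA + ML pooled), where the variance is
genuine.

## Numerical choices

* Angles are averaged arithmetically on degrees in $[0, 180]$; the
  quantity is an unsigned separation angle, so circular statistics are not
  needed. Cosines are clamped to $[-1, 1]$ before `acos`.
* Vertices sampling an exactly zero field vector (source exclusion zones)
  get a missing angle and are excluded from ROI means, never mapped to an
  arbitrary angle.
* Nearest-voxel search runs in a provably sufficient local index
  neighbourhood derived from the operator norm of the inverse affine, so
  it is exact for rotated and anisotropic voxel grids; ties are broken by
  row-major voxel order. Vertices outside the lattice (±half a voxel) are
  an error, never clamped — they indicate a coordinate-convention bug.
* Nearest-vertex ties go to the smallest index; equidistant ROI-overlap
  ties go to the bank-labelled ROI of the pair (otherwise to the
  lexicographically smaller label).
* Degenerate (zero-area) faces are skipped in normal averaging; a vertex
  with no valid incident face is a hard error.
* Overlap resolution is performed within gyrus pairs only (M1 bank vs M1
  crown; S1 bank vs S1 crown), not across the sulcus.
* The pial/white correspondence assumption is enforced, not repaired: no
  co-registration is attempted when topologies differ.
* Mean and standard error in cohort summaries use the sample ($n-1$)
  standard deviation; SE is reported missing for $n = 1$.
* OFF and PLY surfaces are written as float64 (round trips exact to
  1e-6 mm); GIfTI and FreeSurfer binary store float32 by format
  definition, so their round trips are exact to float32 resolution only.

## Problem sizes

The default synthetic subject has 2,821 vertices and 5,400 faces per
surface and a $95 \times 35 \times 37$ voxel field volume at 1 mm — sizes
chosen so a 20-subject, 3-montage cohort runs in well under a minute on a
single core while keeping several vertices per ROI ring and several voxels
per fold. Test fixtures use coarser grids of the same family.

## Limitations

* The inner-normal orientation is derived from face winding; meshes wound
  inconsistently will silently flip angles (synthetic meshes and all
  supported readers use outward winding).
* Linear mixed-effects modelling and post-hoc contrasts over the cohort
  table are deliberately out of scope; the tidy per-subject CSV is the
  interface to external statistics tools.
* No scalp-mesh projection or automated 10-10 electrode positioning:
  electrode centres are inputs.
* The plane in which "orthogonal to the motor strip" is resolved is a
  Gram-Schmidt projection against a configurable world anterior axis; on
  strongly tilted strips a surface-tangent construction could differ.
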