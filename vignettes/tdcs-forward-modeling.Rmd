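---
title: "Volume-conductor forward modeling of tDCS montages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-conductor forward modeling of tDCS montages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(fieldlab)
```

## The model

Transcranial direct current stimulation (tDCS) injects a weak direct
current (1--2 mA) through scalp electrodes. At DC the head behaves as a
passive volume conductor: the potential $V$ obeys the continuity
equation

$$\nabla \cdot (\sigma \nabla V) = 0,$$

with tissue conductivity $\sigma$ (S/m), electric field
$\mathbf{E} = -\nabla V$ (V/m) and current density
$\mathbf{J} = \sigma \mathbf{E}$ (A/m²). Boundary conditions: the anode
assembly injects a total current $I$ = 1 mA, the cathode assembly is
ground, and every other outer surface (skin against air) is electrically
insulated.

The conductivities are the standard isotropic values for this class of
model:

| tissue | $\sigma$ (S/m) |
|---|---|
| skin | 0.465 |
| fat | 0.025 |
| skull | 0.01 |
| CSF | 1.65 |
| gray matter | 0.276 |
| white matter | 0.126 |
| air | $10^{-15}$ |
| saline sponge / gel | 1.4 |
| electrode metal | $5.99 \times 10^7$ |

CSF is by far the most conductive tissue and acts as a preferential
current pathway; the skull is the dominant resistive barrier. A note on
conventions: with these numbers a field of 0.18 V/m in white-matter-like
tissue (0.126 S/m) carries $0.18 \times 0.126 = 0.0227$ A/m² — the
package computes $J = \sigma E$, the form consistent with Ohm's law
(the reciprocal form $J = E/\sigma$ that sometimes appears in print does
not reproduce such value pairs).

## The synthetic head phantom

Individualized models segment a 1 mm³ T1 MRI. This package instead
*emulates* such a segmentation with a concentric-sphere phantom
(`build_phantom()`): shells of white matter, gray matter, CSF, skull,
fat and skin with default outer radii 58, 72, 76, 83, 85 and 92 mm.
These radii follow published spherical-head conventions; they are a
design choice, not a reproduction of any individual anatomy. The voxel
grid is isotropic (default 1 mm; 2 mm is the working resolution for
desk-scale runs) with the origin at the sphere centre, $+z$ the vertex,
$+y$ the nasion and $+x$ the right preauricular point.

Nine regions of interest stand in for the structures usually analysed
in montage comparisons (`label_rois()`): PFC (anterior gray cap), M1
(gray cap about the C3 direction), S1 (cap immediately posterior), the
occipital cortex (posterior cap), left/right insula (mid-depth lateral
gray patches), cingulate (superior parasagittal gray slab), thalamus
(central ellipsoid) and brainstem (inferior axial cylinder). They are
purely geometric: angular caps and primitive solids assigned in a fixed
priority order, which makes them pairwise disjoint by construction.
Passing tests on this phantom therefore demonstrates the physics and
the pipeline, *not* anatomical accuracy — there is no gyral folding, no
anisotropy, and the ROIs are convex stand-ins.

An optional midsagittal CSF cylinder (`medial_csf_conduit`) emulates a
highly conductive intracerebral vessel running from under the vertex
toward the centre, the mechanism usually invoked for deep current
delivery with a vertex--occiput montage. It is off by default. An
optional smooth random perturbation of the layer boundaries
(`perturb_amp_mm`, seeded, default 0) breaks perfect sphericity when
robustness to geometry is of interest.

## Electrodes and montages

Scalp positions come from the proportional-arc construction of the
10-10 system (`standard_position()`): the nasion--inion midline arc and
the ear-to-ear arc through Cz are subdivided in 10%/20% steps, the
outer 10% circle carries the Fp1/Fp2...O1/O2 ring, and intermediate
rows (F, FC, CP, P, AF, PO) subdivide the circle through their two
outer-ring ends and their midline point. By construction Cz--C3 = 36°,
Cz--T7 = 72°, and left/right pairs mirror exactly.

`stamp_electrode()` places a scalp-conforming sponge (5 mm, σ = 1.4)
topped by metal (2 mm) for 50 × 70 mm pads, or a 2 mm gel layer under a
12 mm disk for HD electrodes. Layer thicknesses are quantized to whole
voxels (minimum one layer) so that coarse grids keep the
skin--sponge--metal sandwich intact; the lateral footprint is measured
along the assembly's own surface so a pad keeps its 50 × 70 mm
cross-section. Pad orientation is "vertical" (70 mm axis along the
local meridian) or "horizontal" (along the local parallel); at the
vertex, where the meridian degenerates, the nasion axis takes its
place, so a "horizontal" pad at Cz runs ear to ear.

The five montages of `get_montage()` — M1-SO, DLPFC (F3--F4), Cz--Oz,
HD-4x1 (anode C3, cathodes Cz/F3/T7/P3) and HD-2x2 (anodes C3/C5,
cathodes FC3/FC5) — all inject 1 mA. The 4×1 cathode ring is derived
from the named 10-10 labels, which on this 92 mm head gives an arc
radius of ≈57 mm; published descriptions sometimes quote ≈75 mm for an
adult head, a difference that comes entirely from head size and label
spacing, so the labels are treated as authoritative.

## Discretization and solver

The solver (`assemble_system()`, `solve_potential()`) uses a 7-point
finite-volume stencil on the voxel grid. The face conductance between
neighbouring conductive voxels is the harmonic mean of their
conductivities times face-area/spacing; air voxels are excluded from
the domain entirely, which realises the insulated boundary with far
better conditioning than a $10^{-15}$ S/m material would. Electrode
metal voxels are Dirichlet nodes — at $5.99\times10^7$ S/m the metal is
equipotential, and the harmonic mean then reduces to the half-cell
conductance of the tissue side of the contact. The anodes are held at a
provisional 1 V, the cathodes at 0 V, and the solution is rescaled so
the integrated anode current equals the requested total — exact by
linearity, and it reproduces the "1 mA total current" condition without
prescribing how the current splits among multiple anodes or cathodes
(the split emerges from the equipotential condition; for HD-4x1 each of
the four cathodes draws a share set by its geometry).

The symmetric positive-definite system is solved by Jacobi-preconditioned
conjugate gradients to a relative residual of $10^{-8}$ (cap
$50\,n^{1/3}$ iterations), which is fully deterministic: identical
configurations give byte-identical reports. A 2 mm head (~0.4 M
unknowns) solves in ~700 iterations / ~10 s on one core. E is obtained
by central differences (one-sided against air), J by $\sigma E$
voxelwise.

## Peaks and focality

Voxel grids produce discretization spikes at electrode edges, so
"peak" values are reported twice (`peak_field()`): the absolute maximum
and a robust peak, the 99.9th percentile for masks of at least $10^4$
voxels (plain maximum for smaller masks). Focality
(`focality_volume()`) is the brain volume carrying at least half the
robust brain peak — volume at half maximum; fraction 0.5 is a
convention, and the quantity is monotone in the fraction. The montage
comparison (`compare_montages()`) adds a deep/superficial ratio: the
best deep-structure peak (thalamus, brainstem, cingulate, insulae) over
the best superficial peak (PFC, M1, S1, occipital).

## The analytic oracle

For validation the package carries an exact solution
(`fit_series()`, `oracle_potential()`): the potential of point-current
source/sink electrodes on an N-layer concentric sphere, expanded in
Legendre polynomials with per-layer radial terms
$A_l r^n + B_l r^{-(n+1)}$. Coefficients are fixed per degree by
regularity at the centre, continuity of $V$ and of $\sigma \partial_r V$
at each interface, and the surface flux condition with degree-$n$
source term $(2n+1)I/(4\pi R^2)$. The $n=0$ terms of source and sink
cancel, so the series runs over $n \ge 1$ and has zero mean on the
outer surface (the gauge). Radial basis functions are scaled per layer
so degrees up to several hundred neither overflow nor underflow;
default truncation is $N = 300$, converged to $<10^{-6}$ relative
against $N = 400$ in the tests. For a homogeneous sphere the series
matches the closed form
$\frac{I}{4\pi\sigma R}\left[\frac{2}{d} - 2 + \log\frac{2}{1-tx+d}\right]$
to machine precision.

`validate_solver()` builds the matching voxel phantom, stamps two 8 mm
disk electrodes, solves at 1 mA, and compares $|\mathbf{E}|$ on a
mid-gray-shell Fibonacci sample (2000 directions, excluding 20° caps
under each electrode where a disk and a point electrode legitimately
differ).

## Measured accuracy and a known limitation

On a homogeneous 92 mm sphere the solver agrees with the oracle to
≈0.9% median $|\mathbf{E}|$ error at 2 mm voxels (1.8% at 4 mm). On the
5-shell head with the full conductivity contrast, however, the median
error at 2 mm is ≈17% (≈42% at 4 mm), decreasing first order in voxel
size. The dominant mechanism is the staircase representation of *thin
high-contrast shells*: the 4 mm CSF layer is 165× more conductive than
the skull below it, and a voxelized shell both under-transports current
tangentially and leaks radially at its steps. The error is dominated by a nearly uniform over-estimate of
brain-field magnitude rather than by a distorted spatial pattern.
Reaching a few percent on this geometry needs sub-millimetre grids or
boundary-conforming meshes; local fixes to the face-conductance rule do
not remove a geometric error. Consequences
for use: *comparisons between montages* on the same phantom (peak
ratios, focality orderings) are robust, since the bias is common-mode;
*absolute* field magnitudes at 2 mm should be read as having a
10--20% model error on layered geometries, on top of the much larger
uncertainty introduced by real anatomy.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `voxel_size` | 2 mm (tests), 1 mm available | grid resolution |
| `total_current_mA` | 1 | injected current |
| `rel_tol` | 1e-8 | CG relative residual |
| percentile | 99.9 | robust peak order statistic |
| focality fraction | 0.5 | volume at half maximum |
| sponge / gel / metal | 5 / 2 / 2 mm | assembly layers |
| oracle degree $N$ | 300 | series truncation |

All randomness (boundary perturbation only) is seeded; the solver and
the pipeline are deterministic. Problem sizes used throughout the test
suite and the analysis scripts — a 2 mm phantom (105³ grid, ~0.4 M
unknowns) for the five-montage study and 2/4 mm spheres for validation
— were chosen as the coarsest grids that keep the montage comparison
stable; 1 mm runs use the same code paths.

## Degenerate inputs and numerical conventions

Non-increasing layer radii, a voxel size exceeding the thinnest layer,
unknown montage or ROI scheme names, unmapped label codes, overlapping
electrode footprints, and anode/cathode sets with no conductive path
between them all raise immediate, typed errors. An all-zero field gives
a zero focal volume (not an error). Ray/label ties at shell boundaries
resolve by `r <= radius` (a voxel centre exactly on a boundary belongs
to the inner tissue); electrode layers are stamped strictly outside the
scalp radius and never overwrite tissue.
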