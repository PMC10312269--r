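---
title: "Methods: how brainNetVis builds brain-network figures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how brainNetVis builds brain-network figures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A figure is a composition of three components, each optional and each
independently styled: an anatomical **template** volume, a **node** set and
an **edge** set. The only coupling rule is that edges require nodes. The
package treats all connectivity as *undirected*: adjacency matrices must be
symmetric (within 1e-9), self-loops are dropped with a warning (a
zero-length segment is unrenderable), and duplicate unordered pairs are
collapsed to their first occurrence. Directed or signed-edge semantics are
out of scope.

All geometry lives in world millimetres under the RAS convention (x grows
to the subject's right): volumes are reoriented to RAS on load, and the
voxel-to-world map is the NIfTI affine applied to 0-based, *continuous*
voxel indices. Centroids are computed in continuous index space and then
mapped — no rounding — so a label's centroid is exactly the affine image of
its mean voxel index. Nodes are identified internally by dense 0-based
integers; original graph vertex names survive as a `name` metadata column.

## Tunable parameters

| option | default | unit | why |
|---|---|---|---|
| `template_style` | `glass` | — | translucent outline keeps interior nodes/edges visible |
| template alphas | surface 1.0, glass 0.01, cloudy 0.05, filled 0.2 | opacity | per-style densities differ by orders of magnitude; chosen so each style reads as one translucent object |
| `template_level` | 0 | intensity | mask = grid > level; 0 suits skull-stripped images whose background is 0 |
| `template_voxelsize` | native | mm | block-aggregation performance lever for `filled`/dense styles |
| `template_segments`, `template_compactness` | 500, 0.05 | — | supervoxel count and spatial/intensity trade-off for `glass` |
| `node_scale` | (2, 6) | marker size | bounds of the affine size mapping when `node_size` names a column |
| `node_dimalpha`, `edge_dimalpha` | 0.15 | opacity | highlighting dims, never hides, the unselected remainder |
| `edge_threshold` | none | weight | edges with weight < threshold are removed **before** width scaling; `edge_thresholdabs` switches to \|weight\| (signed comparison is the least surprising default) |
| `node_sphereres` | 20 | grid steps | sphere tessellation fidelity only |
| `seed` | 42 | — | spring-layout determinism |

Color inference: a non-numeric column, or an integer-valued column with at
most 12 distinct values, is categorical (one palette color per category, a
legend entry each); anything else maps linearly between its observed min
and max onto a colormap, clamped at the ends against floating-point
overshoot. The rule is overridable per call (`kind =` in `mapColor()`).

## View geometry

The six anatomical letters carry fixed (azimuth, elevation) angles under
RAS: L (180, 0), R (0, 0), A (90, 0), P (−90, 0), S (−90, 90),
I (−90, −90). The letters themselves are standard; the numeric angles are
a package convention, documented and test-locked, since any consistent
assignment produces the named views. Rotation sequences interpolate both
angles linearly, the azimuth along the shorter arc; an exact 180°
separation (e.g. anterior→posterior) is a tie broken toward *decreasing*
azimuth, so `view = "AP", frames = 3` passes through (0, 0). Preset grids
are likewise fixed package conventions: `preset-3` = "LSR", `preset-4` =
"LPRA", `preset-6` = rows "LRA"/"PSI", `preset-9` adds a row of three
oblique angles. A lowercase `s` is allowed anywhere a letter is (including
multi-row lists) and yields a 2D spring-layout panel: a seeded
Fruchterman–Reingold embedding (igraph) that reuses the node colors, sizes
and highlight alphas computed once for the anatomical panels.

Rendering is orthographic: each panel projects world coordinates onto a
camera basis and draws back-to-front (painter's algorithm, faces sorted by
mean depth, Lambertian shading against a headlight). This is exact for
disjoint convex pieces and an approximation for interpenetrating
geometry — acceptable for the intended translucent styles, and fully
deterministic, which the export contract relies on.

## Numerical choices

**Isosurfaces.** `extractSurface()` meshes the 0.5 iso-level of the
binarized mask with a marching-tetrahedra tessellation (six tetrahedra per
cell sharing the main diagonal, linear interpolation along crossing edges).
Shared cell faces interpolate identically, so surfaces of zero-padded
solid masks are watertight; a convex solid yields one closed component
with Euler characteristic 2. Interpolating a *raw binary* field produces
45° staircase facets that overestimate curved areas by ~28%, so the mask
is first smoothed with a 3×3×3 Gaussian kernel, σ = 0.55 voxels. That
value balances two analytic anchors: the surface of a radius-10-voxel ball
lands within ~6% of 4πr², while a 10-voxel cube stays within ~7% of its
face area (smoothing chamfers edges, which penalizes small cubes — the
effect is a perimeter term that vanishes for larger solids). Masks too
small to survive smoothing fall back to the binary field; sub-kernel
features can still be blunted, and `smoothing = 0` disables the filter.

**Glass borders.** No SLIC implementation exists in the installed R
stack, so the package segments the masked volume itself: seeds on a
regular grid inside the mask, then a k-means-style refinement under
D² = d_intensity² + (compactness·d_spatial/S)², five iterations, entirely
deterministic. Adjacent segments whose mean normalized intensities differ
by less than `mergeTol = 0.02` are merged before border extraction, so
borders trace *intensity structure*: a uniform solid yields only its outer
shell (every border voxel within one voxel of the analytic surface), while
nested intensity regions keep their internal boundary. Border voxels use
6-connectivity, as does the `cloudy` surface-voxel definition — the
cheapest deterministic border rule, stated so tests can be exact.

**Downsampling.** `downsampleVolume()` aggregates whole voxel blocks:
block means for intensities (conserving the global mean when dimensions
divide evenly), modal labels for parcellations with background excluded
from the vote unless a block is all background (a mean would fabricate
labels). The output affine places each coarse voxel at the world centroid
of its block, preserving world extent within one output voxel. Upsampling
is refused.

**Hemispheres.** Left is world x ≤ 0, right is x ≥ 0; structures exactly
on the midline belong to *both* sides. The closed boundary is the only
deterministic convention that never silently loses midline structures, at
the cost of counting them twice in a left∪right union. Edges are kept only
when both endpoints survive — only within-hemisphere connections are
shown.

**Metadata attachment.** When extra per-node tables (`nodesDf`) are merged
onto parcellation- or atlas-derived nodes, row *k* attaches to the *k*-th
label in ascending integer-label order. Nothing in a bare table identifies
labels, so a fixed, reproducible convention is required; ascending order is
the one every centroid table already uses.

## The synthetic fixtures

`makeTemplate()` emulates a skull-stripped anatomical image as a smooth
ellipsoid: 64×64×64 grid of 2 mm voxels, semi-axes 45×55×40 mm (human-brain
scale, small enough for sub-second surface extraction), intensity 1 inside
with a linear falloff band of 10% of the normalized radius. Its mask volume
matches the closed-form ellipsoid volume within 10%. `makeParcellation()`
Voronoi-partitions the mask around uniformly drawn seed voxels;
`makeNetwork()` places nodes uniformly inside the ellipsoid and draws a
stochastic block model (3 communities, within-probability 0.3, between
0.05, uniform(0,1] weights) with `community`/`measure1`/`measure2`
metadata columns; `makeHighlightMatrix()` marks a random subset of existing
edges in a symmetric binary matrix, the shape network-based-statistics
tools emit. Every generator is a pure function of (config, seed).

What the fixtures deliberately do *not* emulate: cortical folding, tissue
contrast or intensity inhomogeneity, non-isotropic or oblique affines
beyond what the tests construct explicitly, and realistic connectome
statistics (small-worldness, hubs, distance-dependent wiring). Passing
tests therefore demonstrate the geometric and contractual behavior of the
pipeline — centroid math, panel grammar, aesthetic mapping, export
determinism — not that any particular real dataset renders legibly.

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances: 10–30-node networks, 10³–25³ voxel phantoms for geometry
oracles (50 random parcellations, 100 random adjacency matrices), and the
64³ fixture template for end-to-end renders. These sizes were chosen so
every oracle remains brute-forceable and the whole suite stays
interactive-fast; the code paths are size-independent.

## Known limitations

- Only volumetric NIfTI input; surface formats (GIFTI/CIFTI) are not
  supported.
- Static output only — no interactive rotation; multiple panels are the
  intended substitute.
- Undirected, sign-agnostic edges; no multigraphs, curved edges or
  arrowheads.
- Painter's-algorithm compositing can mis-order mutually intersecting
  opaque meshes.
- The remote template-repository adapter is an injected interface; the
  package itself never touches the network, and only the local directory
  resolver ships.
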