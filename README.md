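# brainNetVis

Multi-panel 3D visualization of brain networks in R.

Network neuroscience figures have to communicate two things at once: the
topology of a weighted graph and the anatomy it lives in. brainNetVis draws
weighted, undirected connectomes onto anatomical reference volumes as
publication-ready static figures. It is aimed at researchers who have a
connectivity matrix (or edge list), node locations (coordinates, an
integer-labeled parcellation, or an atlas descriptor), and optionally an
anatomical template, and who want a declarative, reproducible way to turn
those into multi-view 3D panels — without hand-placing any graphics.

## The model

A figure is the composition of three independently specifiable components:

- **Template** — a skull-stripped or segmented 3D NIfTI volume with its
  4×4 affine **A** mapping voxel indices *(i, j, k)* to world millimetres
  (RAS orientation). Rendered in one of four styles: `glass` (supervoxel
  segmentation + intensity-border voxels, low alpha), `surface`
  (iso-level 0.5 mesh of the binarized mask, marching-tetrahedra
  tessellation), `filled` (one point per voxel, with a `template_voxelsize`
  block-aggregation lever), or `cloudy` (background-adjacent surface
  voxels).
- **Nodes** — rows with world coordinates *(x, y, z)* plus arbitrary
  metadata columns. A parcellation defines node *r* at its label centroid
  `mean_{v ∈ r} A·v`. Styles: `circles`, `spheres`, `parcels`.
- **Edges** — an *N×N* symmetric adjacency matrix or an *(i, j, weight)*
  edge list; straight segments are drawn between node centroids, with
  optional weight thresholding and weight→width scaling.

Aesthetics are *column-driven*: `node_color = "community"` assigns one
palette color per category of that metadata column (integer-valued columns
with ≤ 12 distinct values are categorical; anything else maps linearly onto
a colormap), `node_size = "measure1"` maps a column affinely onto a size
range, and `highlight_edges` takes an NBS-style binary matrix and dims
everything outside the selected cluster. Legends are generated
automatically.

Views are a small grammar: anatomical letters (`L R A P S I`) with fixed
camera angles, multi-letter strings for panel rows (`"LSR"` → 3 panels),
lists of strings for grids (`c("LSR","AIP")` → 2×3), `"preset-N"` grids,
`view = "AP", frames = F` rotation sequences interpolated along the
shorter azimuth arc, a numeric `(azimuth, elevation)` tuple, and a
lowercase `"s"` for a seeded force-directed (Fruchterman–Reingold) spring
panel that reuses the anatomical panels' colors and sizes.

There is deliberately no default template: a reference volume is drawn only
when you name one, so nodes can never silently acquire the wrong space.

## Worked example

Everything below is generated — the synthetic fixture module ships with the
package, so no download is needed:

```r
library(brainNetVis)

cfg <- fixtureConfig(seed = 1)              # 64^3 grid, 2 mm voxels
net <- makeNetwork(30, fixtureConfig(nNodes = 30, seed = 1))
tpl <- makeTemplate(cfg)                    # ellipsoidal "brain"

fig <- plotBrainNetwork(
  template = tpl, nodes = net$nodes, edges = net$edges,
  template_style = "glass",
  node_color = "community",                 # categorical palette + legend
  node_size = "measure1",                   # affine size mapping + legend
  view = "LSR",                             # left / superior / right
  savename = "example.png")
fig
#> FigureResult: 3 panel(s)
#>   nodes: 30
#>   edges: 51
#>   template: synthetic
#>   legend: 2 block(s)
```

Three panels were drawn (one per view letter), 30 nodes colored by their 3
communities and sized by `measure1`, 51 edges, and a two-block legend
(community swatches, size key). `panels(fig)` returns the per-subplot
handles; `provenance(fig)` records the resolved options, element counts and
seeds.

Parcellation-based nodes work the same way:

```r
parc <- makeParcellation(tpl, nLabels = 12, seed = 1)
head(computeCentroids(parc), 3)
#>   node_id         x         y          z label
#> 1       0 -13.82069 -23.84879   3.997286     1
#> 2       1 -15.44905  20.59420  17.841472     2
#> 3       2  10.38532  22.09973 -22.920552     3
plotBrainNetwork(nodes = parc, node_style = "parcels", view = "S")
```

A command-line wrapper is installed at `inst/scripts/brainnetvis`:

```sh
Rscript inst/scripts/brainnetvis --nodes nodes.tsv --edges edges.tsv \
    --view LSR --node-color community --savename out.png
```

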