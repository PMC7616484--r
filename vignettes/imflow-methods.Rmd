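---
title: "imflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{imflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imflow)
```

This vignette explains the models and procedures implemented in `imflow`,
the assumptions behind them, the parameters that matter, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The workflow model

An analysis is an ordered, linear list of module invocations. Each module
reads named items from a per-job *workspace* and writes named items back,
either as new entries or as in-place updates (an updated image keeps its
identity and its image-level measurements; this avoids duplicating large
stacks). Items are 5D calibrated image stacks — axes (x, y, channel, z,
time), with singleton axes for absent dimensions — and object sets.
Workspaces never interact: batch processing creates one per input file,
runs them independently, and discards their contents after export.

Execution is *reactive*: a module is effectively enabled iff its user
flag is on and every named image/object input is produced by an
effectively enabled earlier module. Disabling one module therefore
disables exactly its dependent chain, and re-enabling restores it — the
computation is a pure function of the user flags, so it is monotone
(enabling a module can never disable another). Validation runs before
execution and rejects any input name that no earlier module can produce,
so unsatisfiable references are never discovered mid-run. Workflow
handling modules evaluate predicates over object-set counts or image
measurements and may terminate the run or skip forward to a labelled
module; jumps are forward-only, keeping execution single-pass.

Workflows serialize to a versioned JSON dialect (conventionally
`.wf.json`) with a fixed key order, making
serialize–deserialize–serialize round trips byte-identical. Every
exported workbook embeds this text verbatim in a "Configuration" sheet;
`recoverWorkflow()` turns it back into a runnable workflow. The module
registry is the extension point: any function registered under an id
becomes available to workflows by name.

## Coordinate stores

Object voxels are stored behind one access contract in three forms:

* **Pointlist** — an explicit, duplicate-free list of XYZ coordinates.
* **Quadtree** — per z-slice, a recursive subdivision of the
  power-of-two-padded slice into quadrants, stopping at uniform nodes.
* **Octree** — a single 3D subdivision into octants.

The padded area beyond the image extent is defined to be background and
is never emitted as coordinates; this makes subdivision well-defined for
arbitrary extents. Trees are *maximally merged* at all times — no
subdivided node has all-uniform children of equal state. Construction
guarantees this (a region whose foreground count equals its area, or
zero, becomes a leaf before any child is created; counts come from a
summed-area table, so each uniformity test is O(1)), and single-voxel
insertion re-merges affected ancestors on the way back up.

Memory cost is reported in abstract units: 3 per pointlist voxel
(x, y, z) and 4 per tree node (corner, size, state). Physical byte costs
are hardware- and implementation-dependent; the unit model is chosen to
preserve the orderings that matter — a single pixel in a 2^k square
costs the quadtree 4(4k+1) units against the pointlist's 3; a large
solid region collapses to few nodes and reverses the ordering. For
1-px-wide curves the tree pays a small constant factor per pixel
(roughly 4–7 units/px depending on how often adjacent pixels share a
2×2 block — diagonal steps never do), far from either extreme; the
fixture suite asserts same-order-of-magnitude costs there and strict
orderings for the single-pixel and solid morphologies. Creation-time
comparisons are deliberately not asserted anywhere: they measure the
host, not the data structure.

Spot and skeleton producers always emit pointlists (for those
morphologies it is always the most efficient choice); general object
identification exposes the store method as a user parameter.
Downstream indifference — identical measurements regardless of store —
is tested explicitly.

## Objects, relationships, calibration

Objects are purely spatial (XYZ); time is a property of the object
(its frame index), and cross-time structure is expressed only through
relationships. Parent–child links are one-to-many: a child holds at
most one parent per parent class, reassignment unlinks the previous
parent first, and both ends are updated atomically (objects are
reference objects, so links mutate in place). Partner links are
symmetric many-to-many. Ancestry over parent links must stay acyclic;
any assignment that would make an object its own ancestor — through any
chain of classes — is rejected. The package forbids this generally,
treating relationship graphs as a DAG per workspace.

Calibration (dx, dy, dz, frame interval, with unit names) travels on
images and object sets; modules that combine them require agreement and
fail hard on mismatch rather than silently mixing units. Measurements
are named numeric values; a missing measurement is NA in memory and an
empty cell on export, and measurement-based filters retain objects with
missing values by default (an explicit `missingPolicy = "remove"`
reverses this). Removing objects or whole sets severs every link into
the removed items, so no surviving object dangles.

## Image modules

**Thresholding** uses Otsu's method on a 256-bin histogram of min-max
scaled intensities, maximising between-class variance, globally or per
slice; foreground is strictly above the threshold, output values are
{0, 255}. Ties across an empty histogram gap are broken toward the
lowest cut. A constant image yields an all-background result with a
warning, not an error. **Hole filling** converts background components
not connected to the slice border into foreground, independently per
slice and timepoint (2D; 3D filling is a possible future flag).
**Outline overlays** colour each object's boundary pixels — foreground
voxels with at least one non-object 4-neighbour in-slice — using a
seeded shuffle of equally spaced hues, so the same seed reproduces the
same image. **TIFF I/O** writes multi-page TIFFs (channel-fastest page
order) plus a JSON sidecar carrying axis sizes, bit depth and
calibration; loading prefers the sidecar, falls back to TIFF resolution
tags, and otherwise defaults to 1 px units with a warning. Integer data
up to 16 bits round-trips exactly; non-integer data is quantised to 16
bits on save.

## Object modules

**Identification** labels connected foreground components per timepoint
with user-selected connectivity (4 or 8 in-plane; 6 or 26 volumetric),
implemented over the voxel adjacency graph; ids are sequential in scan
order, so results are deterministic. **Shape measurement** adds voxel
counts, pixel and calibrated areas/volumes (N·dx·dy, with dz for 3D),
centroids in both unit systems, and bounding boxes. A region confined
to one z-slice is reported as an area, a multi-slice region as a
volume.

**Tracking** links detections between consecutive frames by solving a
linear assignment problem over squared calibrated centroid distances.
Links beyond `maxDist` are inadmissible; every object also has a
non-link alternative costed at `altFactor` (default 1.05) times the
largest admissible cost in that frame pair, following the convention of
the cited linker family. The solver is a Jonker–Volgenant shortest
augmenting path implementation (exact, O(n³)); the suite cross-checks
it against exhaustive enumeration at small sizes. Chains of links
become Track objects — coordinate-less parents of their per-frame
detections; unlinked detections start new tracks, and gap closing,
splitting and merging are deliberately out of scope. Equal-cost
solutions are resolved deterministically because rows and columns are
ordered by object id. **Track motion** reports total path length,
Euclidean displacement, directionality (displacement ÷ path length, in
[0, 1]; the specific ratio definition is this package's declared
choice), mean velocity (path length ÷ elapsed time) and duration;
per-step speeds land on the child detections. Single-detection tracks
get path 0 and missing directionality/velocity rather than dividing by
zero.

**Skeleton analysis** thins the input per slice with the Zhang–Suen
algorithm, classifies skeleton pixels with more than two 8-neighbours
as junction pixels (adjacent junction pixels merge into one Junction
object — merging is our choice; keeping them separate would fragment
T-joints), groups the remaining pixels into Edge objects, and partners
an edge with a junction iff any pixel pair is 8-adjacent. Junction and
edge pixels partition the skeleton disjointly. Pruning removes exactly
the edges with one junction partner (open branches); isolated edges (0
partners) and junction-to-junction spans (2) survive.

## Export

Workbooks are written by a small built-in xlsx writer (ZIP container
with stored entries, inline-string SpreadsheetML) and contain: an image
sheet (one row per workspace per image with job metadata), one sheet
per object class (metadata, id, timepoint, measurements sorted by name,
parent ids per parent class, partner counts per partner class), an
optional per-image summary sheet (mean, min, max, sample sd with the
n−1 denominator, sum, count per object-set measurement; empty sets
report count 0 with missing statistics), and the Configuration sheet.
Missing values are empty cells, never 0 or "NaN". Column and sheet
ordering is fixed so identical runs produce byte-identical files; the
layout is this package's own declaration, not a claim about any other
tool's. A CSV mirror flag writes each sheet alongside the workbook for
headless diffing.

## Synthetic fixtures: what they emulate, and what not

The generators are pure functions of their parameters and a seed, and
every test consumes only generated data plus its ground truth.

* `makeBlobImage` — bright disks (intensity 200) on a noisy background
  (30 ± 5, clipped at 80), placed by rejection sampling so blobs never
  touch; 0.5 µm/px calibration. Noise is kept strictly sub-threshold so
  segmentation truth is unambiguous: tests on these images may assert
  exact counts and areas. Real micrographs — shading, blur, touching
  nuclei — are *not* emulated, so passing tests show the machinery is
  correct, not that any particular biological segmentation is easy.
* `makeMovingSpots` — solid spots advancing along parallel 3-4-5
  steps (dx = 3, dy = 4; exactly 5 px per frame) with optional integer
  jitter; the precondition (spacing > 4·(step + 3σ)) keeps the
  assignment unambiguous. Rigid translation of a rasterised disk moves
  its centroid exactly, so motion statistics have closed-form expected
  values.
* `makeSkeletonImage` — 1-px polyline shapes (line, plus, H, 2×2 grid)
  with junction/edge counts known by construction.
* `makeMorphologyTrio` — single pixel, thin sinuous 1-px filament
  (slope kept below 1 so the curve is 8-connected and one pixel per
  column), and a solid ellipse covering ~a third of the frame, at
  256×256 — the three morphology classes for the store-cost
  comparison.
* `makeRandomMask` — unions of random spheres/boxes plus ~0.1%
  scattered voxels; the store-equivalence suite runs on these
  object-like masks (uniform random noise would degenerate every tree
  to pixel-level subdivision, a regime covered separately by dedicated
  small cases).

## Problem sizes and numerical choices

The shipped suite uses 200 random masks of 16–128 px per side and 1–8
slices for store equivalence, 50 seeded spot movies (2–5 spots, 5–10
frames) for tracking recovery, 100 random workflows for reactivity,
and 1 000 random operations for the relationship audit — sizes at which
the exhaustive oracles remain cheap and the behaviour already exercises
every code path. Assignment ties are broken by id order; Otsu ties by
the lowest cut; blocked assignments use a large finite cost (1e12)
rather than infinities. Integer TIFF round trips are exact by
construction (values map 1:1 onto the 8/16-bit sample range).

## Known limitations

Single linear pipelines only (no branching graphs); TIFF is the only
image format (multi-series container formats are out of scope, though
the series-name metadata and filters exist so the batch API is stable);
2D hole filling and skeletonisation (per slice); frame-to-frame linking
without gap closing; no disk-backed image storage — stacks must fit in
memory. The xlsx writer produces plain value sheets only (no styles,
charts or formulas) and its reader is intended for workbooks this
package wrote.
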