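---
title: "Parsing reaction scheme images into reaction graphs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing reaction scheme images into reaction graphs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnscheme)
```

## The problem

Chemists communicate transformations graphically: a reaction scheme shows
2-D structure diagrams joined by reaction arrows, with short alphanumeric
labels ("1a") below diagrams and conditions text (reagents, catalysts,
temperatures) above or below the arrows. Machines cannot consume these
figures directly, which blocks large-scale mining of reaction data from the
literature. `rxnscheme` turns a raster image of a scheme into a
machine-readable *reaction graph*: nodes are chemical diagrams, and each
directed edge is a reaction step linking a reactant group to a product group
via one arrow, with any conditions text attached to the step.

The package combines learned detection with symbolic (rule-based) stages
that inject layout knowledge a chemist takes for granted: labels sit below
their diagram, conditions sit along the normal of their arrow, arrowheads
point at products, and a step ends where the next arrow begins.

## Pipeline anatomy

For one image, `extract_scheme()` runs:

1. **Binarization** — global Otsu threshold on the grayscale image
   (schemes are high-contrast line art), ink as foreground.
2. **Connected components** — maximal 8-connected foreground sets;
   diagonal adjacency matters because arrowheads touch shafts
   corner-to-corner.
3. **Region detection** (diagrams, labels, conditions) — a pluggable
   backend, see below.
4. **Arrow detection** — components filtered by simple bounds (area,
   elongation, fill ratio) become proposals; a two-branch convolutional
   model classifies each 64 x 64 patch as arrow / non-arrow and, for
   arrows, into solid, curly, equilibrium or resonance.
5. **Diagram completion** — a raw diagram box is refitted by dilating its
   largest component with a locally sized disk kernel and absorbing every
   component the dilated mask touches (this recovers detached superatom
   text).
6. **Text postprocessing** — each text region is reclassified using its
   nearest diagram and nearest arrow, then labels are paired with their
   nearest diagram and conditions with their nearest arrow.
7. **Arrow geometry** — a rotated rectangle fitted to the arrow pixels
   (principal-axis least squares) gives the direction; the center of mass
   marks the head side. Curly arrows get an endpoint analysis instead.
8. **Step scanning and stitching** — scans outward from each arrow collect
   reactant and product diagrams; shared diagrams link steps into the
   final graph, exported as JSON or GraphML.

All coordinates are 0-based, origin top-left, x rightward, y downward;
boxes are half-open `[x0, x1) x [y0, y1)`. This one convention is used by
every function and file format in the package.

## The scheme engineer

Real annotated schemes are expensive, so training and testing run on
*artificial* schemes composed by the package itself. A `schema_spec()`
fixes the layout family — `linear` chains of steps in reading order
(wrapping onto further rows when a maximum width is set) or `cyclic` rings
like catalytic cycles — together with the number of steps, the diagram
group sizes, and the probabilities that a diagram carries a label or an
arrow carries conditions text.

Elements come from an element bank of procedurally rendered glyphs:

* **Diagram glyphs** are polyline skeletons (a jittered ring with bond-like
  spokes), optionally with a small detached text cluster a few pixels away
  standing in for a superatom. They are *not* renders of real molecules:
  what the downstream stages need are the visual feature classes (line
  drawings, signal discontinuities, text blocks), not chemistry. The
  generated schemes make no chemical sense by construction.
* **Arrows** are rendered analytically at any angle from stroke
  primitives: solid (shaft + filled head), curly (quadratic arc + barbed
  hook), equilibrium (two harpoons whose half-heads bridge the shafts so
  the arrow stays one connected component), resonance (heads both ends).
  The renderer records tail and tip, which become the ground-truth
  direction.
* **Labels / conditions** are rows of random letter-like stroke cells.
* **Negatives** are plus signs and brackets; they are placed as decoys and
  also separate diagrams within a group.

Each glyph passes through `augment_glyph()` (isotropic scale, small
rotation, optional Gaussian blur, re-thresholded) before placement.
Placement enforces a 4 px non-overlap margin; against arrows the test uses
the actual ink rather than the bounding box, because a rotated arrow's
axis-aligned box vastly overstates its footprint. Conditions are placed
0.15-0.6 arrow lengths from the arrow midpoint along its normal, so the
directionality criterion used later is satisfiable by construction; labels
go strictly below their diagram with a small gap. A single seeded RNG
threads through every draw: fixed `(schema, bank, seed)` reproduces the
image and annotation byte for byte.

`generate_dataset()` writes PNGs, one COCO-style annotation file (category
ids 1 = diagram, 2 = label, 3 = conditions, 4 = arrow, boxes as
`[x, y, w, h]`), a sidecar annotation with pairings and arrow geometry, and
a ground-truth graph JSON per scheme.

What the generator does *not* emulate: scanned-page noise, fused
components (an arrow touching a letter), text fonts beyond the stroke
cells, crowded multi-column layouts, or chemically meaningful structure.
Tests passing on this distribution therefore demonstrate the symbolic
machinery and the trainability of the models, not performance on real
journal figures.

## The arrow model

Arrows are small and carry little semantic content, which is why they get
a dedicated lightweight detector rather than a share of the main region
detector. Proposals are connected components passing configurable bounds
(defaults: area between 20 px and 5% of the image; elongation at least 2
or fill ratio at most 0.2). Each proposal is masked to its own pixels,
centered, padded square and rescaled to 64 x 64.

The model is a compact convolutional network written in base R matrix
operations (im2col convolutions, hand-written backpropagation, Adam and
SGD updates): three 3 x 3 conv / ReLU / 2 x 2 max-pool stages (8, 16, 32
channels), a shared 64-unit fully connected layer, then two branches — a
1-unit detector head and a 4-unit subtype classifier reached through one
extra hidden layer. Given the 64 x 64 inputs and desk-scale sample sizes
(hundreds of patches), this trains in minutes on one CPU.

The loss is the weighted two-branch objective

$$L = \lambda_1\,\mathrm{BCE}(p_\text{arrow}, y>0)
    + \lambda_2\,\mathrm{CE}(\mathbf{p}_\text{subtype}, y), \qquad
  \lambda_1 = 10,\ \lambda_2 = 1,$$

with the subtype term contributing only for true arrows: a subtype is
undefined for a non-arrow patch, so its gradient is masked there (the
published description leaves the negative-patch supervision of the 4-way
branch open; masking is this package's resolution). Training defaults are
20 epochs, Adam, learning rate 0.001, batch 32, fully seed-deterministic.
Labels run 0-4 (0 = non-arrow, then solid, curly, equilibrium, resonance).

A deliberate limitation carried over from the design: an arrow fused with
other ink exists only as a merged component, so the arrow itself can never
be recovered — at best the blob is (mis)classified as a whole.

## The region detector

The three remaining classes ride behind one interface with two backends.

The **oracle backend** replays a scheme's ground-truth annotation, with
optional perturbations (Gaussian box jitter, drop rate, spurious-box rate)
for robustness studies. With zero perturbation every downstream stage
becomes a pure function of the annotation — this is the harness used to
test postprocessing and graph formation in isolation.

The **learned backend** is a reduced detector: class-agnostic proposals
from dilation-grouped components pooled over two dilation radii (2 and
4 px — no single radius can separate a "superatom gap" from a "label gap";
the classifier and per-class NMS arbitrate), a small convolutional crop
classifier (background / diagram / label / conditions), score threshold
0.5, NMS IoU 0.5. Its configuration records the published full-scale recipe
(Faster R-CNN with a ResNeXt-101 backbone, DIoU box loss with RPN/head
weights 2.0 / 10.0, SGD at 0.001, 5000 iterations, 2000 schemes) as the
target it approximates; the in-package trainer uses the same optimizer
family and learning rate at a few hundred iterations. Reproducing the
published detection F-scores is explicitly out of scope for the reduced
path — the symbolic stages are the bespoke content here.

## Symbolic postprocessing

**Diagram completion.** The kernel radius is computed locally:
`clamp(1.2 x median nearest-neighbour gap between the components inside
the raw box, 3 px, 5% of the image diagonal)`. It must bridge superatom
gaps (a few px) without bridging the tens of px separating neighbouring
diagrams. Completion marks the region `postprocessed` and skips regions
already marked, making it exactly idempotent.

**Reclassification.** For each text region, find the nearest diagram and
nearest arrow by box/ink distance. Diagram closer *and* region below the
diagram (center below its bottom edge, horizontal overlap at least 25% of
the narrower box) makes it a label; arrow closer *and* the directionality
criterion satisfied makes it conditions; otherwise the prior class stands.
The directionality criterion bounds the region center's offset from the
arrow center: at most 1.0 arrow lengths along the arrow's normal and 0.6
along its axis (both configurable; the source description leaves them
unquantified). Ties go to the diagram, then reading order — determinism
over elegance.

**Pairing.** Label to nearest diagram, conditions to nearest arrow
(many-to-one allowed), and diagrams whose completed box lies inside a
conditions region are attached to that conditions record. Distance to an
arrow is measured to its axis segment, not its axis-aligned box — for
diagonal arrows the difference decides pairings in ring layouts.

## Arrow geometry

The rotated rectangle comes from a principal-axis (least-squares) fit of
the pixel centers; the long axis is the direction, and the center-of-mass
offset along it picks the head side (ink accumulates in the head). An
offset below 0.5% of the arrow length is treated as symmetric:
`head_side = 0`, direction sign arbitrary but flagged. Equilibrium and
resonance arrows are flagged bidirectional.

Curly arrows need endpoints. Four shallow probe rectangles (depth 0.2 of
the perpendicular box dimension) each nominate their most extremal arrow
pixel. Stage 1 merges picks closer than `max(5 px, 0.2 x box diagonal)` —
on a strongly curved terminus, two probes can pick points of the same
physical end up to about a fifth of the diagonal apart, which is why the
radius is that large; distinct termini sit a full arrow length apart and
are never merged. Stage 2 erases a window of the same scale around each
pick: removal at a true terminus leaves the arrow connected, removal
mid-arc (or at an elbow) splits it; sub-3 px fragments are erasure crumbs
and are ignored. Hooks are told from plain ends by scan-line pixel counts
along a locally fitted line (within 15% of the arrow length of the
endpoint — local enough that a curved stroke is straight), binned at 2 px
to damp rasterization flicker; a coefficient of variation below 0.25 means
constant width, hence an end. The reference (hook, end) pair maximizes
nearby diagram area (within 1.5 arrow lengths), encoding the assumption of
a main reactant and product per step.

## Step scanning and graph stitching

Scan directions: for solid/equilibrium/resonance arrows the fitted axis
(signed toward the head); for curly arrows the lines from the box midpoint
to the reference hook (products) and end (reactants). The scan walks
equidistant strips of width 0.25 arrow lengths along each direction inside
a corridor of lateral half-width 0.2 arrow lengths (floor 20 px),
collecting every diagram whose completed box meets a strip, and stops when
a strip meets another arrow — that arrow belongs to the next step. The
stop test uses the other arrows' *rotated* rectangles, and the stopping
strip still collects diagrams that enter the corridor before the blocking
arrow does, with a grace margin of 0.15 arrow lengths (a neighbouring
arrow's head abuts the shared diagram and can graze the corridor a few
pixels ahead of the diagram's box — common in rings). A diagram seen from
both sides goes to the nearer side, ties to the reactants.

If one side collects nothing, the step is assumed to span multiple text
lines: diagram boxes are clustered into horizontal bands, and the previous
band is searched when the arrow sits in the lower half of the image, the
next band otherwise; a missing reactant takes the rightmost diagram of the
previous band, a missing product the leftmost of the next (reading order).

Steps sharing a diagram id stitch implicitly into the reaction graph;
nodes are individual diagram regions (merging visually identical diagrams
across a scheme would need structure recognition, which is out of scope).
Within a step, products keep reading order. Export is JSON (nodes with
boxes and optional decoded text, steps with reactant/product/conditions
ids) or GraphML via igraph, both round-trip safe.

## Evaluation machinery

`prf_metrics()` computes recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and
`F = 2PR/(P+R)` in percent, reporting `NA` where a denominator vanishes.
`match_regions()` does greedy one-to-one matching by descending IoU at a
default threshold of 0.5 (the published account defers exact matching
rules to unavailable supplementary material, so the threshold is exposed
and reported). `match_graphs()` establishes node correspondence by
diagram-box IoU (same 0.5), finds start steps (reactants produced by no
other step), traverses, and counts matched steps; a cyclic scheme has no
start, so a seeded random node begins a circular walk — the counts are
invariant to that choice. Diagram-label matching is scored as equivalent
recall only (correct vs incorrect pairings), mirroring how such matching
is reported.

## Numerical choices and degenerate inputs

* Uniform images binarize to an empty mask with a warning; blank images
  yield empty graphs, not errors.
* A single-pixel arrow is degenerate and errors; an arrow whose endpoint
  filter leaves fewer than two survivors raises an "unparseable arrow"
  error, which the pipeline catches by falling back to the frame axis.
* Batch extraction isolates failures: a corrupt image is logged and
  skipped, the rest of the batch completes.
* Every stochastic stage draws from one seeded generator; per-scheme seeds
  derive from the master seed below `2^31`.

## Problem sizes used in the bundled checks

The test-suite and acceptance-script sizes are chosen so the whole battery
runs in minutes on a single CPU while still exercising every code path at
meaningful scale: 50 linear plus 10 cyclic schemes for end-to-end
annotation recovery, 250 procedural patches (200 train / 50 held out, 20
epochs) for the arrow model, 10 + 10 schemes and 150 SGD iterations for
the reduced region detector, and 100 procedural curly arrows for the
endpoint analysis, scored against an independent Zhang-Suen
skeleton-degree oracle.

## Known limitations

* Fused components (arrow touching text) lose the arrow: only the merged
  blob is visible to the proposal stage, by design.
* The reduced region detector is a stand-in at desk scale; its published
  full-scale counterpart is recorded as configuration, not reproduced.
* Directionality of equilibrium/resonance arrows is taken from the COM
  like solid arrows and flagged bidirectional; the flag is carried, not
  semantically resolved.
* The generator's data distribution is idealized; robustness to real
  scans should be assessed with the oracle perturbation knobs
  (`jitter_sd`, `drop_rate`, `spurious_rate`) and, ultimately, real
  annotated data plugged in through the same COCO format.
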