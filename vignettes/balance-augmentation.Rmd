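---
title: "Methods: occlusion-aware balance augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occlusion-aware balance augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occubal)
```

# The procedure

`occubal` implements oversampling-by-synthesis for detection datasets whose
boxes carry one of eight occlusion labels (`N`, `L`, `F`, `B`, `LF`, `BL`,
`BF`, `BLF`) and whose images belong to a (region, illumination) cell. The
pipeline has four stages — count, plan, synthesize, pack — plus standard
VOC/YOLO I/O and VOC-style evaluation. The underlying assumptions are:

* **Occluders enter from the boundary.** A branch or leaf hiding an apple
  crosses the edge of the apple's bounding box; it does not materialize in
  the middle. The edge-entry rule encodes this prior.
* **Occlusion class is compositional.** A `BLF` apple is an `N` apple plus
  a fruit, a branch and a leaf occluder, so fused classes can be
  synthesized by sequential composition of the single-occluder steps, and
  the emitted label is a pure function of the element kinds applied.
* **Illumination does not mix.** Elements segmented from daylight images
  pasted onto night crops would be photometrically implausible, so the
  component pool is keyed by illumination and sampling never crosses keys.
* **Labels must stay exact.** Crops are never resized during packing and
  pasted extents are recorded directly as boxes, so synthetic labels are
  correct by construction rather than re-annotated.

# Counting and planning

`count_boxes` tabulates boxes per (sub-dataset key, class).
`make_balance_plan` then:

* skips sub-datasets with fewer than `min_boxes_to_retain` boxes in total
  (default 1000). On the shipped benchmark table this retains
  `ZY_H, ZY_L, QX_H, PSR_H` and skips `QX_L` (491 boxes) and `PSR_L` (0):
  a sub-dataset that small contributes almost no `N` material to
  synthesize from, and balancing it would mean manufacturing a cell almost
  entirely out of duplicated crops;
* sets the target to the **largest retained cell count** (10,579 on the
  shipped table — class `B` in `ZY_H`), so no data is discarded and every
  deficit is non-negative; `target` can be overridden upward;
* defines `deficit = target − count` per retained cell. Conservation
  (`count + deficit = target`) is asserted property-style in the tests.

Percentage shares in `imbalance_report` are rounded half-up to one decimal;
max/min ratios are reported exactly and floor-truncated (the form usually
quoted, e.g. "16×" between the largest and smallest class totals, "195×"
between the largest and smallest nonzero retained cell).

The shipped table's own grand total is 81,392 boxes and the implied
balanced total is `4 × 8 × 10,579` plus the unbalanced remainders; the
package always reports recomputed values rather than any externally quoted
total.

# Synthesis geometry

**Branch/leaf (edge entry).** The `N` crop carries a 6×6 grid (cell sizes
`w/6 × h/6`, kept fractional; pixel rectangles are rounded only at paste
time). The start point is drawn uniformly from the 4·6 = 24 boundary
lattice points; the endpoint uniformly from all lattice points not in the
start's row or column and more than 3 grid lengths away. Distance is
**Chebyshev** in grid units: the excluded neighbourhood is then an
axis-aligned block adjacent to the start, which matches the grid geometry;
Euclidean distance is available via the `metric` argument. On the 6×6 grid
no boundary start has an empty endpoint set (verified exhaustively in the
tests), so the retry loop (budget 100) exists only for robustness on
degenerate custom grids. The element is cropped to a sub-rectangle with
sides scaled by a uniform draw in [0.5, 1] (covering scale² of its area),
anchored at its alpha-weighted centroid (geometric center for an
all-transparent mask), then resized anisotropically to the spanned
rectangle and alpha-composited. Compositing uses a hard mask (alpha
binarized at 0.5, no feathering): synthetic occlusion boundaries are sharp,
which keeps the changed-pixel region exactly the paste rectangle and makes
the label geometry verifiable pixel-by-pixel.

**Fruit (overlap-capped canvas).** Pasting a fruit element directly on the
crop could cover it almost completely, turning an `N` apple into what a
detector would have to call `F` with nearly no visible evidence — or
conversely make the pasted fruit the apparent `N`. Instead the crop is
centered on a 14×14-cell canvas (its own cells; `N` occupies the central
6×6 block, offsets rounded from fractional cells), and the fruit element —
resized to the crop's size — has its upper-left corner drawn uniformly at
pixel resolution in quadrant 1 (the canvas's upper-left 7×7 cells). A draw
is rejected until the rectangle overlap with the `N` footprint is at most
34 % of the crop area *and* the element centroid does not coincide with
the canvas origin. Unconstrained quadrant-1 corners can reach overlaps
near 100 % (corner at the `N` corner), so the cap is enforced by rejection
sampling; with the default geometry the acceptance region is large and the
100-retry budget is never exhausted in practice. The canvas is cropped
back to the `N` footprint, so the output crop keeps its size.

**Fused classes.** `BL` = branch then leaf; `BF` = fruit then branch;
`LF` = fruit then leaf; `BLF` = fruit, then branch, then leaf (the fruit
step first, while the substrate is still a clean `N`). An alternative
route pastes one pre-segmented composite element by the edge-entry rule.
Compositionality — the fused result equals running the single steps under
the same RNG stream — is tested directly.

**N.** Deficits of class `N` are filled by cyclic extraction alone: the
sub-dataset's `N` boxes are cropped in a seeded random order, cycling
round-robin when the deficit exceeds the number of distinct boxes, so
reuse is as even as possible.

# Packing and merging

The free-space policy is **shelf packing**: left to right along a row, new
row when the current one is full, new base image when the crop fits
nowhere on the canvas. It is deterministic, never overlaps placements, and
keeps labels exact; optimal bin packing is a non-goal (density is
irrelevant — base images are plentiful). Inter-crop padding defaults to
5 px so adjacent synthetic boxes never touch. Crops of different classes
share base images (classes are iterated within one packing pass per
sub-dataset). Base images are standardized to 640×480 or 1280×720 (chosen
uniformly per image, seeded), matching common orchard camera formats; for
low illumination a configurable fraction (default 0.25) is additionally
Gaussian-blurred (σ = 2 px) to emulate the blurred-supplement base
material low-light collections typically need. Outputs are written as PNG
plus Pascal VOC XML and YOLO txt, with a JSON build manifest of scheduled
vs produced counts per cell.

# Evaluation

Matching is greedy per class and image: predictions in order of decreasing
confidence, each taking the unmatched ground-truth box with the highest
IoU if that IoU ≥ 0.5. `AP` integrates the precision envelope over recall
(all-point interpolation; the 11-point variant is available), and `mAP` is
the arithmetic mean of the eight per-class APs (factor 0.125). Aggregate
`P`/`R` require a score cutoff to define TP/FP counts; the cutoff is an
explicit argument (default 0.5) rather than an implicit convention.
Zero-denominator precision or recall is reported as 0 with an `undefined`
flag so empty classes do not crash aggregate reports.

# Coordinate and I/O conventions

Boxes are 0-based, half-open (`[xmin, xmax) × [ymin, ymax)`), so width is
`xmax − xmin` exactly — unambiguous for overlap arithmetic. Pascal VOC's
1-based inclusive convention is converted at the file boundary; YOLO's
normalized center format round-trips within 0.5 px. Out-of-bounds boxes
are rejected by default (`on_invalid = "clip"` opts into clipping). The
train/test split is by image, seeded uniform shuffle, test size rounded
half-up (`test_fraction = 0.3` gives the canonical 3:7 split). Region and
illumination ride in a manifest CSV when not derivable from files. A
single master seed derives per-stage seeds by hashing stage labels, so
every stage is independently reproducible and a fixed seed makes the whole
build byte-identical.

# Illumination

The binary high/low illumination label is an injection point: any
classifier can be plugged in as `predictor`/`labeler`, and manifest labels
bypass classification entirely. The default is a Rec.601 mean-luma
threshold at 90/255 — bright daytime scenes sit well above it, backlit and
night scenes well below. It is a deterministic, monotone heuristic that
gives the pipeline a reproducible split; it is not claimed to reproduce
the assignments of any trained illumination model.

# What the toy generators do and do not emulate

`generate_fixture_dataset` renders flat shapes (disk = apple, rectangle =
branch, ellipse = leaf, offset disk = occluding fruit) on textured
backgrounds whose mean gray encodes illumination (defaults 160 and 40,
either side of the luma threshold), placing exactly the requested number
of boxes per (key, class) cell on a non-overlapping slot grid.
`generate_fixture_pool` draws elements with analytically known masks, and
`generate_fixture_predictions` jitters ground truth with
quality-controlled noise, missed detections and spurious boxes so AP rises
monotonically with quality. These fixtures exercise every geometric,
counting and labelling contract of the pipeline. They do **not** emulate
real orchard statistics: no photometric realism, no box-size or aspect
variation beyond the slot size, no annotation error, no correlated
occlusions. Green tests therefore certify the pipeline's arithmetic and
geometry, not detector-level gains on real imagery — the latter depend on
element quality and photometric consistency, which the pipeline
deliberately leaves to its inputs.

# Problem sizes and numerical choices

The test suite uses toy worlds of 2 regions × 2 illuminations with
per-cell counts up to 10, balance targets of 12–30, 256-px images and
48-px elements; the geometric fuzz suites draw 10,000 placements. These
sizes fully exercise cycling (deficits exceed available `N` boxes),
multi-base packing and every class route. Other choices: percentage
rounding is half-up (1 decimal); the test-count split rounds half-up;
alpha masks binarize at 0.5; rasters are arrays in [0, 1] and PNG output
is bit-deterministic; oversize crops error rather than silently rescale;
partial builds are not emitted on error.

# Limitations

* Element segmentation is out of scope: real pools need externally
  produced masks (the toy generator provides exact ones).
* Hard-mask compositing leaves sharp paste boundaries; a detector could in
  principle key on them. Photometric harmonization (blending, color
  transfer) is deliberately not applied.
* The luminance heuristic misclassifies unevenly lit scenes a trained
  classifier would handle.
* Balancing to the maximum cell multiplies dataset size (the shipped
  benchmark table implies ~4× more boxes), with corresponding training
  cost.
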