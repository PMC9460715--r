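# occubal

Balance augmentation for multi-type occlusion fruit-detection datasets.

## The problem

Orchard apple detectors must recognize fruit that is partially hidden, and
*what* hides it matters: a branch crossing an apple looks nothing like a
leaf covering it or another apple in front of it. Datasets annotated with
eight occlusion classes — `N` (no occlusion), `L` (leaf), `F` (fruit), `B`
(branch) and the fused combinations `LF`, `BL`, `BF`, `BLF` — are severely
imbalanced: unoccluded apples dominate while triply-occluded ones are rare,
and the skew differs by orchard region and by illumination (daytime vs
backlit/night footage). Training on such data makes lightweight detectors
systematically weak on the rare occlusion classes.

`occubal` rebalances such a dataset by *synthesizing* the missing
instances instead of reweighting or discarding:

1. **Count** annotation boxes per (region, illumination, class) cell and
   report the imbalance (`count_boxes`, `imbalance_report`).
2. **Plan** per-cell deficits toward a global balance target — the largest
   retained cell count; sub-datasets with too few boxes are skipped
   (`make_balance_plan`).
3. **Synthesize** occluded crops from no-occlusion (`N`) crops and a pool
   of segmented occlusion elements:
   - `B`/`L`: an element enters from the crop boundary. The crop carries a
     6×6 grid; the start point is one of the 24 boundary lattice points,
     the endpoint any lattice point not in the same row or column and more
     than 3 grid lengths away (Chebyshev); the element, cropped at a random
     scale in [0.5, 1], fills the spanned rectangle.
   - `F`: the crop sits centered on a 14×14-cell canvas; a fruit element
     resized to the crop is placed with its corner in the upper-left
     quadrant, rejected until its overlap with the `N` footprint is ≤ 34 %
     of the crop area and its centroid misses the canvas origin, then the
     canvas is cropped back to the `N` footprint.
   - Fused classes compose these steps (e.g. `BLF` = fruit, then branch,
     then leaf).
4. **Pack** the synthetic crops onto fruit-free base images (640×480 or
   1280×720) with shelf placement and automatic labels, and merge with the
   original training set (`pack_crops`, `build_balanced_dataset`).
5. **Evaluate** detections with the standard formulas
   `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, per-class `AP = ∫ P(R) dR`
   (all-point interpolation, IoU 0.5) and the eight-class mean
   `mAP = 0.125 · Σ AP(n)` (`evaluate_detections`).

Pascal VOC XML and YOLO txt annotations are supported on both ends, and a
fixtures module generates toy datasets, pools and detector outputs so the
whole pipeline runs without any download.

## Worked example

The package ships the benchmark statistics table of a three-region orchard
dataset (`inst/extdata/mtoa_table2.csv`: Zhaoyuan, Qixia, Prosser, split
into high/low illumination sub-datasets):

```r
library(occubal)
tab <- read_count_table(system.file("extdata/mtoa_table2.csv", package = "occubal"))
rep <- imbalance_report(tab)
plan <- make_balance_plan(tab, min_boxes_to_retain = 1000)
print(plan)
```

```
largest class N: 22986 boxes (28.2%); smallest BLF: 1374 (1.7%)
cell imbalance within retained sub-datasets: 195x
<ob_balance_plan> target 10579 per cell
  retained: ZY_H, ZY_L, QX_H, PSR_H
  skipped:  QX_L, PSR_L
  deficits (to synthesize):
         N    L     F     B    LF   BL    BF   BLF total
ZY_H   723 4982  9283     0 10105 4174  8643  9919 47829
ZY_L   940 6021  9678  4908 10327 7446  9851 10296 59467
QX_H  9306 9775 10311  7526 10463 9137  9645 10310 76473
PSR_H 8429 5284 10039 10390  9122 9637 10525 10432 73858
```

Reading: `QX_L` (491 boxes) and `PSR_L` (0 boxes) are too small to balance
and are skipped; every retained cell is raised to 10,579 boxes — the
largest observed cell (`B` in `ZY_H`) — so e.g. `ZY_H` needs 47,829
synthetic instances in total, none of them class `B`.

Running the synthesis end-to-end on a generated toy dataset:

```r
spec <- fixture_spec(data.frame(key = c("ZY_H", "ZY_L"), N = c(8, 6), B = c(10, 4),
                                L = 3, F = 2, LF = 1, BL = 4, BF = 2, BLF = 1),
                     seed = 7)
ds   <- generate_fixture_dataset(spec, "toy")
part <- partition_by_illumination(ds)
plan <- make_balance_plan(count_boxes(part), min_boxes_to_retain = 10)
pool <- generate_fixture_pool(spec)
res  <- build_balanced_dataset(part, plan, pool, seed = 3, out_dir = "toy_out")
count_boxes(partition_by_illumination(res$dataset))   # every cell == plan$target
```

A thin command-line wrapper exposes the same steps as subcommands
(`stats`, `plan`, `split`, `pool-validate`, `synth`, `pack`, `balance`,
`eval`, `fixtures`):

```sh
Rscript inst/cli/occubal.R plan --counts inst/extdata/mtoa_table2.csv --out plan.json
```

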