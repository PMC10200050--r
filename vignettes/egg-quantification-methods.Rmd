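---
title: "Methods: tile-based whitefly egg quantification and resistance statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-based whitefly egg quantification and resistance statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggquant)
```

## Overview

`eggquant` quantifies whitefly eggs on large stitched leaf images by
cutting the image into fixed-size tiles, detecting candidate eggs per
tile, and reconciling the per-tile detections into one per-image count.
This vignette documents the model behind each stage, the parameters that
matter, the numerical conventions, and what the synthetic test bed does
and does not demonstrate about real images.

## Coordinate conventions

All boxes are axis-aligned rectangles in 0-based, half-open pixel
coordinates: a box covers `[x1, x2) × [y1, y2)` with `x` as column and `y`
as row, so a box's width is exactly `x2 − x1` and area arithmetic is
unambiguous. Both supported annotation dialects (normalized YOLO text and
a pixel-coordinate CSV) are converted to this convention on read.

## Cropping and tiling

An `L × W` image rarely divides into `c × c` tiles exactly, so the
surplus `S_L = L mod c`, `S_W = W mod c` is removed before tiling, split
as evenly as possible across the two sides of each axis. For an odd
surplus the extra pixel is removed from the bottom/right — an arbitrary
but fixed choice that makes the crop deterministic. With the default
`c = 1400` the cropped image partitions exactly into 1400 px cores; each
core is extended by 100 px of padding per side into a 1600 px window, so
adjacent windows overlap by 200 px and any egg (at most ~90 px across)
lying on a core boundary is seen *whole* by at least one window.

Where a padded window extends past the cropped image, pixels are taken
from the original image (the cropped-away surplus provides them); beyond
the original image the window is mirror-reflected by default. Reflection
was chosen over zero-fill because a fabricated dark border would change
detector behaviour at the image edge; `"replicate"` and `"zero"` policies
are available.

## Detection and post-processing

The per-tile detector is a contract (`detector_backend()`): any function
from a padded RGB tile to boxes with confidences. Internal resizing is
the backend's concern — the pipeline always hands it the full window.
After detection, each box is retranslated to original-image coordinates
by adding the window origin and crop offsets (an exact, invertible
translation), and the three post-processing stages run in a fixed order:
merge, size filter, confidence filter.

**Merging.** Boxes whose pairwise IoU exceeds 0.5 are duplicates of one
egg seen from adjacent tiles. The merge rule groups boxes by connected
components of the "IoU > threshold" graph and replaces each group with
its coordinate-wise envelope (lowest `x1`/`y1`, highest `x2`/`y2`),
carrying the maximum constituent confidence. Merging pairs one at a time
is order-dependent — merging A with B first can enlarge the envelope
enough that its IoU with C drops below the threshold, while merging B
with C first would have chained all three — so the component-wise rule is
used: it is order-free, and it is re-applied until a fixed point because
envelopes can create new overlaps. The k-ary IoU (intersection of all
boxes over the exact union of all boxes, via coordinate compression) is
implemented and tested, but the merge rule itself only consumes pairwise
IoU, which is the only deterministic reading of merging "two or more"
overlapping boxes.

Maximum was chosen for the merged confidence (rather than mean) because
a duplicate detection is evidence *for* the object, and max keeps the
confidence filter monotone under merging.

**Size filter.** A detection is kept iff both sides are ≥ 20 px and
≤ 90 px. This is the literal "either side out of band → reject" reading;
the band brackets the observed egg box extents (~22–88 px at ~350
px/mm) and removes trichome fragments, leaf spots (small) and nymphs or
smears (large). Rejected boxes are kept with a reason code for auditing.

**Confidence filter.** Kept iff `confidence ≥ τ` (boundary kept, so a
sweep grid value keeps exactly the boxes at or above it); default
`τ = 0.6`, the optimum of the 0.30–0.70 × 0.05 grid sweep. Whether the
original protocol thresholds before or after merging is not stated
explicitly anywhere we could verify; this package follows the listed
order (merge → size → confidence). With max-confidence merging the two
orders differ only when a duplicate group mixes confidences across τ.

## Evaluation protocol

Object level: predictions are matched one-to-one to ground truth
greedily in descending IoU order (ties broken by truth index then
prediction index), a pair counting only when IoU is strictly above 0.5.
Greedy matching is not guaranteed optimal; tests verify its true-positive
count never exceeds an exhaustive-assignment oracle and that the match
respects count conservation. Precision, recall and F1 follow from the
matched counts; precision with zero predictions is reported as missing
rather than zero.

Image level: the signed relative counting error `(TC − AC)/TC` and the
agreement form `1 − |TC − AC|/TC` are both computed — the signed form
as printed in the original evaluation protocol is an *error* (a perfect
count gives 0), while the agreement form is what a "counting accuracy of
0.94" refers to; exporting both avoids silently resolving the
discrepancy. Miss rate is `missed/TC`. Per-image metrics are aggregated
by unweighted mean; `r²` between predicted and true counts is the squared
Pearson correlation (the convention for predicted-vs-true scatter plots),
with an identity-line variant behind `method = "identity"`.

The threshold sweep retains unthresholded detections, re-applies only the
confidence stage per grid value, and reports the τ maximizing mean F1,
ties going to the smaller τ (the cheaper, higher-recall choice).

## Assay statistics

Per clip cage, five females are released for five days. Per plant the two
cages are pooled before applying

- adult survival `AS = Σalive / Σreleased`,
- oviposition rate `OR = 2·Σeggs / (Σalive + Σreleased)`,

so each accession contributes n = 3 plants, not 6 cages — pooling first
avoids pseudo-replication of the plant effect. "Total whiteflies" is the
number *released*, not recovered: some cages recover fewer than five
whiteflies, which would make a recovered-based denominator ambiguous;
such rows are kept with a warning. AS is arcsine-square-root transformed
(the standard variance stabilizer for proportions — a literal arcsine of
the raw proportion stabilizes nothing) and OR square-root transformed.
Comparisons are two-sided equal-variance Student's t-tests, with Welch's
variant available. On the packaged assay table the two variants agree at
the 0.05 level for the sharper imaging device; for the second device one
oviposition contrast sits near the boundary and Welch's reduced degrees
of freedom (near-zero variance in the susceptible group) push it just
above 0.05 — a caveat worth knowing at n = 3.

The packaged fixture (`inst/extdata/whitefly_assay.csv`) is a clip-cage
assay of four Solanum accessions: susceptible tomato (Moneymaker) and
potato (RH89-039-16) cultivars paired with resistant wild accessions
(*S. habrochaites* LA1777, *S. berthaultii* BER481-3), three plants per
accession, two cages per plant, egg counts from two imaging devices.

## The synthetic test bed

The generator emulates what matters to this pipeline: egg-sized,
egg-shaped, egg-coloured objects on a textured green background, with
exact ground truth. Eggs are anti-aliased ellipses with major axis 47–86
px, axis ratio 0.35–0.47 (a whitefly egg is ~0.2 × 0.08 mm, ratio 0.4),
colours on a translucent-green-to-brown ramp, placed by rejection
sampling under a minimum center distance (default 110 px, keeping eggs
disjoint). Ground-truth boxes are the exact analytic ellipse bounds
(floor/ceil to whole pixels), not dilated. Distractors: thin bright
trichome polylines, translucent honeydew discs, sub-20-px specks,
over-90-px smears, and defocus patches (two passes of a radius-8 box
blur — strong enough to pull a small egg below the detector's contrast
threshold, emulating leaf-curl blur causing missed detections). All
randomness flows through one seed per scene; the same seed reproduces
the scene bit-for-bit.

The reference detector thresholds the `2R − G` channel contrast (eggs
score ~0.5, background ~−0.15, honeydew stays below threshold), labels
connected components, and scores each component by fill ratio and the
proximity of its moment-based axis ratio to 0.4 — the moment ratio is
rotation-invariant, so a rotated egg is not penalized, while a trichome's
elongation keeps it below confidence 0.5. Components touching the tile
window border are dropped: a clipped partial detection cannot be
IoU-merged with its complete duplicate from the neighbouring tile, which
always exists because the padding (100 px) exceeds the maximum egg extent.
Component boxes are grown by 1 px per side to recover the anti-aliased
rim lost to thresholding, keeping minimum-size eggs above the 20-px
filter.

**What passing means — and does not.** On clean synthetic scenes the
pipeline recovers counts exactly (counting accuracy and F1 of 1.0 over
20 seeded scenes of 10–200 eggs); on scenes salted with distractors and
defocus, predicted counts track true counts with r² > 0.95. These results
validate the *pipeline arithmetic* — tiling, retranslation, merging,
filtering, evaluation — under a detector that is reliable by
construction. They say nothing about detecting real eggs in real images:
the generator has no leaf venation, no specular highlights, no touching
egg clusters, no continuous focus gradients, and its colour separation is
cleaner than nature's. On real images the detector seat is meant for a
trained model plugged in through `detector_backend()`.

Scene sizes used in the shipped tests and acceptance script — 3000 ×
3000 px canvases (2 × 2 tile grids after cropping) with up to 200 eggs —
were chosen to exercise every geometric path (surplus crop, interior and
edge tiles, cross-tile duplicates) while a full run stays in the
minutes range on a single CPU; the tiling arithmetic itself is tested up
to the largest supported microscope dimensions (9287 × 10399 px, 42
tiles). Eggs are placed clear of the cropped-away border
(`edge_margin_px`), as a clip-cage sample sits centrally in a real image;
eggs in the surplus band would be cropped away by design and counting
them against the pipeline would test the generator, not the algorithm.

## Degenerate inputs and numerical choices

- Images smaller than one tile core raise an explicit "image too small"
  error rather than silently padding.
- `iou()` of a single box is 1; of an empty set, an error.
- A match with no truths and no predictions yields missing metrics with a
  warning; `TC = 0` images are excluded from aggregates.
- `r²` of a constant vector is missing with a warning (the correlation is
  undefined), not 0.
- Identical groups in a t-test give `t = 0, p = 1`; two groups that are
  *both* constant raise an error suggesting an exact comparison instead.
- Confidence ties at the filter boundary are kept (`≥ τ`), making the
  sweep grid unambiguous.

## Known limitations

- The merge envelope can, in pathological overlap chains, grow beyond
  any constituent box; real duplicate groups (near-identical boxes from
  adjacent tiles) are unaffected, but heavily overlapping *distinct*
  objects would be merged into one. The protocol accepts this: eggs laid
  touching each other are genuinely hard to separate at detection time.
- Greedy matching can under-count true positives relative to optimal
  assignment in contrived overlap patterns (never observed in the fuzzed
  test instances, where it is compared against an exhaustive oracle).
- The assay module implements exactly the published two-group design; it
  does not model cage effects (mixed models) or correct for multiple
  comparisons, matching the original analysis.
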