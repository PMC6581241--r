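---
title: "Gallstone detection with anatomical-context confidence rescoring"
author: "cholescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gallstone detection with anatomical-context confidence rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholescan)
```

## The problem

Cholelithiasis — gallstones in the biliary system — is diagnosed on
abdominal CT by finding stones inside the gallbladder. Two stone
appearances matter clinically: *granular* stones are bright, compact and
irregular; *muddy* stones are larger, low-contrast gray masses only
slightly darker than the bile around them. A single-stage object
detector can localize both, but it also hallucinates: a gray patch of
liver tissue looks locally identical to a muddy stone. Radiological
context resolves the ambiguity — gallstones exist only inside a
gallbladder, which sits against the liver. This package implements that
contextual reasoning as an explicit, auditable rule system layered on
top of a grid/anchor detector, together with everything needed to test
it end to end without clinical data: a synthetic phantom generator, a
small fully convolutional detector, AP/mAP evaluation and a k-fold
cross-validation harness.

## The context policy

The detector emits detections with confidences in percent
(objectness score × class score × 100). For each image, organ presence
is assessed from the non-stone detections: an organ counts as present
when some detection of it reaches the presence threshold (default 25%,
the same value as the output threshold). Every stone confidence $c$ is
then rescaled to $c' = \min(100,\; c \cdot w)$, with $w$ chosen by
context:

| rule | context                   | weight (default)       |
|------|---------------------------|------------------------|
| R1   | liver and gall present    | `w_both` = 1.2 (capped at 100) |
| R2   | gall present, liver absent| `w_gall_only` = 1.0    |
| R3   | liver present, gall absent| `w_liver_only` = 0.6   |
| R4   | neither present           | $c' = 0$               |

A box is output only when $c'$ strictly exceeds the output threshold
(25%). The canonical case: a muddy-stone misdetection at 33% on a slice
with a liver but no gallbladder falls to $33 \times 0.6 = 19.8\% < 25\%$
and is suppressed. Because raw stone false positives on negative slices
concentrate between 25% and 40%, the 0.6 weight maps that whole band
below the output threshold — which is exactly why it is the default.

Design choices where the rule system is under-determined:

* R1 says "increase up to 100%". We realize all four rules as one
  multiplicative family; 1.2 is a mild boost and the cap keeps the value
  a valid percentage. Any $w_\text{both} \ge 1$ preserves the rule
  ordering $0 = w_{R4} \le w_{R3} \le w_{R2} \le w_{R1}$.
* R2 says "unchanged or decrease slightly"; we default to the identity
  end of that range.
* The presence threshold is not separated from the output threshold
  anywhere in the rules, so it defaults to the same 25%.
* Containment ("stones *in* the gallbladder") is offered as an option
  (`require_containment`): when enabled, a stone whose centre lies
  outside the best gall box is treated as if the gall were absent for
  that stone. It is off by default because the rules are phrased in
  terms of co-occurrence, not geometry.
* The policy reports the adjusted confidence (19.8%), not the raw one;
  the adjusted value is the one the output decision is based on, so it
  is the honest number to show.

The policy is deliberately *not* idempotent: it is a final output
decision applied once per image. Applying it twice would re-weight
already-weighted confidences.

## The phantom generator

The synthetic module emulates only the properties the pipeline needs:

* five object classes with a fixed intensity ordering — background 30,
  liver 100, muddy stone 120, gall 140, spine 220, granular stone 230
  (8-bit gray), with additive Gaussian pixel noise (sd 8). The margins
  between bands exceed two noise standard deviations, so the ordering
  "granular brighter than gall, muddy slightly darker than gall" is
  recoverable from pixels;
* spatial relations: the gall ellipse is placed tangent to the liver
  boundary (lower right); stones are placed inside the gall with
  rejection sampling so stone boxes do not overlap each other; the spine
  is a bright disk with a darker canal at the bottom centre;
* shapes: the liver is a union of overlapping ellipses; granular stones
  are 10-vertex polygons with jittered radii (±10%) and angles,
  appearing bright and irregular; the muddy stone is a single large
  low-contrast ellipse; all sizes are drawn relative to the 128-px desk
  image (512 px is supported — every size scales with the image);
* confounders: `negative_confounder` slices contain a liver with an
  interior gray patch drawn in the muddy-stone band and *no* gall —
  the exact scenario the policy's R3/R4 rules suppress.

The default scenario mix (30% granular, 20% muddy, 10% both, 30% plain
negative, 10% confounder) exercises every policy branch. Counts follow
largest-remainder rounding, and each image gets an independent
sub-seed, so the same dataset seed reproduces identical bytes.

What the phantoms do **not** model: Hounsfield-unit physics, organ
texture, partial-volume effects, patient variability, 3-D continuity
between slices. Passing tests on phantoms therefore demonstrate that
the pipeline's logic and arithmetic are correct and that the detector
can learn the stated appearance relations — not clinical performance.

## The detector

The detector is a reduced fully convolutional network in the
single-stage grid/anchor style: no pooling anywhere, downsampling only
by 3×3 stride-2 convolutions (four stages, widths 12/24/32/48 by
default), a 3×3 mixing convolution, and a 1×1 prediction head emitting,
per grid cell, three anchor-attached boxes × (4 box terms + objectness
+ 5 class scores). Box decoding is the standard log-space
transform: centre = (cell + sigmoid offset)/grid, size = anchor ×
exp(raw)/grid, all normalized by the image side; class scores are
independent sigmoids. Encoding inverts it exactly (round-trip < 1e-9).

A second, finer detection scale (`use_skip_upsample`) upsamples the
deepest features (nearest neighbour — an index copy, not pooling),
concatenates a skip connection from the previous stage and runs a small
tower (1×1 bottleneck, 3×3 convolution) before its own head. The 3×3
tower convolution is essential: without it the four sibling cells that
share one upsampled parent are indistinguishable to a 1×1 head, and
small-object confidences cannot be learned. Stones (8–14 px) are owned
by the fine scale; organs by the coarse one — each truth box is
assigned to the single scale and anchor whose prior best matches it, so
the two heads never produce rival duplicates of one object.

The input is presented as three channels: raw intensity, a 5×5
mean high-pass, and a stone-scale (13×13) running-*median* high-pass.
The contrast channels carry the "darker/brighter than surroundings"
cue that defines muddy stones; the median background is used at stone
scale because a mean would smear a dark halo around bright granular
stones, which reads as a spurious muddy signature.

Training is mini-batch Adam on the usual composite loss: squared error
on (σ(tx), σ(ty), tw, th) at responsible anchors with the small-box
emphasis factor (2 − normalized area), binary cross-entropy on
objectness, binary cross-entropy on class scores. Three refinements
that matter at this scale:

* empty cells far from any object get objectness weight `w_noobj` = 0.3,
  while *hard negatives* — cells whose anchor prior touches a truth box,
  i.e. organ interiors — keep full weight. This is what suppresses
  muddy-stone hallucinations inside plain gallbladders;
* cells under or immediately next to a truth box (at the truth's own
  best anchor) are ignored by the objectness loss rather than punished:
  their features are nearly identical to the responsible cell's, and
  punishing them caps the positive confidence the net can learn;
* class scores are additionally trained (at half weight) at every cell
  covered by a truth box, because class identity is well defined across
  the whole object: a stray firing inside a granular stone then carries
  the label "granular" and is merged away by class-wise NMS instead of
  surviving as a muddy ghost.

Training augments each image with its horizontal/vertical flips
(targets flipped accordingly), sampling one of the four variants per
epoch — quadrupled data diversity at no per-epoch cost, which at
300-image scale is what closes most of the generalization gap for the
stone classes.

Everything is seeded: weight init from the network seed, shuffling from
the training seed, augmentation choices from the same stream, and the
loss trace is reproducible run to run on one CPU. Divergence
(non-finite loss) aborts with a diagnostic rather than returning a
broken model.

## Evaluation

Matching is greedy per class in descending confidence order (ties by
input order): a detection matches the unmatched same-class truth with
the highest IoU when that IoU reaches the threshold (default 0.5);
each truth yields at most one true positive. AP integrates the monotone
(right-envelope) interpolated precision-recall curve at every distinct
recall (the 11-point variant is available by flag). mAP(all) averages
the five class APs; mAP(stones) averages exactly the granular and muddy
APs — the cholelithiasis figure of merit. Per-class APs are carried at
full precision and rounded only for display; this is why a table's
mAP(all) column can differ slightly from the mean of its *printed*
class cells.

Cross-validation partitions images into balanced folds (sizes within
1), trains on k−1 folds and evaluates the held-out fold twice: raw
detections and policy-adjusted output. It also counts held-out negative
images with stone boxes above the output threshold before and after the
policy — the negative-sample audit, which by construction can only
shrink under the policy. Slice curation applies the same
presence logic used by the policy: keep a slice iff both a liver and a
gall detection reach the presence threshold.

## Problem sizes and numerical choices

Desk-scale defaults were chosen so the full pipeline — phantom
generation, training, 3-fold cross-validation — runs on a single CPU in
minutes: 128×128 images, 300-image datasets, 100 training epochs, batch
8, learning rate 2e-3 with a 10× decay over the last quarter of
training. Both detection scales are on by default: at these object
sizes the single coarse scale cannot regress stone boxes reliably, so
the one-scale variant (`use_skip_upsample = FALSE`) is kept only as a
baseline. Degenerate inputs are rejected with messages naming the
violated constraint (stones without a gall, boxes with non-positive
extent, class indices outside 0..4, k larger than the dataset).
Ties are deterministic throughout: NMS and matching break confidence
ties by input order, anchor assignment by smallest index, fold sizes by
largest-remainder order.

## Known limitations

* The muddy stone is intrinsically the hardest class — its boundary is
  two or three noise standard deviations from the surrounding gall —
  and its AP is the binding constraint on mAP(stones); the detector's
  held-out granular AP is typically well above it.
* The phantom's appearance model is deliberately minimal; none of the
  numbers produced here are claims about clinical CT.
* The policy is exactly the stated rule system: no learned context
  model, no spatial reasoning beyond optional centre containment.
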