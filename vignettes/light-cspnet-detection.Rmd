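---
title: "A lightweight CSP detector for orchard fruit: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lightweight CSP detector for orchard fruit: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fruit detection in orchard imagery is a small-object problem under a compute
budget. Fruits span a few pixels to a few hundred, sit in overlapping
clusters, and are partially hidden by foliage; the detector is meant to run
on low-power edge hardware, so parameter count and FLOPs matter as much as
accuracy. `lightcsp` implements a single-stage anchor-based detector built
for exactly this trade-off: a lightweight cross-stage-partial (CSP)
backbone, a size-dependent down-sampling policy, three shallow detection
branches fed by a deep–shallow fusion step with dual (channel + spatial)
attention, and the standard YOLO-family decoding/NMS machinery around it.

Because no GPU deep-learning framework is involved, the whole network —
forward pass, reverse-mode gradients, SGD — runs on the CPU through the
package's own differentiation engine with compiled convolution kernels.
This caps the problem sizes that are practical (see *Problem sizes* below),
but makes every component inspectable and exactly reproducible.

## The backbone

The trunk is assembled from two ideas.

**Light-CSP block.** A standard CSP block routes features through a
transformed path and an identity path that are re-merged by a 1×1
"transition" convolution, which shortens duplicated gradient paths. The
Light-CSP block miniaturizes this to three 3×3 convolutions arranged as a
nested two-level cross stage: the input passes a 3×3 convolution to `C1`
channels (call it `X`); `X` feeds both an identity branch and a nested pair
of 3×3 convolutions to `C2` channels (`Y`, then `Z`); `concat(Y, Z)` passes
a 1×1 transition of `2*C2` filters and is concatenated with `X`. Output
width is therefore always `C1 + 2*C2`. Every convolution carries batch
normalization and Leaky ReLU (slope 0.1).

The published block equations describe the routing as a channel *split*,
but the listed filter widths and the `C1 + 2*C2` output arithmetic are only
mutually consistent if both branches see the full map; `lightcsp`
implements that duplicate-routing reading. This is the one place where the
block's textual description and its width table disagree, and the width
table wins.

**Size-dependent down-sampling.** At low down-sampling rates (large maps,
small receptive fields) plain strided convolution discards neighbour-pixel
relations that small fruits live in. The stem therefore uses a
*cross-scale-fusion* operator: a 3×3 stride-2 path and a 1×1 stride-2 path
over the full input, concatenated and merged by a 1×1 convolution — twice,
taking 416×416×3 to 104×104×64. At high rates (small maps, semantic
features) 2×2 max-pooling separates the four Light-CSP stages instead,
preserving translation invariance at zero parameter cost.

With the default widths (64,32), (128,64), (256,128), (512,256) the trunk
exposes taps of 128, 256, 512 and 512 channels at strides 4, 8, 16, 32 for
a 416 input. The deepest stage ends at its `2*C2 = 512`-channel
concatenation: in the published width table that stage's transition row *is*
the single-class detection head (512 → 18 channels), so the backbone proper
has no fourth transition. `profile_model(arch_config())` reproduces the
table row by row, and the same table ships as a machine-readable fixture in
`inst/extdata/architecture_table.yaml` that the test suite walks.

## Fusion and detection branches

Detection happens on three *shallow* branches — strides 4, 8 and 16 —
rather than the conventional deepest 13×13 scale, which is what makes the
few-pixel fruit regime detectable at all. Each branch fuses three taps: the
equal-scale map, the next deeper map (2× nearest-neighbour up-sampled) and
the next shallower map (2×2 max-pooled); the highest-resolution branch has
no shallower neighbour and fuses two. The two resampled maps pass a
channel-attention gate (CBAM-style: average- and max-pooled descriptors
through a shared bottleneck, reduction 16, summed and sigmoid-gated), the
three maps are concatenated, the concatenation passes a spatial-attention
gate (channel mean/max stat map, 7×7 convolution, sigmoid), and a 1×1
convolution merges the result into the branch feature map. The published
description names the attention inputs but not their internals; the
CBAM-style reading adopted here is the minimal standard interpretation of
"dual attention", and applying attention to the two *resampled* maps (the
equal-scale map passes unattended) matches the two enhanced features the
flow diagram shows. Whether the equal-scale map should join before or after
spatial attention is genuinely open; it joins before, so the spatial gate
sees the full concatenation.

Each branch ends in a 1×1 head convolution to `3 × (5 + nc)` channels
(three anchors; four box offsets, objectness, `nc` class scores). Decoding
follows the YOLO parameterization — `center = (sigmoid(t) + cell) * stride`,
`size = anchor * exp(t)` with `t` clamped to ±4 — followed by class-wise
greedy NMS (defaults: confidence 0.25, IoU 0.45; both CLI-exposed). Anchors
come from k-means under the `1 − IoU` shape distance with guarded
mean/geometric-mean/median updates (the guard keeps the objective monotone,
which a plain mean update does not under a non-Euclidean
distance) and five seeded restarts, sorted by area and split 3/3/3 across
the branches.

## Branch widths and the parameter budget

The reference budget for this architecture is 5.96 M parameters —
deliberately below the 6.06 M of the YOLOv4-tiny baseline it competes with.
The backbone as tabulated costs 5,606,528 parameters and the three MFDA
attention modules 86,033 (together ≈ 5.96 M — plausibly the figure the
budget was quoted from). The branch-merge convolutions and heads
necessarily add more: mirroring the tap widths (128/256/512) in the merges
would cost ≈ 0.6 M extra and break the budget, so `lightcsp` uses uniform
128-channel branches, giving 6,027,975 ≈ 6.03 M total — inside the
YOLOv4-tiny bound, 0.07 M above the printed reference value.
`param_breakdown()` reports the per-module split, and the acceptance test
prints it whenever the realized total differs from the printed one. No
width combination that is not transparently reverse-engineered from the
printed number lands within ±0.01 M, so the package keeps the principled
uniform choice.

The three ablation toggles reproduce the published component study:
baseline (conv stem + FPN fusion), + dual attention, + cross-scale-fusion
stem, + deep–shallow fusion. The FPN baseline is a standard top-down path
(1×1 laterals to 128 channels, nearest up-sampling, addition); with the
attention toggle on, channel attention gates each top-down map and spatial
attention each merged map. Parameter counts are strictly increasing across
the four variants (5.78, 5.79, 5.80, 6.03 M) while the head geometry is
identical, so the variants differ only in the components under study.

## Training

The training recipe: SGD with momentum 0.9, weight decay 5e-4 on
convolution kernels, initial learning rate 0.01, batch size 8, input scale
drawn uniformly from {320, 416, 512} every 10 iterations (the network is
fully convolutional, so scale only changes the grids), mosaic augmentation
(four sources scaled/cropped into random quadrants, boxes clipped, dropped
below 25% residual area), and a 7:3 deterministic split. The iteration
budget named in the recipe (30,000) is read as iterations, not epochs — an
epoch count that size is implausible for datasets of a few thousand images.

Two schedule details are not specified by the recipe and are package
choices: a linear 100-iteration learning-rate warm-up (without it,
lr = 0.01 occasionally diverged to NaN within the first dozen steps in CPU
probes — warm-up is the standard remedy in this model family), and an
optional cosine decay that is off by default (it degraded short overfit
runs in probes). Loss weights follow YOLOv3 conventions — the recipe does
not state a loss — with binary cross-entropy on objectness (background
weight 0.5, anchors whose shape-IoU to a box exceeds 0.5 without being its
best match are ignored) and classes, squared error on sigmoid-space center
offsets and raw log-size offsets, weight 5 on the box term, averaged over
the batch. Objectness head biases start at −4 so the untrained detector is
near-silent. Every iteration derives its RNG state from
`(seed, iteration)`, so runs are bitwise reproducible and resumable.

## The synthetic orchard generator

`render_scene()` emulates the regimes that motivate the architecture, with
exactly known labels: a low-frequency green-noise background; shaded
elliptical fruits (radial gradient + specular highlight, hue drawn from a
ripe-orange band) placed singly or in clusters of 2–4 with forced overlap;
elongated leaf-shaped occluders drawn on top; a global brightness factor.
Later shapes occlude earlier ones; a fruit's label is dropped once less
than 15% of it remains visible, and every emitted box is the exact ellipse
bounding box clipped to the image. The small-target regime (radius 3–6 px
at 416) produces boxes smaller than one stride-32 cell, which is precisely
the case the shallow branches exist for.

What the generator does *not* emulate: real texture statistics, perspective
and scale correlation, colour variety across cultivars, motion blur,
illumination gradients within a scene. Passing tests on synthetic scenes
therefore demonstrates that the architecture, losses, training loop and
metrics are implemented correctly and can fit real signal structure — not
that the published real-dataset accuracies transfer. Reproducing those
numbers requires the original datasets and GPU-scale training, which are
out of scope here.

## Problem sizes and numerical choices

All numeric work is double precision. Batch norm uses eps 1e-5 and momentum
0.03 (running statistics; unbiased variance), He-style initialization,
seeded from the architecture config. FLOPs are counted analytically by
walking the graph in shape mode: `2·k²·Cin·Cout·Hout·Wout` per convolution,
2/element for batch norm, 1/element for activations, gates, additions and
pooling comparisons, resampling free; the same walk yields the
architecture table and the exact parameter count, so profiler and network
cannot drift apart.

The test suite's training runs use a width-reduced configuration — stage
widths (8,4), (16,8), (32,16), (64,32), i.e. one eighth of the default,
with 32-channel branches and attention reduction 4 — on 16 synthetic scenes
at 160×160, batch 4, 500 iterations. These sizes are chosen so a full
overfit study (three seeds) runs in minutes on one CPU core; at the default
widths the same loop is ~50× more compute and is practical only for
single forward passes (profiling, shape contracts), which the suite also
exercises at 416.

Degenerate inputs are handled explicitly: odd spatial sizes are an error in
the cross-scale operator (never silently padded); zero-area boxes are
dropped with a warning before clustering and rejected in target encoding;
k-means ties break toward the lower centroid index and empty clusters are
reseeded from the farthest point; `exp` box offsets are clamped at ±4; with
no detections at all, precision is 1 by convention and is logged as such;
AP uses all-point interpolation (the precision envelope), and duplicate
detections of one ground-truth box count as false positives.

## Known limitations

- CPU-only: default-width training at full resolution is out of practical
  reach; the engine is intended for method study, small problems and exact
  verification, not production training.
- The FLOP convention above is one of several in circulation; compare FLOP
  figures only within this package.
- Multi-class support is implemented but the defaults and fixtures are
  single-class, mirroring the per-fruit training setting.
- Weight-file size on disk depends on serialization and is reported
  nowhere; parameter count and FLOPs are the lightness metrics.
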