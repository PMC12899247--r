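---
title: "The YOLO-WL architecture: construction, audit and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The YOLO-WL architecture: construction, audit and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yolowl)
```

## What this package is

YOLO-WL is a lightweight one-stage convolutional detector for wildlife in
UAV (drone) imagery. Animals seen from survey altitude are small — in the
reference wildlife survey data most instances are below 32 × 32 pixels —
visually similar across species, and embedded in cluttered habitat
backgrounds. The architecture answers with three ideas:

* **MSDDSC** (multi-scale dilated depthwise separable convolution) enlarges
  the receptive field cheaply: parallel depthwise 3 × 3 branches at dilation
  rates 1, 2, 3 are fused by a pointwise integration, inside the repeated
  unit of the backbone's C2f blocks ("C2f-MSDDSC").
* **MLKSA** (multi-scale large-kernel spatial attention) pools the feature
  map to per-pixel mean/max statistics, runs five parallel large-kernel
  convolutions (5/7/9/11/13), fuses them, and gates the feature map with a
  sigmoid spatial attention map.
* **SSA-PAN**, a path-aggregation neck built on the *shallow* pyramid
  P2–P4 (strides 4/8/16) instead of the conventional P3–P5, with **SGF**
  junctions that spatially re-weight each incoming feature before
  concatenation. No stride-32 feature reaches the head; the finest level
  (P2) is what makes sub-32-pixel animals detectable.

The backbone additionally uses grouped GCBS downsampling stems
(`groups = gcd(in, out)`) and LFC, a halving of the stride-32 stage's
channel width, which in the shipped manifest is simply data: rows 7–9 carry
128 channels.

This package is a *model kit*: it builds the network from a declarative
manifest, audits every layer's parameter count against the published layer
table, counts FLOPs analytically, implements box decoding, NMS and the
precision/recall/AP evaluation chain, and generates synthetic aerial scenes
so that all of it is testable without any external dataset or GPU. It is
not a production training framework.

## The manifest is the architecture

`inst/extdata/yolo_wl.yaml` transcribes the published configuration: 29
rows (0–28), each with its source rows, module, arguments and expected
parameter count, and the published totals (1,394,688 parameters, 1,394,672
of them gradient-carrying, 9.9 GFLOPs at 640 × 640). `build_model()`
constructs exactly what the manifest says; `audit_parameters()` compares
built counts row by row. Alternative widths are a manifest edit
(`scale_manifest()`), not code.

```{r audit, eval = FALSE}
model <- build_model()
audit_parameters(model)
```

### The row-5 reconciliation

The published table prints 1,048 parameters for the GCBS [64, 128, 3, 2]
row, while the gcd-grouped construction (and the identically-shaped row 7)
gives 1,408. The printed per-row sum disagrees with the printed total by
exactly 360 = 1,408 − 1,048, which identifies the printed value as a digit
transposition. The manifest therefore carries both values and the audit
reports the reconciled 1,408 with an explicit note, rather than silently
passing or failing the row.

### Bias and normalization placement

Printed counts pin down placement choices that prose leaves open. Three
rules reproduce every determined row exactly: convolutions followed by
batch normalization carry no bias; batch normalization is affine (2
parameters per channel; row 0's 464 = 432 + 32 forces this); SiLU is the
activation everywhere except inside MLKSA, which uses ReLU for its branch
and fusion convolutions and a sigmoid for the gate. In MLKSA the two fusion
convolutions keep their bias *and* batch normalization, and the final 1 × 1
gate convolution carries only a bias — the unique small placement solution
giving the printed 990, which is also independent of the input width
because channel pooling reduces everything to 2 channels first.

## Resolving the C2f-MSDDSC wiring

The published counts for the four C2f-MSDDSC rows (11,882; 82,916; 325,380;
179,330) do not follow from the module's equations alone. Two facts can be
derived exactly from the four counts:

* the stock C2f skeleton (1 × 1 split and merge convolutions) is retained
  unchanged, and
* each repeated inner unit at hidden width $h$ must cost
  $33h^2 + 40.5h + 98$ parameters.

The constant 98 equals $2 \cdot 7^2$ — a bias-free 7 × 7 convolution over a
2-channel mean/max pooled descriptor, i.e. a spatial gate of exactly the
kind the architecture uses elsewhere. The half-integer linear term forces a
width-$h/2$ stage. `search_msddsc_config()` enumerates a bounded structural
space (pre-compression ratio, number of dilation rates, retained stock
convolutions, pointwise output ratio, bias/normalization placements,
integration kernel, gate kernel) in a fixed order and returns the first
configuration minimizing the total absolute deviation from the expected
counts. Against the shipped manifest it resolves, with zero deviation, to:

* the stock bottleneck (two 3 × 3 convolutions with shortcut) retained,
* three parallel depthwise 3 × 3 branches at dilation rates 1, 2, 3
  (bias, no normalization — the single-activation reading of the branch),
* pointwise compression of each branch to $h/2$ channels (bias + BN +
  SiLU),
* a 3 × 3 integration convolution from the $3h/2$-channel concatenation
  back to $h$ (BN, no bias, SiLU),
* a 7 × 7 mean/max spatial gate on the integrated feature, and
* a residual addition.

Parameter counts cannot distinguish all structures: several other
placements in the space are count-equivalent (dilation rates in particular
are invisible to counts). The search order is therefore part of the
specification of the default: it prefers no pre-compression, fewer rates,
and the more literal placements first, and it is deterministic, so repeated
runs — and the shipped default `c2f_msddsc_config()` — always agree. The
literal equation-level block (compression → parallel dilated branches →
1 × 1 integration → residual) is available separately as `msddsc_block()`
with its own configuration object, including the optional residual
projection needed when the compression ratio is not 1.

## The SGF junctions

The neck fuses 2 or 3 feature maps per junction. The published counts are
102 for the 2-input junction and 103 for the 3-input one. A per-input gate
(sigmoid of a 5 × 5 convolution over the mean/max pooled descriptor, with
bias: 51 parameters) explains 102 as two gates exactly. Three independent
gates would give 153, not 103; the odd count decomposes uniquely in this
family as 2 · 51 + 1. The package therefore gates the two lateral inputs
and scales the direct path by a single learnable scalar. This is a design
decision forced by count evidence, not by published equations; it is the
only reading in the gate family that reproduces both printed values, and it
keeps the whole-model totals exact.

## The head, decoding and metrics

The head is the stock anchor-free decoupled design: per level a box branch
(two 3 × 3 conv-BN-SiLU at width max(16, ch₁/4, 4·reg_max), then 1 × 1 to
4·reg_max bin logits) and a class branch (width max(ch₁, min(nc, 100))),
plus a frozen 16-weight expectation projection over the regression bins —
which is exactly the published difference between total and
gradient-carrying parameters. With nc = 6 and input widths (32, 64, 128)
the closed-form decomposition 78,470 + 106,118 + 161,414 + 16 = 346,018
matches the printed row.

Decoding takes, per cell and box side, the softmax expectation over the 16
bins as the distance (in stride units) from the cell center; class scores
are sigmoids. Greedy class-wise NMS suppresses by descending score with
ties broken by detection order. AP integrates the monotone
(ceiling-from-the-right) interpolated precision envelope over all recall
points: the published definition is a continuous integral, and all-point
interpolation is its faithful discretization (not the historical 11-point
variant). mAP averages per-class AP over the classes *present in the
ground truth*; classes without ground truth are undefined and excluded.
Evaluation uses a confidence floor of 0.001 to trace full PR curves;
interactive decoding defaults to 0.25 with NMS IoU 0.45.

## FLOP accounting

`count_flops()` is analytic: one multiply-accumulate counts as two FLOPs,
a convolution costs 2 · output-elements · (in/groups) · k²; normalization,
activations, pooling and resampling are excluded. This convention is
stated because the published figure does not define one. Under it, the
model that reproduces every printed parameter count exactly measures 11.4
GFLOPs at 640 × 640, not the printed 9.9: the P2-level head alone (width-64
box branch at stride 4, fixed by the head row's exact parameter count)
accounts for about 4 GFLOPs, and the same published sources print 9.7
elsewhere for the same model and 8.2 for a baseline that standard counters
put at 8.7. The discrepancy is reported, not hidden: the audit is the
parameter table, and the FLOP figure documents its convention.

## The synthetic scene generator

`generate_scene()` emulates the statistical profile of UAV wildlife
surveys, not their appearance: multi-octave value-noise backgrounds drawn
from desert/grassland/beach palettes; elliptical animal blobs with
class-specific color and aspect ratio; six classes with a strongly skewed
frequency distribution (class 0 dominant, matching the ordering of real
survey data); a log-normal box-side distribution (median 18 px, about 87%
of raw sides below 32 px at 640 × 640 — the sub-32-pixel majority that
motivates the shallow pyramid); optional partial occlusion and brightness
jitter. Everything is deterministic given the seed, and labels are written
in normalized YOLO text format at 6-decimal precision.

What passing tests on these scenes do *not* show: robustness to real
habitat texture, inter-species visual similarity, lighting extremes, or
annotation noise. The generator's purpose is to make the machinery —
shapes, gradients, decode/NMS/AP, learnability — testable and
reproducible, not to predict field accuracy.

## Training, and what "smoke" means

The package trains by hand-rolled reverse-mode differentiation over its
layer graph (verified against central finite differences for every layer
family, including batch normalization in batch-statistics mode). The
objective is deliberately simple: each ground truth is assigned to the
center cell at the pyramid level whose stride best matches its size;
binary cross-entropy on all class logits plus an L1 penalty between the
softmax-expectation box distances and the true distances at positive
cells. This is a learnability check, not the full production training
objective (no task-aligned assignment, no IoU-based box loss).

The smoke-train study conditions are: the shipped architecture at
width multiplier 0.25 with 4 regression bins (the head branch widths scale
with the bin count, which is what makes the reduced variant genuinely
tiny), 64 synthetic 256 × 256 scenes, 200 SGD steps at batch 8, learning
rate 0.01, momentum 0.937, weight decay 5 × 10⁻⁴ (the published training
recipe's optimizer settings). The smoothed loss (running mean over 25
steps) is required to decrease strictly across 25-step checkpoints; in a
representative run it falls from about 1.37 to 0.58.

## Numerical choices and degenerate inputs

* Weights: He-normal initialization, sd = sqrt(2 / fan-in); BN γ = 1,
  β = 0; biases 0. Seeded via `build_model(seed =)`.
* Batch normalization: eps 10⁻³, running-stat momentum 0.03; inference
  uses running statistics, training uses batch statistics.
* Max operations (spatial max pooling, channel max pooling) break ties by
  first index; their backward passes route gradient to the recorded argmax.
* Inputs must be rank-4 (H, W, C, B) with sides divisible by 32; violations
  are errors naming the offending row.
* `floor(e · C) = 0` in compression, odd C2f output widths, empty kernel
  lists, dangling manifest references, and label lines with the wrong arity
  are all rejected with explicit messages.
* Degenerate metric cases: a class with ground truth but no detections has
  AP 0; a class without ground truth has no AP and is excluded from the
  mean; an empty ground-truth set is an error.

## Problem sizes used by the test suite

Unit and property tests run on widths 2–16 and spatial sizes 6–16 so that
finite-difference gradient checks and brute-force oracles stay exact and
fast; the full-width model is built (cheaply) for every parameter audit,
and forward passes of the full graph are exercised at reduced widths and
96–320 pixel inputs. The acceptance checks rebuild the full model, run the
configuration search from scratch, and train the reduced variant under the
smoke conditions above.

## Known limitations

* The MSDDSC wiring is identified only up to count-equivalence; the
  resolved structure is one principled member of the zero-deviation class.
* The FLOP figure depends on the stated convention and does not reproduce
  the printed 9.9 (see above).
* The training objective is a simplified surrogate; reported losses are
  not comparable to production detector losses.
* The generator makes no attempt at photorealism; detection accuracy on it
  says nothing quantitative about real aerial surveys.
* Forward/backward performance targets CPU experimentation at reduced
  scale, not deployment.
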