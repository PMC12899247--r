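# yolowl

An auditable R implementation of **YOLO-WL**, a lightweight one-stage
convolutional detector for wildlife in UAV aerial imagery. Animals imaged
from survey altitude are tiny (mostly under 32 × 32 pixels), visually
similar across species, and embedded in cluttered habitat; YOLO-WL answers
with multi-scale dilated depthwise separable convolutions (MSDDSC) in the
backbone, multi-scale large-kernel spatial attention (MLKSA) in front of
the head, and a shallow-pyramid neck (SSA-PAN over P2–P4, strides 4/8/16)
whose SGF junctions spatially re-weight features before fusion.

The package is a *model kit*, not a training framework. It:

* builds the full network from a declarative YAML manifest transcribing the
  published layer table (29 rows, 1,394,688 parameters, 1,394,672 of them
  trainable — the difference is exactly the head's frozen 16-weight
  expectation projection);
* audits every row's built parameter count against its expected count,
  including an explicit reconciliation of one known misprint;
* resolves the under-determined C2f-MSDDSC inner wiring by a bounded,
  deterministic count-matching search (`search_msddsc_config()`);
* counts FLOPs analytically under a stated convention
  (1 MAC = 2 FLOPs, convolutions only);
* implements box decoding (softmax-expectation over 16 regression bins),
  greedy class-wise NMS, and the precision/recall/AP/mAP evaluation chain
  with all-point monotone interpolation;
* generates seeded synthetic aerial scenes (procedural habitat textures,
  class-specific animal blobs, log-normal sub-32-px size profile, YOLO text
  labels) so everything is testable offline; and
* supports smoke-level training of reduced-width variants via hand-rolled
  reverse-mode differentiation, verified against finite differences.

The key quantities it reproduces exactly, per layer family:

| block | arguments | parameters |
|---|---|---|
| GCBS stem (`groups = gcd(in, out)`) | [3, 16, 3, 2] | 464 |
| GCBS | [16, 32, 3, 2] | 352 |
| GCBS (stride 32, LFC width) | [128, 128, 3, 2] | 1,408 |
| SPPF | [128, 128, 5] | 41,344 |
| C2f | [256, 128, 1] | 131,840 |
| C2f-MSDDSC (resolved wiring) | [32, 32, 1] | 11,882 |
| MLKSA (any input width) | [32] / [64] / [128] | 990 |
| SGF-2 / SGF-3 | [1] | 102 / 103 |
| Detect head (nc = 6, reg_max = 16) | [6, [32, 64, 128]] | 346,018 |

## Worked example

```r
library(yolowl)

model <- build_model()          # shipped manifest, resolved MSDDSC wiring
audit <- audit_parameters(model)
audit$totals[1:3]
#> $built
#> [1] 1394688
#>
#> $trainable
#> [1] 1394672
#>
#> $frozen
#> [1] 16

head(audit$rows, 3)
#>   index     module expected reconciled built delta
#> 1     0       GCBS      464        464   464     0
#> 2     1       GCBS      352        352   352     0
#> 3     2 C2f-MSDDSC    11882      11882 11882     0

as.numeric(count_flops(model, 640))   # analytic, 2*MACs, conv-only
#> [1] 11.38737
```

The audit shows every row matching its (reconciled) expected count and the
published totals; the FLOP counter reports 11.4 GFLOPs at 640 × 640 under
its stated convention (the published figure of 9.9 is not reproducible
from the published per-layer counts under any convolution-counting
convention; see the vignette for the analysis).

Generating data, evaluating a detector, and smoke-training:

```r
cmd_gen("scenes", n = 16, image_size = 640, seed = 1)
cmd_eval("scenes", oracle_detector())          # $map50 = 1, $map5095 = 1
res <- cmd_smoke_train("scenes", steps = 50)   # reduced-width variant
```

A thin command-line wrapper over the same functions ships as
`inst/cli/yolowl.R` (`audit`, `gen`, `eval`, `train` subcommands).

## Package layout

* `R/blocks_core.R` — conv/GCBS/C2f/SPPF blocks and the closed-form
  parameter-count oracle (`conv_param_count()`).
* `R/msddsc.R` — the literal MSDDSC block, the C2f-MSDDSC integration and
  the configuration search.
* `R/mlksa.R`, `R/sgf.R` — attention and fusion junctions.
* `R/assembly.R` — manifest parsing, model construction, audit, FLOPs,
  detection head.
* `R/detection_eval.R` — IoU, decoding, NMS, AP/mAP.
* `R/synthetic.R` — the scene generator and YOLO label I/O.
* `R/train.R`, `R/layers.R` — the reverse-mode layer system and the smoke
  training loop.
* `src/ops.cpp` — im2col/col2im, direct grouped convolution, pooling
  kernels.
* `vignettes/yolo-wl-architecture.Rmd` — the methods vignette: model,
  resolved design decisions, numerical choices, limitations.
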