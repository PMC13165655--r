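---
title: "Methods: quantization-robust CNN benchmarking for PPG-based blood pressure estimation"
author: "edgeBP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantization-robust CNN benchmarking for PPG-based blood pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cuffless blood pressure estimation maps a single-channel
photoplethysmography (PPG) waveform to systolic and diastolic pressure
(SBP/DBP, mmHg). Models that look accurate in floating point are not
automatically deployable on microcontrollers, where inference runs in
full-integer INT8 arithmetic: some architectures drift substantially after
post-training quantization (PTQ) while others preserve their predictions
almost exactly. edgeBP implements the complete evaluation loop needed to
study this *architecture-dependent quantization robustness* on a desk:
synthetic paired PPG/arterial-pressure (ABP) cohorts with exact per-beat
ground truth, the standard conditioning pipeline, five compact 1D CNN
families with an in-package training engine, a self-contained full-integer
INT8 engine, and the accuracy/drift/feasibility reporting around them.

## Synthetic cohort: what it emulates and what it does not

Real reference datasets for this task pair fingertip PPG with invasive ABP
at 125 Hz. The generator reproduces the *statistical envelope* that matters
to the pipeline, not hemodynamic physics:

* **Population pressures.** SBP is drawn from a normal law truncated to
  [78.25, 199.87] mmHg centred at 139.01 (an approximately bell-shaped,
  broad distribution); DBP from a shifted log-normal
  `50 + LogNormal(log(11.49), 0.55)` truncated to [50.00, 158.02] mmHg,
  giving a median near 61.49 and the markedly right-skewed shape seen in
  clinical cohorts. Only range, median and skew direction are published for
  the reference data; the scale parameters (SD 24 mmHg, sdlog 0.55) were
  chosen once to give realistic spread inside those supports and are
  frozen. Pairs are rejected until `DBP <= SBP - 10` mmHg (a minimum pulse
  pressure).
* **Beat morphology.** Each beat is an additive two-lobe shape — a systolic
  Gaussian lobe plus a delayed dicrotic lobe — rescaled per beat so its
  sampled extrema equal the beat's DBP/SBP targets *exactly*. This is a
  deliberate design choice: label ground truth becomes independent of
  morphology realism, so windowing and labeling can be tested to 1e-9.
* **Pressure-encoded PPG.** A synthetic stand-in is only useful if the
  input actually carries the regression targets, so the PPG morphology
  encodes them through physiologically motivated (if simplified) cues:
  pulse amplitude grows with pulse pressure (`0.4 + 0.6·(SBP−DBP)/150`,
  readable across records because the fixed-amplitude baseline wander
  survives per-record min-max normalization as an amplitude reference),
  the systolic lobe widens with SBP (`0.09 + 0.00035·(SBP−78)` s), and the
  dicrotic lobe shrinks with DBP (`0.5 − 0.004·(DBP−50)`, clamped to
  [0.05, 0.5]). The coefficients were chosen once for plausible
  within-support variation and frozen; they are *not* a claim about real
  PPG-pressure physiology, only a guarantee that a supervised task exists.
* **Nuisance structure.** Beat-to-beat heart-rate jitter (3%), a slow
  sinusoidal SBP/DBP drift (8 mmHg over a 60 s period), and, on the PPG
  channel only, baseline wander (0.25 pulse units at 0.25 Hz) and white
  noise (SD 0.03). Keeping ABP noise-free keeps window labels exact.
* **Deliberately invalid records.** Exact (rounded, not Bernoulli) counts
  of records that violate the retention rules — shorter than 8 minutes, or
  containing an ABP excursion above 200 mmHg — so filter tests can assert
  exact counts.

Not emulated: pulse-wave propagation and reflection, motion artifacts,
sensor-contact effects, multi-wavelength PPG, and any true
PPG-morphology-to-pressure physiology. Consequently a model trained on this
cohort learns the generator's (simple, partly amplitude-coded) association
between PPG shape and pressure; passing tests demonstrate that the
*pipeline, training and integer engines* behave correctly, and that
quantization-robustness orderings can be reproduced qualitatively — they
say nothing about clinical accuracy on real data.

## Conditioning pipeline

Records are retained only if at least 8 minutes long (60,000 samples at
125 Hz; the threshold is a `minDurationS` argument so desk-scale cohorts of
2-minute records can run the identical pipeline), with finite,
non-constant channels, and ABP never above 200 mmHg (strictly). The PPG
channel is detrended by removing the per-record least-squares line (the
conventional reading of "detrend"; a moving-average high-pass would also be
defensible but is not the default) and min-max normalized to [0, 1] per
record. Windows are 1024 samples (8.192 s) with 75% overlap (hop 256,
0-based half-open slices); each window's labels are the ABP maximum and
minimum over the same slice, so a record of N samples yields
`floor((N - 1024)/256) + 1` windows.

Splitting is *window-level* random 70/30 — deliberately mirroring the
leakage-prone protocol common for this dataset family; a subject-wise mode
exists behind a flag but is not the default. Test windows whose value
vectors are exactly identical (bit-faithful comparison via hex rendering)
to a training-pool window are removed from the test side; removing from
test rather than train preserves training-set size semantics. The surviving
pool is reshuffled 80/20 into train/validation with its own fixed seed
(42). Sizes use nearest-integer rounding with ties up.

## Model zoo

All five families take a (1024, 1) window and regress the two pressures in
raw mmHg (no label scaling). ReLU follows every convolution; no
normalization layers are used anywhere — none are part of the reference
designs, and their absence keeps the integer engine free of folding logic.
The published description fixes each family's structure but not its exact
widths; the layer widths, kernel sizes and head widths below were fixed by
a one-time constrained search so that each configuration lands exactly on
its published trainable-parameter total, and are frozen in YAML files under
`inst/extdata/architectures/`:

| name | structure | params |
|---|---|---|
| `baseline_cnn` | conv(k3) 8/24/48/80, max-pool 4 after each, flatten, dense 56, dense 2 | 33,826 |
| `residual_cnn` | 4 residual stages (two conv(k5) per block, identity shortcuts, 1x1 projection at channel changes) 20/40/124/180, max-pool 4 between stages, flatten, dense 188, dense 2 | 554,498 |
| `residual_cnn_slim` | same residual structure, 20/40/64/100, global average pooling, dense 2 | 140,034 |
| `mobilenet_1d` | conv(k3, stride 2) stem to 8 ch, then 4 stages of depthwise(k3, stride 2) + pointwise, to 16/28/72/100, GAP, dense 2 | 10,738 |
| `micro_tcn` | conv(k5, stride 2) stem to 16 ch, 4 residual blocks of two dilated causal conv(k3) with dilations 1/2/4/8, strided 1x1 downsampling between blocks, to 16/28/42/58, GAP, dense 2 | 41,698 |

The slim residual shares its first two stages with the full residual model
and narrows the last two — consistent with "reduced filters per stage" plus
the GAP head. Max pooling of size 4 is used in the baseline/residual
families; MobileNet-1D and the TCN downsample by strided convolutions.
Residual blocks keep channels constant inside the block (identity
shortcuts) and use a 1x1 projection on the shortcut where the channel count
changes — standard residual practice; the reference description is silent
on transitions.

## Training engine

No automatic-differentiation backend is available in this environment, so
the package authors both passes: forward and backward kernels for every
layer kind (Rcpp/Armadillo im2col + GEMM for convolutions; direct loops for
depthwise and pooling), verified against numerical differentiation in the
test suite. Protocols follow the published table: the baseline trains with
Adam (lr 1e-3), MSE, 400 fixed epochs; all other families with AdamW
(lr 8e-4, decoupled weight decay 1e-4), Huber loss (delta 1.0, mean over
both outputs and all samples), early stopping with best-weight restoration,
and reduce-on-plateau (factor 0.5, minimum lr 1e-6). Published patience
values are ranges ("30 to 35", "10-12"); the defaults fix 30 and 10.
Batch size 128 and seed 42 everywhere. The scheduler and stopper are pure
functions of the validation-loss sequence and are unit-tested without any
training.

Two numerical choices worth noting: the output head's bias is initialized
at the training-label means (a standard regression-head initialization;
with zero bias the first thousands of Adam steps would be spent raising a
constant toward ~139 mmHg), and weight decay is applied to all tensors
(the reference setup does not state an exclusion list).

The **fast profile** used by the test suite and the acceptance script keeps
the identical optimizer/loss/schedule protocol but caps training at 12
epochs (early-stop patience 6, plateau patience 3). Desk-scale problem
sizes are stated below; the full profile remains the default for users.

## Full-integer INT8 engine

The quantization scheme is the de-facto full-integer PTQ convention:
per-channel symmetric INT8 weights (scale `max|w|/127` per output channel,
stored range [-127, 127]), per-tensor asymmetric INT8 activations
calibrated by plain min/max (no percentile clipping) over a representative
set of 512 training windows, INT32 biases at scale `s_in * s_w`, and INT8
input and output tensors. No retraining or fine-tuning follows conversion.
Choices the published description leaves open, fixed here and pinned by
tests: rounding is half away from zero everywhere; a convolution or dense
layer feeding only a ReLU adopts the post-activation range (the ReLU
becomes an integer clamp at the zero point); max pooling and flatten
inherit their input edge and perform no requantization; global average
pooling folds the 1/L into its requantization multiplier; residual adds
rescale both addends to the output edge and saturate. Degenerate
(zero-width) ranges fall back to an epsilon scale of 1e-8, and biases
saturate at the INT32 range.

Every requantization multiplier `s_in * s_w / s_out` is decomposed at
quantization time into a 31-bit mantissa and a right shift; products are
carried in 64-bit integers with half-away rounding. In fixed-point mode no
floating-point value influences any integer tensor — the test suite jitters
every stored float field in its last ulp and asserts bitwise-identical
integer outputs. A float-multiplier path is retained for debugging and
agrees with the fixed-point path within 1 LSB (asserted over 10^6
randomized accumulator/multiplier pairs and over 100 randomized toy
networks end to end). Because the exact calibration statistic and rounding
mode of industrial converters are not published, small numeric deviations
from any particular toolchain's INT8 models are expected; the engine's
contract is internal consistency and the documented conventions above.

## Evaluation and reporting

Errors are `e = reference - estimate`. ME is their mean, SD their sample
standard deviation (n-1 denominator, exactly as defined), MAE the mean
absolute error. The flags `|ME| <= 5` mmHg and `SD < 8` mmHg (strict) are
attached as *reference benchmarks for retrospective comparison* — the
formal AAMI/ESH/ISO protocol is subject-level and prospective, and is
explicitly not assessed. FP32/INT8 consistency is the product-moment
Pearson correlation between the two representations' predictions, per
output, plus the maximum absolute prediction delta; drift is the exact
INT8-minus-float delta of each statistic. The physiological check counts
strict `DBP > SBP` violations. Distribution figures are exported as binned
tables rather than rendered plots.

Deployment feasibility is arithmetic, not measurement: the duty cycle is
`100 * latency_ms / (1000 * 8.192 s)` for a *user-supplied* latency (165.8
ms is the documented example, giving 2.0%); the weight footprint counts 1
byte per INT8 kernel element, 4 per INT32 bias, 4 per per-channel scale and
5 per activation edge; the activation peak comes from a liveness analysis
over the package's own fixed topological schedule (producer output live
until last consumer). Vendor allocators schedule differently, so these
estimates are documented formulas, not reproductions of any toolchain's
report.

## Desk-scale study conditions

The acceptance script and the heavyweight tests run one fixed protocol: a
synthetic cohort of 100 records x 2 minutes (~5,500 windows, ~3,300 of
them training), the fast training profile, 512 calibration windows, and
evaluation on the held-out test split (~1,650 windows). On one CPU this
fits in minutes per architecture. Under these conditions the package
reproduces the study's central qualitative findings: the trained slim
residual keeps FP32/INT8 Pearson correlation above 0.99 for both outputs,
and the baseline CNN shows a larger float-to-INT8 SBP mean-error shift than
the slim residual. These are seed-pinned stochastic properties of the
synthetic protocol, not numeric reproductions of results on the real
dataset — the real-data error tables are out of scope by design.

## Known limitations

* The synthetic PPG/pressure association is far simpler than physiology;
  absolute error statistics on this cohort are not comparable to real-data
  results.
* Window-level splitting leaks overlapping segments between train and test
  by construction (as in the mirrored protocol); use the subject-wise mode
  for honest generalization estimates.
* The integer engine is scalar C++ written for correctness and testability,
  not a performance-tuned kernel library.
* Serialized-model sizes in container formats, vendor code generation, and
  on-device measurements are out of scope.

```{r example}
library(edgeBP)
report <- runBenchmark(cohortSpec(nRecords = 20L, durationS = 60),
                       architectures = c("baseline_cnn",
                                         "residual_cnn_slim"),
                       profile = "fast", calibrationSize = 128L,
                       minDurationS = 60)
report@consistency
```
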