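---
title: "PSP-EffB0-MSFF: model, training recipe and evaluation conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSP-EffB0-MSFF: model, training recipe and evaluation conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pspmsff` implements an encoder–decoder network for two-dimensional liver
segmentation in abdominal MRI, built from three components: an
EfficientNetB0 encoder with four skip taps, a pyramid pooling module (PPM)
at the bottleneck, and multi-scale feature fusion (MSFF) blocks on every
skip connection, followed by a five-stage decoder. This vignette records
the model as implemented, the assumptions and conventions behind every
tunable, and what the bundled phantom experiments do and do not
demonstrate.

## The segmentation model

**Encoder.** Inputs are 256×256×3 tensors (grayscale slices replicated
across channels, see *Preprocessing*). The EfficientNetB0 backbone — a
stride-2 stem, seven stages of mobile inverted bottleneck convolutions
(MBConv) with squeeze-and-excitation, and a 1×1 head convolution to 1280
channels — produces feature maps whose resolution halves at the stride-2
stages. Skip features $S_i$ are tapped at the expansion activations of the
four stride-2 block entries (blocks 2a, 3a, 4a, 6a), i.e. the tensors just
before each downsampling depthwise convolution. For a 256×256 input this
yields maps of 128²×96, 64²×144, 32²×240 and 16²×672; those channel
counts are a structural property of the backbone and are what ties the
whole decoder budget together. The 8²×1280 head output is the bottleneck.
All encoder parameters are trainable from the start; no layer is frozen.

Pretrained ImageNet weights are not bundled and cannot be fetched in an
offline install; `build_encoder(pretrained = TRUE)` therefore warns and
falls back to the package's truncated-normal variance-scaling
initialisation (fan-out, scale 2 — the initialisation EfficientNet itself
uses). Every architecture, shape and FLOPs property is weight-independent.
Stochastic depth (drop-connect), sometimes used when training this
backbone at scale, is deliberately omitted: it is unnecessary at the
problem sizes targeted here and would complicate the determinism
guarantees.

**Pyramid pooling.** The bottleneck is pooled adaptively to 1×1, 2×2, 3×3
and 6×6 grids; each pooled map passes a 1×1 convolution to 128 channels
(BN + ReLU) and is bilinearly upsampled back to the bottleneck
resolution. Input and branches concatenate to 1280 + 4·128 = 1792
channels, reduced to 512 by a 1×1 convolution (BN + ReLU). *Adaptive*
average pooling is used so that bins that do not divide the spatial size
(3 and 6 over an 8×8 map) are well defined: output cell $i$ of $b$
averages input rows $\lfloor iH/b \rfloor$ to $\lceil (i{+}1)H/b \rceil - 1$.

A bin larger than the map it pools is a configuration error in
`ppm_forward()`. `build_model()`, however, is explicitly usable at reduced
input sizes (e.g. 64² for desk-scale training, giving a 2×2 bottleneck),
where some default bins are infeasible; it drops those bins with a warning
rather than erroring, because the reduced-size build exists precisely for
small-input experiments. An explicitly supplied oversized bin still
errors.

**MSFF skip refinement.** Each skip map $F_{in}$ (C channels) passes three
parallel branches — a 1×1 convolution, a 3×3 convolution, and a 3×3
dilated convolution with rate 2 (5×5 extent at 3×3 cost) — each producing
C channels with BN + ReLU. Branch outputs concatenate to
$F_{cat}$ (3C channels: 288, 432, 720, 2016 across the four taps), which a
squeeze-and-excitation-style gate reweights per channel:
$M = \sigma(W_2\,\delta(W_1\,\mathrm{GAP}(F_{cat})))$, with a bottleneck of
$3C/r$ hidden units ($r = 8$ by default; $r$ is exposed because common
practice varies between 4 and 16, and nothing in the design pins it). The
gated map is reduced back to C channels by a 1×1 convolution + BN and
added to a 1×1 convolution + BN projection of $F_{in}$:
$F_{out} = W_r F_{in} + \mathrm{reduce}(M \odot F_{cat})$.

The residual's channel width is the one genuinely open design point: a
literal reading of the fusion equation would project $F_{in}$ up to 3C and
emit a 3C-wide block output, but only the C-wide reading is consistent
with a decoder whose stage inputs are "upsampled decoder features plus one
skip's worth of channels" and with the block being described as returning
to its input width. The package therefore emits C channels by default and
exposes the 3C wiring as `msff_forward(wide_residual = TRUE)` for
experimentation only; `model_config()` refuses it because it breaks the
decoder schedule.

**Decoder and head.** Starting from the 512-channel PPM output, stages
1–4 bilinearly double the resolution, concatenate the matching skip
(MSFF-refined in the `full_msff` variant, raw in `skip_only`, omitted in
`no_skip`; stage 1 consumes the deepest 16² skip, stage 4 the shallowest
128² one) and refine with a single 3×3 convolution + BN + ReLU to 512,
256, 128 and 64 channels. Stage 5 upsamples to full resolution and
refines to 32 channels without a skip. A 1×1 convolution + sigmoid yields
the per-pixel liver probability. Bilinear (parameter-free) upsampling is
used; the architecture table contains no transpose-convolution
parameters, and half-pixel-centre alignment is the convention throughout
the package. The `no_skip` variant keeps the identical five-stage decoder
minus concatenations; it is an approximation of an ablation baseline whose
decoder is otherwise unconstrained.

## The compute engine

No deep-learning framework is available to this package's target
environment, so the network runs on an engine authored here:
convolutions are im2col + single-precision GEMM (depthwise convolutions
take a direct loop path), with reverse-mode gradients for every operator
(convolution, batch normalisation, SiLU/ReLU/sigmoid, concatenation,
channel gating, adaptive pooling, bilinear resampling). Correctness is
enforced by tests against a naive double-precision convolution oracle and
finite-difference gradient checks. Consequences of the single-precision
GEMM: forward results are reproducible bitwise for fixed weights and
inputs, but algebraic identities (e.g. spatial constancy through the PPM)
hold only to ~1e-6 relative accuracy.

Batch normalisation uses eps 1e-3 (the backbone's convention) and a
running-statistics update fraction of 0.1 per batch, chosen so that
inference-mode statistics converge within the short schedules used at
desk scale (they are within ~1% of their limit after ~50 steps). Momentum
is not exposed as a recipe knob because the training objective never
references it.

## Preprocessing, splitting, slice sampling

Images are bilinearly resized to the configured input size, mapped
affinely from the nominal [0, 255] range to [−1, 1] via $v/127.5 - 1$
(the preprocessing convention of the pretrained backbone family), clipped,
and replicated across three channels. Raw MRI intensities with arbitrary
dynamic range (values outside [0, 255]) are first min–max rescaled to
[0, 255]; this keeps any scanner's output usable without per-cohort
configuration. Masks are nearest-neighbour resized (no invented labels)
and binarized by "strictly positive → 1". `slice_sample` objects carry a
`preprocessed` flag so the affine map cannot be applied twice.

Patient-level splitting shuffles ids with a caller-supplied seed and
assigns $\lfloor 0.7N \rfloor$ patients to training,
$\lfloor 0.2N + 0.5 \rfloor$ (round half up) to testing, and the
remainder to validation. This rounding rule is the one that reproduces
both reference cohort tables (95 → 66/10/19, 318 → 222/32/64) from the
stated 70/10/20 percentages; the split manifest CSV makes any given split
reproducible regardless of seed choice. Per-patient slice sampling for
training takes the unique rounded values of `max_slices` evenly spaced
positions over the slice range — deterministic, endpoints always included
— while validation and testing always use all slices, including
background-only ones.

## Training recipe

Adam (β₁ = 0.9, β₂ = 0.999, eps 1e-8) minimises
$0.5\,\mathrm{BCE} + 0.5\,(1 - \mathrm{Dice}_\varepsilon)$ with Dice
smoothing ε = 1e-6 (Dice is computed per sample and averaged; BCE over
all pixels; probabilities are clipped to [1e-7, 1−1e-7] only inside the
logarithms, so the empty-mask smoothing convention is preserved). The
initial learning rate is 2e-4 with batch size 16 and at most 25 epochs.
After each epoch the validation Dice — thresholded at 0.5 and averaged
over slices, matching the inference rule — is monitored: six consecutive
epochs without improvement halve the learning rate (floor 1e-7), twelve
stop training, and the weights of the best validation epoch are restored.
"Improvement" means a strict increase beyond a min-delta of 1e-4, shared
by both schedulers. With a fixed seed and identical data, two runs produce
identical histories.

## Evaluation metrics

IoU and Dice come from pixel confusion counts; a slice whose reference
and prediction are both empty scores 1 by convention (the model is right
to predict nothing). Surface distances are computed in pixel units:
boundaries are foreground pixels with at least one background 4-neighbour
(the image border counts as background), $d(x, S)$ is the exact Euclidean
distance to the nearest boundary pixel (via an exact distance transform,
cross-checked against an all-pairs oracle at 1e-9), HD95 is the maximum
of the two directed 95th percentiles (linear-interpolation percentile),
and ASSD sums both directed distance sets over the total boundary count.
A slice is distance-valid only when both boundaries are non-empty;
aggregation averages distance metrics over valid slices only. Patient-
level summaries average per-patient means (distances over each patient's
valid slices), then take mean ± sd over patients; slice-level summaries
pool all slices. Whether overlap metrics should include background-only
slices is genuinely convention-dependent, so `evaluate_model()` exposes
`overlap_slices = "all"` (default) and `"liver_only"`.

## FLOPs accounting

`count_flops()` sums $2\,C_{in}/g \cdot K_h K_w \cdot C_{out} \cdot H_{out}
W_{out}$ over every convolution and dense layer (dense layers enter as 1×1
convolutions, depthwise convolutions contribute one input channel per
group); multiply–accumulate counts as two operations; biases,
normalisation, activations and pooling are excluded. The per-layer ledger
is additive and exportable as CSV, and the tests verify it against an
independent closed-form recomputation written directly from the
architecture constants. Under this convention the package measures, at
256×256×3: `no_skip` 12.01, `skip_only` 17.90 and `full_msff` 36.79
GFLOPs. The ordering is structural: the fused variant contains the
skip-only graph as a subgraph plus the MSFF layers, so its cost is
strictly larger by exactly the MSFF-attributed ledger entries; no additive
wiring of these blocks can make the fused variant cheaper than the
skip-only one.

## The phantom generator

`phantom_spec()` describes per-patient stacks of axial slices containing
one liver-like region: an ellipse whose radius is modulated by three
low-frequency harmonics (star-shaped, hence always a single connected
component), with centre, area and modulation phase drifting smoothly
across slices so neighbouring slices are correlated and slice- vs
patient-level aggregation differ measurably. Images are two-level
intensity fields (background/foreground gap = `contrast`) shaped by a
multiplicative low-frequency bias field, plus Gaussian noise, clipped to
[0, 255]. A configurable fraction of slices at both stack ends has empty
masks, mimicking slices above and below the organ. Two presets mirror the
qualitative T1/T2 contrast difference: `"t1"` (background 60, contrast
+90, noise sd 8) and `"t2"` (background 140, contrast −70, noise sd 12).
Defaults — 20 patients, 10 slices each, 128² pixels, foreground fraction
in [0.05, 0.35], 20% background slices — are desk-scale choices meant to
exercise every pipeline stage, not to claim realism.

What the phantoms deliberately do not emulate: multi-organ anatomy and
liver-adjacent structures of similar intensity (the hard part of real
boundary delineation), scanner-specific noise spectra and artefacts,
inter-patient anatomical variability beyond affine/harmonic deformation,
and physical voxel spacing. Passing the phantom experiments therefore
demonstrates that the architecture, losses, schedulers and metrics are
correctly wired and can fit and generalise on coherent image/mask
distributions — it says nothing about segmentation quality on clinical
MRI, which additionally requires pretrained weights and real training
data.

## Desk-scale experiment sizes

The bundled experiments run the full pipeline at reduced input size,
chosen so a laptop-class single core completes them comfortably: an
overfit probe (8 liver slices as train = val, 64² input, batch 2, a
200-step budget under the full recipe) that must exceed validation Dice
0.95, and a generalisation run (20 phantom patients split 14/2/4 at the
patient level, 6 slices each, 64² input, ≤ 5 epochs) that must exceed
test Dice 0.85 on held-out patients. All architecture and FLOPs checks
run at the full 256² input. These sizes are the package's own test-design
choices; the training recipe itself is unchanged by them.

## Known limitations

- CPU-only and sized for method verification, not for training on real
  cohorts; no mixed precision, no multi-device support.
- No pretrained encoder weights offline; transfer-learning behaviour is
  out of scope of the test suite.
- 2-d slice-wise operation: no volumetric context or 3-d metrics.
- Surface distances are pixel-unit only; physical-unit (mm) distances
  require voxel spacing metadata the pipeline does not ingest.
- DICOM ingestion and cross-scanner intensity harmonisation are out of
  scope; NIfTI volumes and PNG/TIFF slice directories are the supported
  layouts.
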