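# pspmsff

Two-dimensional liver segmentation for abdominal MRI with the
**PSP-EffB0-MSFF** architecture: an EfficientNetB0 encoder with four skip
taps, a pyramid pooling module (PPM) at the bottleneck, **m**ulti-**s**cale
**f**eature **f**usion (MSFF) blocks on every skip connection, and a
five-stage decoder. The package is aimed at researchers who want to study,
train or ablate this architecture on slice-wise liver data — or verify its
published structure — from plain R, with no GPU, no external framework and
no data download.

It ships the complete pipeline around the network:

- **Model** — `build_model()` assembles the encoder, PPM and decoder in
  three ablation variants (`full_msff`, `skip_only`, `no_skip`); the
  compute engine (convolution, batch norm, pooling, bilinear resampling,
  with reverse-mode gradients) is implemented in Rcpp/Armadillo and
  validated against naive oracles and finite differences.
- **Data** — NIfTI volume pairs or PNG/TIFF slice directories
  (`read_slice_stack()`), the preprocessing chain (bilinear resize,
  `v/127.5 − 1` intensity mapping, channel triplication, mask
  binarization), patient-level 70/10/20 splitting (`split_patients()`)
  and deterministic uniform slice sampling (`sample_slices()`).
- **Training** — Adam on the combined BCE + Dice loss (λ = 0.5 each),
  learning-rate halving after 6 stagnant validation-Dice epochs (floor
  1e-7), early stopping after 12, best-weight restoration, multi-seed
  summaries (`train_model()`, `train_multiseed()`).
- **Metrics** — IoU, Dice, 95th-percentile Hausdorff distance and average
  symmetric surface distance in pixel units, with slice- and
  patient-level aggregation (`overlap_metrics()`, `surface_distances()`,
  `evaluate_model()`).
- **FLOPs** — an analytic per-layer ledger under the convention
  `FLOPs = 2·C_in·K_h·K_w·C_out·H_out·W_out` (`count_flops()`).
- **Phantoms** — a seeded generator of liver-like per-patient slice
  stacks (`phantom_spec()`, `make_phantom_dataset()`) so the whole
  pipeline is exercisable end to end offline.

## The model in brief

For an input $x \in \mathbb{R}^{256\times256\times3}$ the encoder produces
$F_i = \mathrm{EncoderBlock}_i(F_{i-1})$ with skip taps $S_i = F_i$ at
resolutions $128^2{\times}96$, $64^2{\times}144$, $32^2{\times}240$,
$16^2{\times}672$ and an $8^2{\times}1280$ bottleneck. The PPM pools the
bottleneck to bins $\{1,2,3,6\}$, convolves each to 128 channels,
upsamples, concatenates (1792 channels) and reduces to 512. Each skip
passes an MSFF block

$$F_{cat} = [\,\mathrm{Conv}_{1\times1}(S_i) \,\|\, \mathrm{Conv}_{3\times3}(S_i)
\,\|\, \mathrm{Conv}_{3\times3,d=2}(S_i)\,] \in \mathbb{R}^{H\times W\times 3C},$$
$$M = \sigma(W_2\,\delta(W_1\,\mathrm{GAP}(F_{cat}))), \qquad
F_{out} = W_r S_i + \mathrm{reduce}(M \odot F_{cat}),$$

returning to $C$ channels. The decoder doubles resolution five times
($8^2 \to 256^2$), concatenating $F_{out}$ of the matching scale at stages
1–4 and refining with a single 3×3 convolution + BN + ReLU to
512/256/128/64/32 channels; a 1×1 convolution + sigmoid emits the liver
probability map, thresholded at 0.5.

## Worked example

```r
library(pspmsff)

## 1. generate a phantom cohort and split it at the patient level
spec <- phantom_spec(n_patients = 10, slices_per_patient = 6,
                     image_size = 96, seed = 42)
ds <- make_phantom_dataset(spec)
sp <- split_patients(ds$manifest$patient_id, seed = 42)
print(sp)
#> <patient_split> train=7 val=1 test=2 (seed 42)

## 2. build the full model and inspect its cost
model <- build_model(model_config(variant = "full_msff", input_size = 256))
print(model)
#> <psp_model> variant=full_msff input=256x256 params=27,009,805 convs=120 GFLOPs=36.79
print(count_flops(model))
#> FLOPs ledger: 120 layers, total 36788803840 FLOPs (36.79 GFLOPs)

## 3. segment a slice and score it against the reference
vol <- ds$volumes[[1]]
s <- make_slice_sample(vol, 3, size = 256)          # preprocessed sample
prob <- predict(model, s$image)                      # 256 x 256 x 1 x 1
pred <- (prob[, , 1, 1] >= 0.5) * 1
unlist(overlap_metrics(pred, s$mask))
#>       iou      dice
#> 0.2288443 0.3724545
unlist(slice_metrics(s$mask, s$mask)[, c("iou", "dice", "hd95", "assd")])
#>  iou dice hd95 assd
#>    1    1    0    0
```

The untrained (randomly initialised) model scores IoU ≈ 0.23 on the
phantom slice — the probability map is near-uniform, so roughly the
foreground-fraction worth of pixels crosses the threshold — while the
identity comparison shows the metric conventions (perfect overlap, zero
surface distance). Training closes that gap: the desk-scale run in the
test suite reaches validation Dice > 0.99 when overfitting 8 slices and
test Dice ≈ 0.93 on held-out phantom patients after 4 epochs.

The patient split reproduces the reference cohort tables exactly:
`split_patients()` over 95 patients gives 66/10/19 and over 318 gives
222/32/64.

A command-line wrapper over the same functions is installed at
`system.file("cli", "pspmsff.R", package = "pspmsff")` with subcommands
`phantoms`, `split`, `build`, `train`, `eval`, `predict`, `flops`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pspmsff.R",package="pspmsff"))')" \
  build --variant full_msff --input-size 256
```

## Layout

```
R/            autograd engine, encoder, PPM, MSFF, decoder, data IO,
              phantoms, metrics, training, CLI
src/          im2col/GEMM convolution and resampling kernels (Rcpp)
tests/        testthat suite incl. oracle and end-to-end learning checks
scripts/      acceptance.R
vignettes/    methods vignette (model, conventions, design decisions)
inst/cli/     command-line wrapper
```
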