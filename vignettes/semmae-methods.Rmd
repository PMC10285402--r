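---
title: "Masked-autoencoder pre-training for serial-section EM: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked-autoencoder pre-training for serial-section EM: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semmae)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, and the places where a
genuinely open design choice had to be made.

## 1. The problem and the model

Serial scanning EM produces anisotropic 3D stacks — xy resolution of a few
nanometres, z resolution set by section thickness, typically 5–10x coarser.
Dense instance segmentation of such stacks (neurites, mitochondria) is the
bottleneck of connectomic reconstruction, and the supervised networks that
perform it are label-hungry. The package implements self-supervised
pre-training of a vision-transformer encoder by masked autoencoding
directly on the unlabeled volumes, followed by supervised fine-tuning of a
UNETR-style segmentation network initialized from that encoder.

The masked autoencoder consists of:

- **Patch embedding** (`patchify()`, `posembed_3d()`): non-overlapping
  `1 x 16 x 16` patches. The z patch extent of 1 keeps the effective voxel
  of a token close to cubic; it is configurable but `pz = 1` is the
  normative default. Token order is fixed (z-major, then y, then x, with x
  fastest) and every mask plan indexes into that order.
- **Mask sampling** (`plan_random()`, `plan_space_only()`,
  `plan_section_only()`): the visible count under random sampling is
  `floor((1 - r) * N)` — the only convention that keeps 21 of 216 tokens at
  r = 0.90, which we treat as normative. Space-only and section-only
  sampling take *counts* rather than ratios because their feasible ratios
  are quantized to `1 - k/n`; `ratio_to_keep()` converts a requested ratio
  to the nearest feasible count, breaking ties toward more masking.
- **Encoder/decoder** (`mae_encode()`, `mae_decode()`): the encoder runs on
  visible tokens only; the decoder is deliberately smaller (default depth 4,
  width 512 against ViT-Base's 12/768) and sees the full sequence with one
  learned mask token in every masked slot. Over-sized decoders are known to
  degrade the encoder's transferable representation, which is why decoder
  capacity is a first-class configuration knob.
- **Loss** (`recon_loss()`): MSE against per-patch-normalized targets,
  averaged over masked patches only. Normalization uses the biased standard
  deviation with an epsilon floor of `1e-6`; the biased/unbiased choice is
  not material (patches have 256 voxels) but is fixed and documented for
  reproducibility.

### Positional embeddings

The 3D sin-cos table is built by concatenating three 1D sin-cos embeddings
(z, y, x), each over absolute grid indices with `2*floor(d/6)` dimensions.
Widths not divisible by 6 are zero-padded in the trailing columns rather
than rejected: the standard ViT widths (64 for the micro preset, 1024 for
ViT-Large) are not multiples of 6, and padding preserves row distinctness,
which the tests verify exhaustively. The decoder uses a sin-cos table
generated directly at decoder width — an equivalent fixed deterministic
table; inserting an unlearned projection of the encoder-width table would
add an arbitrary random matrix with no benefit.

## 2. Fine-tuning and decoding

`build_seg_model()` transplants the (optionally pre-trained) encoder into a
U-shaped network. Skip taps sit at blocks `round(depth * c(1,2,3)/4)` plus
the final output (3/6/9/12 for depth 12, proportionally scaled otherwise);
the tap indices are not prescribed by the UNETR design we follow, so the
proportional rule is our stated choice. Because `pz = 1` while the xy
stride is 16, the convolutional decoder upsamples only in y and x (four
2x stages of `1 x 3 x 3` convolutions); z stays at full resolution
throughout. This is forced by the anisotropic embedding and is normative.

Training targets are generated on the fly from the label crop:

- **Affinity maps** (`affinity_from_labels()`): the three nearest-neighbour
  offsets only; long-range affinities are out of scope. The loss is
  class-balanced binary cross-entropy — positives and negatives reweighted
  to equal total mass. The configurations this follows are weighted in the
  original affinity literature, and unweighted BCE measurably collapses to
  the majority class at small iteration budgets.
- **BCD** (`bcd_from_labels()`): binary map; contour as foreground voxels
  within `contour_width` (Chebyshev, xy-plane) of a differently-labeled
  voxel; distance as the per-instance-normalized Euclidean distance to the
  nearest differently-labeled voxel. The contour test is xy-only by default
  (`include_z = FALSE`): with z sampled 5–10x coarser than xy, the z-faces
  of thin instances would otherwise all become contour and sever instance
  interiors, breaking marker-based decoding; per-slice contours are the
  community practice for anisotropic EM. Out-of-volume never counts as a
  boundary, for either contours or distances. Per-instance distance
  normalization (instead of a global maximum) makes large and small
  instances contribute comparably to the regression loss.
  The BCD loss is BCE + BCE + MSE with equal weights — the weighting is not
  prescribed by the sources we follow, so 1:1:1 is our stated choice.

Decoding (`zwatershed()`, `decode_bcd()`) is deterministic: every priority
tie breaks by raster order of the voxel (or edge) index, and final label
ids are canonicalized by first-voxel raster order. The zwatershed
parameters (`t_high = 0.9`, `t_low = 0.1`, `min_size = 128`,
`merge_threshold = 0.3`) are community-typical values, all exposed in
configuration; on ground-truth targets the result is
threshold-insensitive. Small fragments merge into the neighbour with the
strongest connecting edge through a union-find (so mutually-pointing small
fragments merge cleanly), and agglomeration proceeds in passes: boundary
mean affinities are computed once per pass, pairs at or above threshold
merge together, and passes repeat until stable.

### Optimizer recipes

The configuration layer ships two reference recipes as defaults, applied
when the corresponding keys are absent from the YAML:

| phase | optimizer | base lr | weight decay | warmup / total | batch | extras |
|---|---|---|---|---|---|---|
| pre-training | AdamW (0.9, 0.95) | 1e-4 | 0.005 | 50k / 400k | 128 | no dropout |
| fine-tuning | AdamW (0.9, 0.95) | 1e-4 | 0.05 | 5k / 200k | 8 | dropout 0.3, drop-path 0.1 |
| fine-tuning (organelle variant) | SGD | 4e-3 | 1e-4 | 10k / 300k | 8 | scales [1, 0.5, 0.5] |

The schedule is linear warmup to the base rate followed by cosine decay to
zero — the standard recipe, stated here because the sources cite it without
formulas. Decoupled weight decay applies to weight matrices only, not to
biases, norms or the mask token. `scales = c(1, 0.5, 0.5)` halves y and x
(2x2 mean pooling for images, subsampling for labels) before cropping,
matching the organelle-task convention; z is never rescaled.

## 3. The synthetic generator

`make_instances()` places random-walk tubes (neurite-like) and ellipsoids
(mitochondria-like) — both structure classes of the downstream tasks — with
geometric anisotropy: z extents are ~0.35 of xy radii, so objects span
several sections but are flatter in z, as in serial-section data.
Instances never overlap and are separated by a 1-voxel background membrane
line, as in SNEMI-style ground truth where the dark boundary voxels carry
no instance id; each instance is 6-connected, spans at least two sections,
and has at least `min_voxels = 150` voxels (real instances at this
resolution are far larger than watershed size filters).
`render_em()` draws membranes dark (`0.15`), interiors bright (`0.75`),
far background slightly above membrane level, adds Gaussian noise
(`sigma = 0.06`) and clips to `[0, 1]`. Rendering depends only on label
geometry, never on ids — a tested invariant.

What this emulates: the contrast polarity, anisotropy, membrane-separated
instance packing (foreground fraction ~0.2–0.35 at the default density) and
noise level of serial SEM. What it does not: realistic intracellular
texture, imaging artifacts (charging, folds, stitching seams), z-blur, or
the morphological complexity of real neuropil. Passing tests on this data
therefore demonstrate that the pipeline's machinery is correct and that
pre-training transfers signal at desk scale — not that the specific
accuracy numbers would carry over to real volumes.

## 4. The desk-scale transfer experiment

`transfer_experiment()` is the CPU-sized analogue of the
pretrain-versus-scratch comparison. Per seed pair it generates a training
and a held-out test volume (`16 x 64 x 64`, 35 instances, xy radii 6–10),
pre-trains a `vit-micro` MAE (300 iterations, random masking at 0.9, batch
4), then fine-tunes two affinity models for 300 iterations each — one from
the pre-trained backbone, one from scratch — sharing the fine-tuning seed
and an identically-initialized decoder, so the arms differ only in backbone
initialization. Desk-scale choices, made once: crops of `6 x 32 x 32`
(a 6x2x2 token grid), base learning rate 3e-3 for both phases (small
models at short budgets need a larger rate than the reference recipes),
batch 1 for fine-tuning, dropout and drop-path off (regularization is
counterproductive at 300 samples), and decoding at `t_high = 0.8`,
`t_low = 0.2`, agglomeration 0.9 — thresholds suited to the soft
calibration of briefly-trained models, shared by both arms. Problem sizes
were chosen so the four-pair experiment completes in about ten minutes on
one CPU.

## 5. Numerical choices and degenerate inputs

- Attention softmax subtracts the row maximum; GELU is exact
  (`x * pnorm(x)`).
- All gradients are hand-derived and pinned by central-difference tests at
  `1e-6` step size in both the MAE and the segmentation network.
- A mask plan always keeps at least one visible token
  (`floor((1-r)*N)` is clamped to 1), and `recon_loss()` rejects plans with
  no masked tokens.
- Training aborts with the iteration index on a non-finite loss.
- `mae_pretrain()` checkpoints carry optimizer and RNG state, so resuming
  reproduces an uninterrupted run bit-for-bit on a single worker.
- Instances with no reachable boundary (filling the whole crop) take
  distance 1 everywhere; single-voxel instances are binary = contour =
  distance = 1 — the degenerate normalization limits.
- Watershed tie-breaks, fragment-merge targets and label canonicalization
  are all raster-ordered, making every decode bit-reproducible.
- Evaluation restricts VI and adapted Rand to truth-foreground voxels
  (`T != 0`, configurable off). "A-Rand" is the adapted Rand *error*
  (1 − F), the lower-is-better convention of the segmentation leaderboards;
  entropies are in nats. Instance AP uses voxel count as the ranking score,
  since no per-instance probability survives watershed decoding.

## 6. Known limitations

- The transformer and convolution stacks are plain-R/OpenBLAS and compiled
  helpers; they are sized for desk-scale experiments (tiny presets,
  hundreds of iterations), not for reference-scale training, although all
  reference hyperparameters are expressible in configuration.
- Only nearest-neighbour affinities are produced; long-range affinity
  variants are out of scope.
- The HDF5 reader handles one named 3D dataset per file (the connectomics
  convention), not chunked cloud-scale stores.
- The pretrain-vs-scratch comparison is a stochastic property over seed
  pairs; individual pairs can invert, which is why the experiment reports
  all pairs rather than a single difference.
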