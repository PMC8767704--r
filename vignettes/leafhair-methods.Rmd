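---
title: "Scoring leaf hairiness from microscope images: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring leaf hairiness from microscope images: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cotton breeders score leaf pubescence on an ascending, non-linear ordinal
scale from 1 (glabrous) to 5+ (pilose), with seven intermediate scores
(`2, 3, 3/4, 4, 4/4+, 4+, 5`). The trait matters at both extremes —
glabrous lines lose fibre yield and insect resistance, pilose lines
attract whitefly and promote gin trash — so breeders select intermediate
(hirsute) material. The traditional assessment is visual, slow and
operator-biased. `leafhair` implements a four-part image-classification
pipeline that reproduces this scoring from abaxial leaf microscope
images: data augmentation, a convolutional feature extractor, a single
fully connected scoring layer, and a leaf-level scoring module. Around
the model it implements the supporting machinery that makes such a
pipeline trustworthy: leaf-group-exclusive dataset splitting, genotype
de-identification, and a synthetic data generator so that every stage is
testable offline.

## The model

An input image is resized to a square (448 px at full scale; the resize
deliberately stretches rather than pads — the alternative is not
documented in the source protocol, and stretching is the recorded
choice), normalised with the ImageNet channel statistics (the statistics
of the corpus used for optional pretraining), optionally augmented, and
passed through a residual network (depths 18/34/50/101/152) whose final
fully connected layer is removed. The global-average-pooled output of
the last convolutional stage — 512 features for depths 18/34, 2048 for
deeper bottleneck variants — feeds a single fully connected layer
initialised with Kaiming-Uniform (weights within `±sqrt(6/fan_in)`),
emitting one pre-softmax score per class. Training minimises multi-class
cross-entropy; the class count is inferred from the classes present in
the training split. The headless depth-34 backbone counts exactly
21,284,672 trainable parameters (21.28M); the depth-101 headless count
computes to 42,500,160, i.e. 42.50M against a reported 42.51M — the
0.01M discrepancy is unexplained upstream and the depth-34 figure is
used as the parameter-count oracle.

Three accuracies are reported. **IA** (image accuracy) is the fraction
of test images scored correctly. **FIA** (first image accuracy)
restricts IA to each leaf's most proximal image (vein 1, position 1) —
the practically relevant single-image regime. **LA** (leaf accuracy)
assigns each leaf the most common predicted score among its test-side
images; when several scores tie for the maximal count, the smallest
score wins. The published rule covers only the two-way tie; extending
"the smallest score was selected" to ties among three or more classes is
this package's design choice, validated against brute-force enumeration
over all prediction multisets of size ≤ 5.

## Split grammar

Images of one physical leaf are near-duplicates, so the atomic unit of
splitting is the leaf group: no leaf contributes images to both sides of
any split. The whole-dataset split sends a random 20% of leaf groups
(rounded half up; the protocol says only "approximately 20%") to test.
For each two-category factor — leaf number (L3/L4), year (Y1/Y2),
environment (GH/FD) — six named splits are generated: mixed (`AB/A`,
`AB/B`), intra (`A/A`, `B/B`) and inter (`A/B`, `B/A`). Inter-year
splits first drop genotypes not grown in both years, then drop score
classes not present on both sides of the reduced list, which yields the
7 common classes for the published composition. Selection operates on
lexicographically sorted leaf ids shuffled under a seed, so splits are
invariant to manifest row order. Repeated validation splitting re-samples
the 80% training side k times into 20/80 pairs — independent resamples,
not a disjoint partition, which is what makes each pair cover 16%/64% of
the whole dataset.

Leaf-group selection is uniform over groups, not weighted by group size;
the protocol notes group sizes are similar on average, and weighting is
not described.

## De-identification

Genotype identity is commercially sensitive, so public artifacts carry
colornames instead. The map is built by shuffling a fixed palette under
a seed and zipping it against lexicographically sorted genotype
identifiers — deterministic and auditable; whether the original
assignment was random or curated is not documented, so seeded-random is
the recorded choice here. Applying the map replaces genotypes and drops
any columns outside the manifest schema; the inverse map recovers the
original names exactly. Image metadata is stripped at the container
level (PNG ancillary chunks, JPEG APPn/COM segments) without re-encoding
pixels, so pixel data is bit-identical by construction. The three-way
storage separation of original data, de-identified data and master map
is organisational; the code enforces only its local corollary — it
refuses to write the master map into the directory holding de-identified
outputs.

## The synthetic generator: what it emulates, what it does not

The generator states a world with the published dataset's *structure*:
a green textured background; one mid-vein entering at the left border
and exiting at the right (never top/bottom); 9–15 images per leaf laid
out as 3–5 positions along 3 veins with the vein-1/position-1 image
flagged `is_first`; multiple leaves per genotype across years and
environments; and per-(year, environment) style shifts — a global
brightness offset and extra dark clutter for field images — so that
inter-environment transfer faces a real domain gap (its magnitude is a
free parameter; the source does not quantify the visual difference).
Hairiness classes are realised purely as stroke density and length:
expected stroke count is `hair_density_base × density_mult[rank+1]`,
with `density_mult = (0, 1, 2.2, 3.8, 5.8, 8.4, 11.5, 15, 19)` chosen
once as a geometric-ish ladder (adjacent ratios 1.27–2.2, within-class
lognormal CV 4%) — "well-separated" in the sense that adjacent class
means sit many within-class standard deviations apart. Rank 0 is
glabrous: exactly zero strokes. Default images are 256 × 192, an
aspect-preserving 1/10 of the source instrument's 2560 × 1920; full
size is a config override.

A green test on this world establishes that the pipeline's mechanics
work end to end — that the model can recover a monotone visual density
signal through the augmentation, training, splitting and scoring
machinery. It does **not** establish phenotyping accuracy on real
leaves: no trichome geometry, no specular optics, no real pixel
statistics, no label noise from human scorers. The published real-data
accuracies (89% per image, 95% per leaf on the whole dataset) require
the real 13,597-image dataset and GPU training of a pretrained depth-34
backbone, and are deliberately not reproduction targets here.

## Numerical and engineering choices

* **No deep-learning runtime exists in the target environment**, so the
  network engine is implemented in base R: im2col convolution backed by
  BLAS matrix products, with the input gradient of stride-1
  convolutions computed as a convolution with the spatially flipped,
  channel-transposed kernel (avoiding scatter loops). Gradients are
  verified against central finite differences at tolerance `1e-4`.
* **Training is supported for the sequential `"tiny"` backbone only** —
  four 3×3 conv blocks (widths 12/24/48/96, ~55k parameters) with leaky
  ReLU (slope 0.1), 2×2 average pooling and global average pooling. The
  residual depths build, count parameters and run inference; training
  them from scratch in interpreted R is outside any sane CPU budget and
  the desk-scale acceptance suite trains only the tiny backbone. Leaky
  ReLU is a robustness choice: at 12 first-layer channels a few dead
  ReLU units can cripple a 10-epoch run.
* **Desk-scale training defaults**: Adam, learning rate `2e-3`, batch 8,
  10 epochs, 64 px inputs, random vertical + horizontal flips, and
  Polyak (exponential moving, decay 0.99/step) weight averaging for the
  evaluated model. The protocol's own `1e-4` default belongs to
  fine-tuning a pretrained deep backbone; training a 55k-parameter
  network from scratch in 10 epochs needs a larger step, and short runs
  have a noisy optimization endpoint that Polyak averaging smooths
  without using any validation data or early stopping (the departure
  from plain final-epoch weights is deliberate and switchable via
  `weight_averaging = FALSE`). Batch norm was evaluated for the tiny
  backbone and rejected empirically: on this mean-coverage signal it
  converged more slowly at every learning rate tried (final loss ~0.6
  vs ~0.2 without); the implementation remains (gradient-checked) for
  the residual architectures.
* **Rotation** is read as degrees of arc although the source prints
  "+30 and −30 °C"; corners exposed by rotation are filled with the
  normalisation channel means so no artificial dark-corner cue is
  injected; interpolation is bilinear for resize and rotation
  ("down sampling" is not further specified upstream).
* **Optimizers**: Adam/AdamW (β₁ 0.9, β₂ 0.999, ε 1e-8; AdamW decay
  0.01 decoupled), RMSProp (α 0.99), plain SGD. Per-run seeds are
  `base + run_index`, and a model is the final-epoch weights — no early
  stopping is described upstream.
* **Ties and degenerate inputs**: `round(0.2 × L)` test groups rounds
  half up; a split needs ≥ 2 leaf groups; a leaf whose first image is
  absent from an evaluation is an error, never a guess; an empty test
  side is flagged in the split report rather than raised, so reports can
  describe broken splits.
* **The published composition table contains one internal
  inconsistency**: its Y2/L4 cell prints 4364 images where both its row
  total (6869 − 2235) and year total (9300 − 4666) force 4634. The
  bookkeeping replica uses 4634, which is what makes the printed totals
  (13,597 images, 1386 leaves) close exactly.
* **The genotype grid is a synthetic reconstruction.** The flattened
  published table does not preserve which conditions each genotype
  occupied; `cotton_genotype_grid()` reproduces every printed marginal
  (27 genotypes; 10/10/26/16/8 genotypes per condition column; 7 score
  classes in Y1, 9 in Y2; class "2" a single Y2-only genotype; 1–5
  genotypes per class) without claiming to be the authors' exact grid.

## Known limitations

* Training deep residual backbones is out of scope (inference only).
* Pretrained ImageNet weights are an optional external asset; nothing
  ships with the package and all tests run from random initialisation.
* The synthetic domain gap between glasshouse and field is a single
  brightness/clutter knob, enough to exercise the split grammar but not
  calibrated to the real physiological differences.
* JPEG metadata stripping removes whole APPn/COM segments; exotic
  vendor metadata embedded inside retained segments (e.g. inside scan
  data) would survive, though none is written by standard encoders.
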