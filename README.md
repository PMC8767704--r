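# leafhair

Ordinal scoring of cotton leaf hairiness (pubescence) from abaxial
microscope images, in R.

## The problem

Leaf hairiness regulates transpiration, sunlight penetration and insect
resistance, and in cotton it also affects fibre yield and value: glabrous
(hairless) lines lose yield and are attacked by jassids and bollworms,
while pilose (very hairy) lines attract silverleaf whitefly and promote
gin trash. Breeders therefore score the trait on an ascending, non-linear
ordinal scale

```
1 < 2 < 3 < 3/4 < 4 < 4/4+ < 4+ < 5 < 5+
```

and select intermediate material. The traditional score is assigned by
eye, on sunny days, by experienced staff — slow and operator-biased.

`leafhair` is a complete re-implementation of a four-part deep-learning
pipeline that replaces that visual call, for researchers in plant
phenotyping and breeding informatics:

1. **Data augmentation** — deterministic resize (to 448×448 at full
   scale) and ImageNet-statistics normalisation, plus optional random
   vertical/horizontal flips (p = 0.5), random crop (512→448), random
   rotation (±30°) and Gaussian noise;
2. **Feature extraction** — residual networks of depth 18/34/50/101/152
   with the final classification layer removed (feature dimension
   512/512/2048/2048/2048; the headless depth-34 backbone counts exactly
   21,284,672 ≈ 21.28M trainable parameters), plus a `"tiny"` 4-block
   CNN (~55k parameters) for CPU-scale training — the network engine is
   pure R + BLAS, no deep-learning runtime required;
3. **Classification** — one fully connected Kaiming-Uniform-initialised
   layer sized to the number of score classes, trained with
   cross-entropy (Adam/AdamW/RMSProp/SGD);
4. **Leaf scoring** — Image Accuracy (IA), First-Image Accuracy (FIA,
   one most-proximal image per leaf) and Leaf Accuracy (LA, per-leaf
   majority vote with smallest-score tie-break), normalized confusion
   matrices and adjacent-class error analysis.

Around the model it implements the supporting machinery: the full
**leaf-group-exclusive split grammar** (whole-dataset 80/20; mixed,
intra- and inter-splits over leaf number, year and environment,
including the reduced inter-year candidate list; repeated 20–80
validation-train resampling), a **two-step de-identification protocol**
(genotype → colorname master map + container-level EXIF/metadata
stripping), and a **procedural synthetic leaf-image generator** so that
the entire pipeline trains and tests offline with no dataset download
and no GPU.

## Worked example

Generate a small labelled synthetic dataset (9 score classes, one
genotype per class, 3 plants × leaves 3 and 4 → 54 leaves), split it
leaf-exclusively, train the tiny backbone for 10 epochs and score it:

```r
library(leafhair)

manifest <- generate_dataset(default_panel(),
                             synth_config(plants_per_genotype = 3, seed = 11),
                             out_dir = "synth_demo")
nrow(manifest)                         # 656 images
length(unique(manifest$leaf_id))       # 54 leaves

split <- make_split(manifest, test_fraction = 0.2, seed = 5)
cfg <- train_config(learning_rate = 2e-3, epochs = 10, batch_size = 8,
                    augmentation = augment_config(ops = c("rv_flip", "rh_flip"),
                                                  target_size = 64),
                    network = network_config("tiny"), seed = 100)
run <- train_model(manifest, split, cfg)   # ~2-3 min on one CPU
run$report
#> <accuracy report whole: IA 0.9845, FIA 1.0000, LA 1.0000 (off-by-1 0.0155, beyond 0.0000)>
```

Every misprediction above lands in an adjacent class (`off-by-1` equals
the whole misprediction fraction) — the model learns the ordinal
structure of the scale. `run$report$confusion_IA` holds the
row-normalized confusion matrix; `split_report(split, manifest)`
verifies leaf exclusivity and class coverage.

The split grammar and scoring module work on any manifest, real or
synthetic:

```r
splits <- make_factor_splits(manifest, "leaf_number", seed = 1)
names(splits)
#> [1] "L3L4/L3" "L3L4/L4" "L3/L3" "L4/L4" "L3/L4" "L4/L3"
```

A command-line interface wraps the same operations
(`generate`, `split`, `train`, `evaluate`, `deidentify`):

```sh
Rscript -e 'leafhair::leafhair_cli()' generate --config experiment.yaml --seed 7
```

## What a green test does and does not establish

The synthetic generator emulates the *structure* of the real dataset
(mid-vein geometry, 9–15 images per leaf, leaf groups, year/environment
style shifts) with hairiness rendered as monotone stroke density. Green
tests establish that the pipeline mechanics are correct end to end; they
do not establish phenotyping accuracy on real cotton leaves, and the
published real-data accuracies are explicitly not reproduction targets
(they require the real dataset and GPU training of a pretrained
backbone). See the methods vignette (`vignettes/leafhair-methods.Rmd`)
for the full account of models, parameter choices and limitations.
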