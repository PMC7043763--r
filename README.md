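# focidetect

Trainable detection and counting of gammaH2AX DNA-damage foci in
two-channel (DAPI + foci) fluorescence microscopy images.

Ionizing radiation produces DNA double-strand breaks; gammaH2AX
immunofluorescence marks each break site as a small bright nuclear focus,
so the per-nucleus focus count is a dose readout. Routine epi-fluorescence
images carry high background, noise, labeling artefacts, halos and
apoptotic nuclei that defeat fixed-threshold counters. `focidetect`
instead *learns* a rater's notion of "focus pixel" from manually labeled
training images and is aimed at radiation-biology labs that want
reproducible, rater-faithful counts from ordinary microscopes.

The pipeline:

* nucleus segmentation: median filter -> CLAHE -> Otsu -> watershed
  splitting of touching nuclei (markers from the Euclidean distance
  transform);
* a multi-scale filter-bank feature space per pixel — 15 sized
  neighborhood filters x 11 disk radii + Scharr + Frangi + 5 Gabor
  channels + raw = 173 channels, or a reduced 10 x 3 + 6 = 36-channel
  bank — compressed by PCA to the components explaining 95% of the
  training-pixel variance;
* classical pixel classifiers and their voting ensembles: MLP, linear SVM
  (bagging 10 over AdaBoost 15), complement naive Bayes and random forest
  (each AdaBoost 15), combined by soft or hard voting;
* object post-processing: removal of objects with area < 16 px and
  circular-Hough splitting of merged foci into centers;
* evaluation: pixel-wise F1 and Matthews correlation coefficient
  (MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))),
  object-wise one-to-one center matching within 5 px giving sensitivity,
  PPV, FNR and F1 = 2TP/(2TP+FP+FN), per-nucleus bootstrap confidence
  intervals (1000 resamples) and CI-overlap significance calls;
* a seeded synthetic-scene generator (five image-quality regimes) so the
  whole chain is testable without microscope data.

## Worked example

Train an MLP on eight synthetic scenes (the mixture emulates a real
training set: 62% good, 24% noisy, 11% halos, 2% artefacts/apoptotic),
then count foci on a held-out scene and score against ground truth:

```r
library(focidetect)

scenes <- generate_training_set(9, cfg_base = scene_config(seed = 1))
train  <- scenes[1:8]; test <- scenes[[9]]

ts  <- build_training_set(lapply(train, `[[`, "foci"),
                          lapply(train, function(s) s$truth$foci_mask),
                          nucleus_masks = lapply(train, function(s)
                            s$truth$nucleus_label_mask),
                          bank_cfg = reduced_bank_config(), seed = 2)
mod <- train_pixel_model(classifier_spec("MLP", seed = 3), ts)

res <- count_foci(mod, test$nuclear, test$foci)
head(res$counts, 3)
#>   nucleus n_foci
#> 1       1     15
#> 2       2      9
#> 3       3      2

sc <- score_centers(res$fociset$centers, test$truth, radius_px = 5)
m  <- compute_metrics(sc$pooled)
round(c(sensitivity = m$sensitivity, ppv = m$ppv, f1 = m$f1), 3)
#> sensitivity         ppv          f1
#>       1.000       0.824       0.903

bootstrap_ci(sc$per_nucleus, "f1", bootstrap_config(seed = 4))[
  c("point", "ci_low", "ci_high")]  # 0.903 [0.862, 0.970]
```

An F1 of 0.903 means the detected center set and the planted ground
truth disagree on about one focus in ten at the 5 px matching radius:
every planted focus was found (sensitivity 1) and the extra detections
are halo/noise pixels that survived the 16 px size filter (PPV 0.824).
`synthetic_benchmark(seed = 1)` wraps these steps with a slightly
smaller per-image pixel subsample (12000) and reaches F1 0.955 on the
same scenes.

The same arithmetic applied to published per-model object counts
(2660 manual foci) reproduces the published metric table, e.g. an MLP
tally of TP = 2551, FP = 372, FN = 109 gives sensitivity 0.959,
PPV 0.873, FNR 0.041, F1 0.914.

## Command line

```sh
Rscript inst/cli/focidetect synth   --out-dir fixtures --seed 1
Rscript inst/cli/focidetect train   --images imgs/ --labels masks/ --out model.json
Rscript inst/cli/focidetect count   --model model.json --nuclear dapi.tif \
        --foci gh2ax.tif --out-centers centers.json --out-table counts.csv
Rscript inst/cli/focidetect evaluate --pred-centers centers.json \
        --manual-centers manual.json --radius 5 --bootstrap 1000 --out report.csv
```

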