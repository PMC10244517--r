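# dixonmuscle

Automated 3-D segmentation of the individual proximal-leg muscles in Dixon
MRI and volumetric per-muscle fat-fraction quantification — the imaging
endpoint used to track muscular dystrophies, where disease progression
appears as gradual replacement of muscle tissue by fat.

A Dixon acquisition reconstructs co-registered water-only (W), fat-only (F),
in-phase (IP = W + F) and out-of-phase (OP = |W − F|) images. The
proton-density fat fraction per voxel is

    FF% = 100 · F / (F + W),

and the clinical readout is the mean FF% and volume of each muscle (18 per
leg). The package provides the full pipeline around that readout:

* a **synthetic Dixon leg phantom** — two mirror-symmetric legs, fat rind,
  femur with marrow, wedge-shaped muscle compartments with exactly known
  per-muscle infiltration — so every stage can be tested against analytic
  ground truth without clinical data;
* **volume handling**: NIfTI I/O, FF maps with validity masking, stitching of
  1–3 partially overlapping axial stacks (exact on consistent overlaps);
* a **3-D U-Net** (C++ backend, float32, register-tiled direct convolutions)
  operating on 2-channel (OP, IP) single-leg patches: 3×3×3 kernels
  everywhere, four convolutions in the deepest layer, stride-2 convolution
  down, nearest-neighbour + convolution up, instance norm + ReLU;
* the **training protocol**: cross-entropy, Adam at 1e-4, batch size 1, two
  random axial slabs per image per epoch, halve-on-plateau learning rate
  (patience 25), optional early stopping (40), best-validation weights,
  subject-grouped k-fold cross-validation, majority-vote ensembling,
  fine-tuning from low- to high-infiltration cohorts;
* **post-processing**: per muscle keep the two largest 3-D components, fill
  enclosed holes; ground-truth utilities for 1-pixel boundary erosion and
  sparse-annotation emulation (every k-th slice, nearest-neighbour fill);
* **evaluation**: per-muscle Dice (DSC), image-level generalized DSC, average
  symmetric surface distance (exact anisotropic distance transform), Wilcoxon
  signed-rank (exact for n ≤ 25, mid-ranks for ties), Bland–Altman agreement
  of FF% and volume.

See `vignettes/dixonmuscle-methods.Rmd` for the model, all conventions and
parameter choices, and the phantom's known limitations.

## Worked example

Simulate a phantom with designed per-muscle FF of 5/20/40/60/80/95 % at 2 %
noise and quantify it with the true label map:

```r
library(dixonmuscle)
cfg <- phantom_config(grid_shape = c(96, 96, 48), n_muscles = 6,
                      infiltration = c(0.05, 0.20, 0.40, 0.60, 0.80, 0.95),
                      noise_sigma = 0.02, seed = 1)
ph <- generate_phantom(cfg)
quantify_scan(ph$dixon, ph$labels)
#> Per-muscle fat fraction report
#>  muscle_id abbrev ff_pct volume_ml n_voxels n_invalid flag
#>          1     RF   4.94     36.60    12708         0
#>          2     VL  19.97    106.05    36824         0
#>          3     VM  40.00     32.69    11350         0
#>          4     VI  60.03     36.60    12708         0
#>          5     PC  80.03    106.05    36824         0
#>          6     AB  95.03     32.69    11350         0
#> Overall FF%: 49.61
```

Each row is one muscle (both legs pooled): the estimated mean FF% over its
valid voxels, its volume (voxel count × voxel volume), and quality flags;
the recovered FF% sits within 0.1 points of the design at 2 % noise and is
exact without noise. The last line is the voxel-weighted FF% over all muscle
voxels.

Training and segmenting end to end (desk scale, a few minutes):

```r
cohort <- make_cohort(8, c(0, 0.2), phantom_config(n_muscles = 6), seed = 1)
folds  <- make_folds(sapply(cohort, `[[`, "subject_id"), k = 2, seed = 1)
train  <- cohort[folds$folds[[1]]]; test <- cohort[folds$folds[[2]]]
net <- dixon_unet(seg_model_spec(depth = 3, base_filters = 8, n_classes = 7,
                                 growth = 1), seed = 1)
net <- train_unet(net, cohort_leg_scans(train), cohort_leg_scans(test),
                  train_config(max_epochs = 40, lr0 = 1e-3, patch_slices = 24))
pred <- segment_subject(net, test[[1]]$dixon, patch_slices = 24)
pred <- fill_holes(filter_components(pred))
attr(metrics_report(pred, test[[1]]$labels), "gdsc_pct")
```

A command-line interface over the same functions is in
`inst/cli/dixonmuscle` (subcommands `simulate`, `predict`, `postprocess`,
`sparsify`, `erode`, `quantify`, `evaluate`, `pipeline`), and
`run_pipeline()` executes the whole simulate → train → predict → postprocess
→ quantify → evaluate chain into a run directory with a manifest.

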