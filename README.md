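# cineheart

Supervised and semi-supervised whole-heart segmentation of 4D (3D + time)
cine cardiac MR images, in pure R (+ small C++ kernels).

## The problem

Time-resolved 3D cine cardiovascular MR covers the whole heart and great
vessels over a full cardiac cycle, typically 30 isotropic 3D frames.
Computing chamber volumes and ejection fractions from such data needs a
per-voxel labeling of eight structures — LV, RV, LA, RA, AO, PA, SVC, IVC —
in every frame, but manual tracing is only feasible on the two extreme
phases, end-diastole (ED) and end-systole (ES). `cineheart` implements a
semi-supervised training strategy that turns those two annotated frames per
subject into training supervision for the whole cycle:

1. Per subject, a *propagator* 3D U-Net is trained from scratch on the
   ED/ES labels and segments the `k = 3` nearest cyclic neighbours of each
   anchor; the pseudo-labeled frames join the training set, a fresh
   propagator is trained, and the frontier advances by two frames per side
   and step until all frames carry labels.
2. Frames are assigned certainty levels `D_1, D_2, …` (1 = manual anchors,
   `1+s` for frames labeled at propagation step `s`).
3. The final network trains on all frames of all subjects: subjects drawn
   uniformly, two frames per iteration drawn with probabilities
   proportional to `w(level) = 2^(1-level)`, so less-certain pseudo-labels
   are seen less often.

The network is a compact 3D U-Net (two 3×3×3 conv + BN + ReLU per
resolution level, 2×2×2 max-pooling, nearest-neighbour upsampling with skip
concatenation, 1×1×1 SoftMax head; ~1.46 M parameters at the default
configuration), trained with AMSGrad on weighted cross-entropy with
inverted class-frequency weights. Evaluation uses the Dice coefficient
`DSC = 2|A∩B| / (|A|+|B|)` per structure, its mean over the 8 structures,
chamber volume curves (voxel count × voxel volume), EDV/ESV/EF, and paired
Shapiro-Wilk-gated t / Wilcoxon comparisons.

Because the clinical datasets behind the method are institutional, the
package ships a deformable beating-heart phantom (`generate_phantom()`)
with complete ground truth and closed-form volume curves: ellipsoidal
chambers and tubular vessels, cosine radius modulation with counter-phase
atria, blood-bright intensities with noise and bias field. All training
and evaluation machinery is exercised end-to-end on phantom populations.

## Worked example

```r
library(cineheart)

# a 30-frame beating-heart phantom with ground truth
ph <- generate_phantom(phantom_config(grid_size = 32, seed = 7))
ph$series
#> <cine_series> phantom-0007: 30 frames of 32x32x32 voxels @ 1.00x1.00x1.00 mm, ED=15 ES=0

# the propagation plan for a 30-frame cine with ED at 28, ES at 13
sched <- build_schedule(schedule_config(30, ed_index = 28, es_index = 13,
                                        k = 3, step = 2))
sched
#> <propagation_schedule> F=30, ED=28, ES=13, 3 steps, 4 levels
#>   step 1: train 2 frames -> predict {27,29,0,26,1,25,12,14,11,15,10,16}
#>   step 2: train 14 frames -> predict {2,24,3,23,9,17,8,18}
#>   step 3: train 22 frames -> predict {4,22,5,21,7,19,6,20}

# volumetry against the phantom's closed form
v <- volume_curve(ph$labels, ph$series$spacing_mm, "LV")
round(ejection_fraction(max(v), min(v)), 1)
#> [1] 66.1
round(100 * (1 - (1 - 0.3)^3), 1)   # geometric prediction at amplitude 0.3
#> [1] 65.7

# the default architecture
count_parameters(unet_config())
#> [1] 1461129
```

The schedule output reproduces the reference frame plan exactly: the first
propagator (trained on frames 28 and 13 only) segments the 12 frames within
cyclic distance 3 of an anchor; two more steps of two frames per anchor
side cover the remaining 16 frames, giving 4 certainty levels.

An end-to-end arm comparison on a small phantom population (several minutes
of CPU):

```r
res <- compare_arms(seed = 1)
res$dice         # mean Dice over 8 structures, all 30 frames, 2 test subjects
```

## Command line

A thin dispatcher over the package functions is installed with the package:

```sh
cineheart phantom --out data/subj01 --grid 32 --seed 7
cineheart propagate --subject data/subj01 --out labels/subj01
cineheart run --arm semi --out runs/semi --seed 1
cineheart evaluate --pred labels/subj01 --ref data/subj01 --out report.csv
```
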