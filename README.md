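# patellometry

Automated patellofemoral landmark detection and morphometry on axial knee
CT, in R.

Patellofemoral anatomy — the geometry of the trochlear groove in which the
patella tracks — is a key determinant of patellofemoral function,
dysplasia and arthroplasty outcomes, but measuring it by hand on every
axial CT slice of every knee is slow and reader-dependent. `patellometry`
implements an automated pipeline for researchers in musculoskeletal
imaging and orthopaedic morphometry:

1. **Seven landmarks per axial slice** — A: trochlear central trough; B/C:
   trochlear medial/lateral aspects; D/E: medial/lateral peripheral
   epicondyles; F/G: medial/lateral posterior condyles — located by a
   **two-stage coarse-to-fine convolutional regressor**. An *aligner*
   network predicts all 7 points on a preprocessed 160×160 bone crop
   (14 normalized outputs); seven per-landmark *patch* networks then
   refine each point within a 36×36 patch centered on the coarse estimate.
   Both stages use a residual backbone with multi-stage supervision (the
   pooled output of every residual stage feeds the regression head), MSE
   loss, Adam, and an exponential learning-rate schedule (×0.95 per
   epoch). Optional SimCLR contrastive pretraining (NT-Xent loss on
   augmented pairs) initializes the backbone from unlabeled slices.
2. **Four patellofemoral parameters** derived from the landmarks, per
   knee:
   - **TEA length** — Euclidean span between the most medial and most
     lateral landmarks on the slice with the longest transepicondylar
     span (cm);
   - **TEA–PFA angle** — acute angle between the transepicondylar axis
     (D–E) and the posterior femur axis (F–G), degrees;
   - **trochlear medial asymmetry ratio** — with A, B, C projected onto
     the TEA, the groove-to-lateral length over the medial-to-lateral
     length, G–L / M–L (≈ 0.5 for a centered groove);
   - **sulcus angle** — angle at A between the rays to B and C, degrees
     (larger = flatter groove).
   The trough slice used for the last two is the one whose landmark A has
   the shortest perpendicular distance to the TEA.
3. **Evaluation statistics** — per-landmark and pooled Euclidean error in
   cm, precision at a 0.40 cm threshold, paired and independent (Welch)
   t-tests, and Bland–Altman agreement with ±1.96 SD limits.
4. **A synthetic knee phantom** — bicondylar distal-femur cross-sections
   with a wedge trochlear groove, rendered at CT-like intensities across
   multi-slice stacks, whose seven landmarks are placed analytically so
   the derived measurements are known exactly. The phantom makes the whole
   pipeline trainable and testable at desk scale; clinical CT data of the
   original study are not redistributable.

## Worked example

```r
library(patellometry)

# a phantom knee with known ground truth
spec <- phantom_spec(sulcus_angle = 140, asymmetry_ratio = 0.5,
                     tea_length = 8.2, tea_pfa_angle = 5, seed = 1)
series <- generate_phantom(spec)
measure_knee(series)
#> Patellofemoral measurements for 'phantom_seed1':
#>   TEA length          8.200 cm  (slice 5, extremes D-E)
#>   TEA-PFA angle       5.000 deg
#>   asymmetry ratio    0.5000     (slice 7)
#>   sulcus angle      140.000 deg (slice 7)
```

The measurements recover the generating parameters exactly: the phantom's
landmarks are analytic, so it doubles as the morphometry oracle. Training
and evaluating the landmark model:

```r
train <- lapply(1:12, function(i) {
  set.seed(i)
  generate_phantom(phantom_spec(seed = i,
    sulcus_angle = runif(1, 110, 160), asymmetry_ratio = runif(1, .3, .7),
    tea_length = runif(1, 7, 9), tea_pfa_angle = runif(1, 0, 10)))
})
model <- two_stage_landmarks(train,
  aligner_config = net_config(160, 14, epochs = 20, seed = 1),
  patch_config   = net_config(36, 2, epochs = 20, seed = 1), seed = 1)

test <- generate_phantom(phantom_spec(seed = 99))
truth <- series_annotations(test)
tab <- compare_models(predict(model, test, stage = "aligner"),
                      predict(model, test, stage = "two_stage"),
                      truth, spacing_cm = 0.04)
tab
#>       stage mean_distance_cm precision n_points
#> 1   aligner        0.1885544 0.8677249      189
#> 2 two_stage        0.1543865 0.9100529      189
```

The patch stage refines the aligner: smaller mean Euclidean distance and
higher precision at the 0.40 cm threshold (here on a 12-knee training
run; the gap widens with more training data).

A command-line interface wraps the same functions
(`inst/cli/patellometry`): subcommands `phantom`, `preprocess`, `train`,
`predict`, `measure`, `evaluate`.

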