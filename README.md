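# pdhand

Detection of Parkinson's disease (PD) from offline handwriting drawings.

PD impairs fine motor control early: resting tremor appears as radial
shakiness in guided drawing tests (Archimedean spirals and meanders),
and micrographia as progressive shrinking of the stroke scale. `pdhand`
implements an image-based detection pipeline for such drawings, for
researchers working on handwriting-based PD screening:

1. **Pre-processing** — a modified Wiener filter
   `Q = [med + ((σ² − u²)/σ²)(HI − med)] + [med₁ + (((σ²)′ − u²)/(σ²)′)(HI − ρ)]`
   combining a median-masked local-statistics branch with a
   brightness-enhanced branch filtered by an improved
   (Laplacian-augmented) Gaussian kernel; plus conventional Wiener,
   Gaussian and median comparators and PSNR/SSIM quality reporting.
2. **Features** — a modified PHOG descriptor whose derivative maps
   `U_X = HI^p ∗ K_X + IE`, `U_Y = HI^p ∗ K_Y + IE` are augmented by an
   improved (evidential) entropy `IE`; contour shape features (area,
   perimeter, convex hull, epsilon); optional VGG16/ResNet-50 style
   embeddings; fused as `Ff = [PHOG^M | SF | DF]` with train-set
   standardisation.
3. **Classifier** — a hybrid of a GhostNet branch (ghost
   modules/bottlenecks) and an improved LinkNet branch (three encoders
   with LeakyReLU/ELU/Swish activations, a Gabor/multi-kernel MDSCM
   module with XOR fusion, and weighted-average-pooling batch
   normalisation `WAP-BN = (Z·S_J − δ_B·S_J)/√(σ_B² + sigmoid(S_J) + ε)`
   with `S_J = (1 − γ)·mean(A_i)` in the decoders). Branch scores are
   fused by averaging: the argmax decides *healthy* vs *patient*.
4. **Evaluation** — confusion matrix (patient = positive), accuracy,
   sensitivity, specificity, precision, F-measure, MCC, NPV, FPR, FNR,
   FDR, and ROC/AUC.
5. **Synthetic data** — a parametric spiral/meander tremor simulator
   (tremor sinusoid + random walk + micrographia decay) so the full
   pipeline runs and is tested without external data. The public HandPD
   image sets (filenames `ID_EXAM-ID_IMAGE.jpg`) are supported as
   optional inputs through the manifest tools.

## Worked example

```r
library(pdhand)

# simulate a patient's spiral, degrade it, and compare denoisers
spec   <- drawing_spec("spiral", image_size = 96)
path   <- generate_path(spec, patient_tremor(), seed = 42)
img    <- render_drawing(path, spec)
noisy  <- inject_noise(img, noise_spec(gaussian_sd = 15, seed = 42))
compare_filters(img, noisy)
#>                method     psnr      ssim
#> 1               noisy 27.31807 0.6843380
#> 2              median 21.86929 0.8898546
#> 3            gaussian 14.28169 0.7560679
#> 4 conventional_wiener 27.90786 0.7225007
#> 5     modified_wiener 30.94720 0.9613408
```

The modified Wiener filter recovers about 3.6 dB over the noisy input
and clearly beats the conventional Wiener filter on both PSNR and
structural similarity — the pre-processing ordering the test suite
asserts over 100 drawings.

```r
# a small end-to-end experiment: 60 drawings, hybrid classifier
ex <- run_synthetic_experiment(n_per_class = 30, seed = 42,
                               config = train_config(epochs = 8))
m <- ex$evaluation$metrics
sprintf("fused accuracy %.3f  AUC %.3f", m$accuracy, ex$evaluation$roc$auc)
#> [1] "fused accuracy 1.000  AUC 1.000"
ex$evaluation$confusion[c("tp", "fp", "fn", "tn")]
#> $tp: 3   $fp: 0   $fn: 0   $tn: 3
```

At the default effect sizes (healthy tremor 1 px vs patient 6 px with
micrographia decay 0.93) the held-out drawings are classified cleanly;
the package-scale benchmark (400 drawings, 20 epochs) is expected at or
above 0.90 accuracy / 0.95 AUC. `ex$baseline_accuracy` reports the
single-feature logistic baseline on the simulator's radial-deviation
statistic for comparison.

A thin command-line front end over the same functions ships in
`inst/cli/pdhand` (subcommands `synth`, `manifest`, `preprocess`,
`features`, `pipeline`).

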