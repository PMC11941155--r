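# pdeeg

Screening for Parkinson's disease (PD) from resting-state scalp EEG.

Resting EEG in PD shows characteristic spectral shifts — elevated theta
(4–8 Hz) power, depressed beta (13–30 Hz) and gamma (30–48 Hz) power —
relative to healthy controls (HC). `pdeeg` implements the full analysis
chain that turns that observation into a classifier, for researchers who
want a tested, reproducible reference pipeline:

1. **I/O** — EDF, BrainVision (`.vhdr`/`.eeg`) and plain matrix + JSON
   sidecar readers/writers; montage validation against two acquisition
   presets (`dataset1`: 32 channels @ 512 Hz, 180 s analysed; `dataset2`:
   29 channels @ 500 Hz, 120 s).
2. **Preprocessing** — zero-phase Butterworth band-pass 0.5–50 Hz; ICA
   removal of eye-blink components identified by correlation with the
   frontopolar proxies Fp1/Fp2; decomposition into the five canonical
   bands (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–48 Hz);
   segmentation into contiguous 1-s epochs (HC epochs labelled 0, PD 1).
3. **Features** — per epoch and channel, Welch power spectral density
   (Hann windows, 50% overlap, three segments per epoch); the band
   summary is the mean in-band density. For a signal $x(t)$ the PSD is
   $S(f)=\lim_{T\to\infty}\frac{1}{2T}\left|\int_{-T}^{T}x(t)e^{-j2\pi ft}dt\right|^2$,
   estimated here by averaged modified periodograms. Features form
   epochs × channels matrices per band, or a band-stacked layout whose
   rows reshape to a bands × channels map (160 columns on 32 channels,
   145 on 29).
4. **Models** — a per-band linear SVM baseline (hinge loss, dual
   coordinate descent, C = 1) and a compact 2D CNN over the stacked map:
   two 3×3 convolutions (ReLU), two 2×1 max-pools halving the channel
   axis (32 → 16 → 8), one fully-connected ReLU layer, sigmoid output;
   Adam on binary cross-entropy. A per-band 1D CNN supports ablation.
5. **Evaluation** — three case contrasts (`case1` PD_ON vs HC, `case2`
   PD_OFF vs HC on `dataset1`; `case3` PD vs HC on `dataset2`);
   subject-dependent (epoch-level, stratified) and subject-independent
   (grouped, leave-one-subject-out) cross-validation with a leak check on
   every run; confusion matrices, accuracy, sensitivity, specificity,
   precision, F1, ROC and trapezoidal AUC.
6. **Synthetic cohorts** — a seeded generator that plants the PD spectral
   effect (band-limited Gaussian oscillations, 1/f background, blinks on
   the frontal pole, per-subject random effects), so the whole pipeline is
   testable without clinical data.

The filter design, FastICA, the SVM solver and the CNN (including
backpropagation) are implemented inside the package (R + Rcpp); no
signal-processing or deep-learning runtime is required.

## Worked example

A scaled synthetic run of the default scenario (dataset1 geometry,
medicated patients vs controls, ICA on, band-stacked CNN, subject-dependent
5-fold CV; 6 + 6 subjects, 20 s per recording so it finishes in about a
minute):

```r
library(pdeeg)

cfg <- run_config(preset = "dataset1", case = "case1", model = "cnn2d",
                  folds = 5, seed = 42, ica = TRUE,
                  duration_s = 20, n_pd = 6, n_hc = 6,
                  cnn = list(epochs = 10, patience = 3))
res <- run_pipeline(cfg)
res$cv
#> <eeg_cv cnn2d> 5 folds: mean acc=0.9000 sens=0.9167 spec=0.8833 auc=0.9715
round(res$cv$fold_metrics[, c("accuracy", "sensitivity", "specificity", "auc")], 4)
#>      accuracy sensitivity specificity    auc
#> [1,]   0.8958      0.9583      0.8333 0.9705
#> [2,]   0.9167      0.8750      0.9583 0.9740
#> [3,]   0.9167      0.9583      0.8750 0.9826
#> [4,]   0.8542      0.9167      0.7917 0.9497
#> [5,]   0.9167      0.8750      0.9583 0.9809
```

Each row is one stratified epoch-level fold: with the generator's default
patient effect (theta ×1.5, beta/gamma ×0.7) the stacked CNN recovers the
planted group structure at ~90% epoch accuracy and AUC ≈ 0.97. The
per-band SVM baseline on the same cohort shows the expected band ordering
— the effect lives in the fast bands:

```r
run_pipeline(run_config(preset = "dataset1", case = "case1", model = "svm",
                        band = "gamma", folds = 3, seed = 42, ica = FALSE,
                        duration_s = 20, n_pd = 6, n_hc = 6))$cv
#> <eeg_cv svm> 3 folds: mean acc=0.6792 sens=0.7000 spec=0.6583 auc=0.7621
# the same with band = "delta":
#> <eeg_cv svm> 3 folds: mean acc=0.6000 sens=0.5833 spec=0.6167 auc=0.6448
```

With `out = "some/dir"`, `run_pipeline()` writes a deterministic artifact
tree (feature table, JSON report, config and manifest); reruns under the
same seed are byte-identical. A thin command-line front end with
`simulate`, `features`, `train`, `evaluate`, `ablation` and `run`
subcommands lives at `inst/cli/pdeeg.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— it simulates a cohort, preprocesses it (ICA on), trains and
cross-validates the band-stacked CNN and the gamma-band SVM, prints the
fold summaries and writes the acceptance JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
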