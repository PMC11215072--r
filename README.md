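# AmyloidDyn

Latent-space quantification and progression modeling of volumetric amyloid
PET, for imaging researchers who want a generative, low-dimensional account
of brain amyloid accumulation: how much amyloid a scan shows (SUVR), how a
subject's scans move through a latent representation over time, and what a
plausible future scan looks like.

## What it does

1. **Generative representation.** A 3D style-based GAN — mapping network
   *M*, synthesis network *G*, discriminator *D* — is trained on PET
   volumes; an inversion encoder *E* (five filtered-downsample + 3³
   convolution blocks, depths 16/32/32/32/16, linear 96-unit head) maps a
   real scan into the intermediate latent space *W*, trained by minimising
   ‖PET − G(E(PET))‖².
2. **SUVR quantification.** Centred PCA compresses the latent table
   (w ≈ w̄ + Σₖ vₖ bₖ); ordinary least squares predicts global SUVR from
   latents or principal scores, evaluated by repeated subject-level
   train/test splits (RMSE / MAE / AUROC with 95% percentile CIs) and an
   elbow curve over the number of components.
3. **Progression ODE.** Latent dynamics follow db/dt = V(b, c) with
   covariates c = (age, APOE-ε4 count). V is estimated non-parametrically:
   finite-difference velocities between consecutive same-subject scans,
   one Gaussian-process regression per component (anisotropic
   squared-exponential + white noise). Forward-Euler integration forecasts
   trajectories, and Îₜ = G(w̄ + Σₖ vₖ bₖ(t)) renders synthetic PET
   evolutions and difference maps.
4. **Phantom cohorts.** A synthetic longitudinal phantom-brain generator
   with a known logistic amyloid law (rate modulated by APOE-ε4 count) and
   an exactly affine load→SUVR map provides ground truth for building and
   validating every stage without access-restricted clinical data.

## Worked example

```r
library(AmyloidDyn)

spec <- phantomSpec(gridShape = c(16, 16, 16), noiseSigma = 0.02)
masks <- phantomMasks(spec)
vol <- buildPhantom(spec, load = 0.5, seed = 1)
computeReferenceSuvr(vol, masks)
#> [1] 1.509583
```

A noiseless phantom recovers the affine map exactly (offset 1.0 + slope
1.0 × load = 1.5); the ~0.01 residual here is the configured acquisition
noise (sigma 0.02) averaged over the cortical and reference masks.

```r
cfg <- pipelineConfig(list(seed = 1,
                           paths = list(output_dir = "amyloid-out")))
runPipeline(cfg)   # simulate -> train GAN -> train encoder -> embed ->
                   # PCA -> SUVR regression -> bootstrap -> elbow ->
                   # velocity field -> forecasts -> renders -> phase plot

rep <- jsonlite::read_json("amyloid-out/evaluate-suvr/bootstrap_report.json",
                           simplifyVector = TRUE)
rep$summary
#>   metric       mean      lower      upper
#> 1   rmse 0.06655226 0.05318677 0.07933422
#> 2    mae 0.05089935 0.03962291 0.06260958
#> 3  auroc 0.97705762 0.93573999 1.00000000
```

Read: across 200 random 65/35 subject-level splits on the tiny phantom
cohort, latent vectors predict ground-truth SUVR to ~0.067 RMSE and
separate amyloid-positive scans (SUVR ≥ 1.1) with AUROC ≈ 0.98. The elbow
table (`amyloid-out/elbow/elbow.csv`) shows the projected-score RMSE
dropping from 0.171 at K = 1 to ~0.076 by K = 5 and flat thereafter,
which motivates the default five-component progression subspace; `render-trajectory/` contains the
baseline and 4-year forecast volumes as NIfTI plus difference panels.

A shell entry point wrapping the same stages is installed at
`inst/cli/amyloid-latent-dyn.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/amyloid-latent-dyn.R", package="AmyloidDyn"))')" \
    all --seed 1 --output-dir amyloid-out
```

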