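# steamchem

NIR chemometrics for in-line monitoring of the steaming of *Gastrodiae
rhizoma* (Tianma).

Steaming converts the parishin esters of the rhizome towards gastrodin while
the homogenate takes up water. `steamchem` implements the full multivariate
calibration workflow used to follow that process from near-infrared
diffuse-reflectance spectra (log 1/R, 4,000-12,000 cm⁻¹ at 8 cm⁻¹, one
spectrum every 30 s): it is aimed at chemometricians and process-analytical
(PAT) scientists who want a tested, scriptable reference implementation of
this pipeline.

The package provides, as S4 classes and functions:

* **Preprocessing** — multiplicative scatter correction (MSC), standard
  normal variate (SNV), Savitzky–Golay smoothing and derivatives, composed
  into fit-on-calibration/apply-to-any chains (`parseChain("MSC+SG9+FD")`).
* **Sample selection** — PCA/Mahalanobis outlier screening and the
  Kennard–Stone maximin calibration/validation split.
* **Calibration** — stepwise MLR (partial-F forward/backward), NIPALS PLS1,
  synergy-interval PLS (exhaustive search over combinations of equal-width
  spectral intervals, `siplsSearch()`), and principal component regression,
  with leave-one-out RMSECV component selection. For a preprocessed
  calibration matrix `X` and response `y`, PLS predicts
  `ŷ = ȳ + (x − x̄)ᵀ b` with `b` folded back from the latent-variable
  decomposition; Si-PLS scores every interval combination by its LOO RMSECV
  and keeps the global minimiser.
* **Validation** — the standard NIR panel: Rc², RMSEC, RMSECV, Rp², RMSEP,
  RPD (= SD(validation)/RMSEP) and RSEP (%), plus paired-*t* and variance-*F*
  agreement tests between reference and NIR-predicted values.
* **Synthetic data** — a seeded generator of steaming-process spectra
  (Beer–Lambert mixtures of Gaussian-band components with first-order
  kinetics, batch effects, scatter/baseline distortions and reference-assay
  noise) emulating the study design: 10 batches × 21 time points. It also
  simulates unmonitored constituents, so calibrations face realistic
  unmodelled spectral variation.
* **Pipeline** — `runPipeline()` orchestrates simulate → screen → split →
  fit (SMLR/PLS/Si-PLS for the four phenolic analytes, PCR for moisture) →
  evaluate, and `monitorProcess()` applies fitted models to new batches.

## Worked example

```r
library(steamchem)

# a small synthetic study: 4 batches sampled every 30 s for 240 s
cfg <- pipelineConfig(
  simulate = syntheticConfig(nBatches = 4, duration = 240, seed = 101),
  sipls = siplsControl(intervalCounts = 8, comboSizes = 2, maxLV = 4),
  maxLV = 6, seed = 101)
run <- runPipeline(cfg)
run$best[, c("property", "method", "Rp2", "RMSEP", "RPD", "LVs")]
```

```
                 property method       Rp2       RMSEP       RPD LVs
1               gastrodin  SiPLS 0.9968786 0.007283028 16.286131   4
2 p_hydroxybenzyl_alcohol  SiPLS 0.9960631 0.005051867 10.091300   4
3              parishin_b  SiPLS 0.9780849 0.006206766  3.616301   4
4              parishin_a  SiPLS 0.9990640 0.005361105 23.564206   4
5                moisture    PCR 0.7534297 2.068622450  1.541981   2
```

Each row is the winning model for one property evaluated on the held-out
Kennard–Stone validation set: `Rp2` is the squared correlation between
reference and predicted contents, `RMSEP` the prediction error in the
property's own units (% w/w for the analytes, % for moisture), `RPD` the
ratio of the validation reference SD to RMSEP (≥ 3 is conventionally read as
quantitatively useful), and `LVs` the latent variables / components chosen
by leave-one-out cross-validation. The four analyte models are
quantitatively strong; moisture — assigned to unsupervised PCR by the
workflow's design — is the weak model (see the methods vignette for why).
This tiny 4-batch demo is for illustration; the default 10-batch study
design, what `runPipeline(pipelineConfig(seed = 1))` and the acceptance
script run, is the configuration meant for real use.

```r
# monitor three new batches and test HPLC-vs-NIR agreement
models <- lapply(run$results, function(r)
  r$models[[if (r$property == "moisture") "PCR" else "SiPLS"]])
held <- generateDataset(syntheticConfig(nBatches = 3, seed = 202))
mon <- monitorProcess(models, held$spectra, held$reference)
head(mon$records)      # per-spectrum predictions in time order
mon$agreement          # paired-t and F-test p-values per property
```

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/steamchem.R simulate --seed 42 --out-dir data/
Rscript inst/scripts/steamchem.R run-all  --seed 42 --out-dir runs/demo/
```

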