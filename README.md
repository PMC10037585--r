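# tibiaseg

Automated segmentation of the mouse tibia in 3D gradient-echo MRI, and the
statistics that certify the precision of the resulting bone-volume
biomarker.

In murine myelofibrosis studies the tibial bone marrow is the primary
disease site; quantitative imaging biomarkers are measured inside the
segmented tibia, so the volume measurement error sets the smallest
biological change the study can detect.  Manual contouring is slow and is
the dominant source of that error.  `tibiaseg` provides:

* **Volume I/O** — MetaImage (`.mhd`/`.raw`) reading/writing with voxel
  spacing geometry (`readMHD()`, `writeMHD()`), coronal slice
  extraction/restacking, physical mask volumes in mm³.
* **A 2D attention U-Net** — four encoder/decoder stages with an
  attention gate on each skip connection, implemented (forward,
  backprop, Adam) in single-precision C++; trained slice-wise with
  binary cross-entropy and validation-based model selection
  (`unetCreate()`, `trainUNet()`, `predictVolume()`).
* **Accuracy metrics** — Jaccard index, volume intersection ratio,
  signed volume error, 3D Hausdorff distance in mm; mean ± SD set
  summaries and Bonferroni-thresholded paired scenario comparisons
  (`caseMetrics()`, `summarizeMetrics()`, `compareScenarios()`).
* **Test–retest repeatability** — within-subject coefficient of
  variation with chi-square confidence intervals, Bland–Altman bias and
  95% limits of agreement, Pearson agreement (`wcv()`, `wcvCI()`,
  `blandAltman()`, `pearsonR()`).
* **A synthetic cohort simulator** — parametric tibia phantoms
  (tapering curved shaft, condylar bulge, dark cortical rim,
  heterogeneous marrow), consecutive-day test–retest pairs by rigid
  repositioning, per-mouse volume growth, simulated annotators with
  calibrated over-segmentation bias, and cohort presets reproducing the
  study census of 32 mice / 157 scans / 49 pairs
  (`generateTibiaPhantom()`, `generateCohort()`,
  `paperDefaultCohortSpec()`, `tinyCohortSpec()`).

The key statistics, in the field's notation: for test–retest volume
pairs (difference *dᵢ*, mean *mᵢ*),

    wCV% = 100 · sqrt( (1/n) Σᵢ dᵢ² / (2 mᵢ²) )

with confidence interval `wCV · sqrt(df / χ²_{1−α/2, df})` to
`wCV · sqrt(df / χ²_{α/2, df})`, `df = n − 1`; Bland–Altman limits of
agreement are `mean(d) ± 1.96 · SD(d)`.  Accuracy uses
`JI = 100·|S∩R|/|S∪R|`, `VI = 100·|S∩R|/|S|`,
`VE = 100·(|S|−|R|)/|R|` and the classical symmetric Hausdorff distance
in physical millimetres; the three volume metrics satisfy the exact
identity checked by `impliedJaccard()`.

## Worked example

A complete synthetic experiment at desk scale — simulate a 6-mouse
cohort (24 scans, 12 consecutive-day pairs), train the attention U-Net
on its training split, and compare the model's volume repeatability with
a simulated second annotator:

```r
library(tibiaseg)

mf <- generateCohort(tinyCohortSpec(seed = 1), "cohort")
cohortCensus(mf)$n_scans            # 24
cohortCensus(mf)$n_pairs            # 12

sc  <- makeScenarios(mf, seed = 1)
net <- trainUNet(sc$full, mf, "cohort",
                 model  = modelConfig(baseFilters = 8),
                 config = trainingConfig(batchSize = 16, maxEpochs = 10,
                                         learningRate = 2e-3, seed = 1))
net
#> AttentionUNet: depth 4, base filters 8 (encoder 8-16-32-64; bottleneck 128)
#>   trained 10 epochs; best epoch 10 (val Jaccard 88.9%)

ev <- evaluateSet(mf, "cohort", net, split = "test")
round(mean(ev$JI), 1)               # 88.2  (% Jaccard vs ground truth)

vols <- rbind(pairVolumes(mf, "cohort", "model", net),
              pairVolumes(mf, "cohort", "EA2"))
repeatabilityReport(vols)[, c("method", "wcv", "ci_low", "ci_high")]
#>    method  wcv ...      # model ~3%, simulated annotator ~6%
```

The mean test Jaccard (~88%) says the network recovers the ground-truth
tibia to expert-level overlap; the wCV column says the same animal
rescanned a day later gets, from the model, a volume that varies by a
few percent — roughly half the simulated annotator's variability, which
is the property that makes the automated segmentation the better
biomarker instrument.

A shell front-end chains the stages (`simulate`, `train`, `predict`,
`evaluate`, `repeatability`, `run-all`):

```sh
Rscript inst/cli/tibiaseg.R run-all \
    --config inst/extdata/config/tiny.yaml --out runs/tiny --seed 1
```

writing per-case metrics, an accuracy summary table, a repeatability
summary table and a JSON-lines log.

## Documentation

The methods vignette
(`vignettes/tibia-segmentation-repeatability.Rmd`) describes the model,
the metric and CI conventions and how they were validated, the phantom
simulator's assumptions, and what the synthetic experiments do and do
not demonstrate about real data.
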