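# cpoct

Depth-resolved attenuation mapping for cross-polarization optical coherence
tomography (CP OCT) of breast tissue.

## The problem

During breast-conserving surgery the surgeon needs to know, within minutes,
whether the resection margin still carries tumor. CP OCT images the excised
specimen at ~10–15 µm resolution in two polarization channels — co-polarized
(detected light keeps the incident polarization) and cross-polarized
(orthogonal) — and different breast tissue types decay the OCT signal at
measurably different rates. `cpoct` turns raw two-channel OCT volumes into
quantitative *en face* attenuation maps and ROI-level statistics that
discriminate five tissue types:

| label | tissue |
|-------|--------|
| AT    | adipose tissue |
| NCT   | non-tumorous fibrous connective tissue |
| HTS   | hyalinized tumor stroma |
| LDTC  | low-density tumor cells in fibrotic tumor stroma |
| HDTC  | high-density tumor-cell clusters |

The clinically decisive contrast is in the **cross** channel: tumor-cell
areas attenuate far less (medians 1.0–2.2 mm⁻¹) than non-tumorous fibrous
tissue (3.7 mm⁻¹) or hyalinized stroma (4.7 mm⁻¹).

## The estimator

For a measured A-scan *M<sub>i</sub>* (linear scale, axial pixel Δ), the
depth-resolved estimate of the attenuation coefficient is the ratio of the
local signal to the cumulative signal remaining below it,

    µ_est[i] = M[i] / (2 Δ Σ_{j>i} M[j]),

which requires no range fitting and resolves µ per voxel. Additive detector
noise with mean ⟨N⟩ biases this estimate as µ_est = H·µ_att + Nµ with

    H[i]  = 1 − ⟨N⟩(imax−i) / (T[i] + ⟨N⟩(imax−i)),
    Nµ[i] = ⟨N⟩ / (2 Δ Σ_{j>i} M[j]),

where T[i] estimates the noise-free signal sum below *i*. The corrected
coefficient is recovered by the SNR-weighted inversion

    µ_att[i] = H·SNRµ / (H²·SNRµ + 1) · µ_est[i],

with `SNRµ = max(0, M − ⟨N⟩)/(⟨N⟩·H²)`, under which the gain reduces to the
direct noise-subtracted inversion (µ_est − Nµ)/H wherever signal exceeds the
noise floor and shrinks smoothly to zero where it does not. The measured
volume is pre-averaged in a local 3×3×3 window to tame speckle, and a final
`log1p` map removes the geometric-sum discretization bias. Maps average
µ_att over 0.105–0.630 mm below the detected tissue surface; ROI medians
over 300 × 300 µm windows feed Mann–Whitney class comparisons (Bonferroni
corrected) and ROC analysis (AUC, Youden-optimal cutoff, Se/Sp/Ac with
Wilson and bootstrap CIs).

Because no public CP-OCT dataset of this kind exists, the package includes a
first-class synthetic-data module: phantoms with exponential depth decay,
fully developed speckle (unit-mean exponential), an additive noise floor,
and per-ROI attenuation variability calibrated to the published
class-distribution summaries (medians and quartiles).

## Worked example

Synthesize the default calibrated phantom — a 2-channel, 800 × 128 × 128
volume (4 mm deep, 1.2 × 1.2 mm field), five class regions, speckle and a 1%
noise floor — then run the full chain (about a minute):

```r
library(cpoct)
spec  <- phantomSpec(seed = 1)
sim   <- synthesizeVolume(spec)
surf  <- detectSurface(sim$volume)
noise <- estimateNoiseFloor(sim$volume, surface = surf)
att   <- attenuationVolume(sim$volume, noise = noise, surface = surf,
                           diagnostics = FALSE)
map   <- enfaceAverage(att)                       # 0.105-0.630 mm window
med   <- roiMedians(map, defaultFixtureROIs(spec))
classStats(med)
```

```
   class channel  n median    q1   q3  mean
1     AT      co 33  3.875 3.780 4.00 3.874
2     AT   cross 33  0.950 0.819 1.04 0.930
3    NCT      co 36  5.471 5.430 5.56 5.497
4    NCT   cross 36  3.896 3.844 3.97 3.911
5    HTS      co 27  5.163 5.127 5.19 5.151
6    HTS   cross 27  4.751 4.709 4.78 4.743
7   LDTC      co 34  5.099 5.040 5.17 5.102
8   LDTC   cross 34  2.315 2.294 2.33 2.310
9   HDTC      co 35  4.238 4.225 4.28 4.257
10  HDTC   cross 35  0.842 0.800 0.98 0.906
```

The recovered medians sit on the generating class table (AT cross 0.9, NCT
cross 3.7, HTS cross 4.7, LDTC cross 2.2, HDTC cross 1.0 mm⁻¹ …): the
estimator reads the ground truth back out of a speckled, noisy volume.
`renderMap(map, "enface_cross.png")` writes the fixed-scale (0–7 mm⁻¹,
blue → cyan → yellow → red) colour rendering.

Diagnostic power is assessed on ROI medians drawn from the calibrated
class-conditional distributions at the study's class sizes:

```r
set.seed(1)
ct <- defaultClassTable()
draws <- do.call(rbind, lapply(ct$label, function(cls)
  do.call(rbind, lapply(c("co", "cross"), function(ch)
    data.frame(class = cls, channel = ch,
               value = sampleROIMu(cls, ch,
                   ct$roi_count_default[ct$label == cls]))))))
res <- tissueComparisons(draws, seed = 1)
rocTable(res)[, c("comparison", "channel", "auc", "se", "sp", "ac", "cutoff")]
```

```
 comparison channel   auc    se    sp    ac cutoff
   TC vs AT      co 0.831 0.928 0.606 0.824  >4.04
   TC vs AT   cross 0.790 0.623 0.970 0.735  >1.31
  TC vs NCT      co 0.844 0.739 0.861 0.781  <4.82
  TC vs NCT   cross 0.994 1.000 0.917 0.971  <2.93
 HTS vs NCT      co 0.657 0.963 0.472 0.683  <5.47
 HTS vs NCT   cross 0.929 1.000 0.861 0.921  >4.12
```

TC pools the two tumor-cell classes (LDTC + HDTC, n = 69). The pattern is
the clinically relevant one: tumor cells versus fibrous tissue is almost
perfectly separable in the cross channel (AUC 0.994, cutoff ≈ 3 mm⁻¹), while
the co channel barely distinguishes hyalinized stroma from normal fibrous
tissue (AUC 0.657).

A command-line wrapper over the same stages lives in `inst/scripts/cpoct.R`
(`simulate`, `estimate`, `map`, `stats`, `roc`, `all`; flags `--config`,
`--seed`, `--out`; YAML schema in `inst/extdata/example_config.yaml`).

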