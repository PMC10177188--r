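---
title: "Depth-resolved CP-OCT attenuation mapping: models and design choices"
author: "cpoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved CP-OCT attenuation mapping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
signal model behind the depth-resolved attenuation estimator, the
noise-compensation algebra, the parameters that matter and the reasoning
behind every design decision that the underlying method leaves open. It
states no empirical result that the test suite or the acceptance script does
not itself compute.

## Signal model

A CP-OCT instrument records backscattered intensity in two polarization
channels (co, cross). Under the single-scattering model with a constant
backscatter-to-attenuation ratio, the mean linear-scale signal in a column
of homogeneous tissue with attenuation coefficient $\mu$ (mm$^{-1}$) decays
as

$$ S(z) \;=\; b\,e^{-2\mu (z - z_s)}, \qquad z \ge z_s, $$

with $z_s$ the tissue surface, $b \propto \mu$ the backscatter level, and
the factor 2 the round trip. The measured signal adds fully developed
speckle (multiplicative, unit-mean exponential on intensity) and an additive
detection-noise floor with mean $\langle N \rangle$:

$$ M \;=\; S \cdot g + \langle N \rangle \cdot d, \qquad
   g, d \sim \text{Exp}(1). $$

All internal processing is on the linear scale; decibels appear only in
rendering, never in estimation.

## The depth-resolved estimator

For one A-scan sampled at axial pitch $\Delta$ the estimator is the ratio of
local signal to the cumulative signal below,

$$ \hat\mu^{\mathrm{est}}_i \;=\;
   \frac{M_i}{2\Delta \sum_{j=i+1}^{i_{\max}} M_j}. $$

It needs no depth-range fit, is scale invariant, and under the
proportional-backscatter assumption resolves layered media per voxel. Two
systematic effects must be handled.

**Additive noise.** Noise inflates both numerator and denominator; the naive
estimate decomposes as
$\hat\mu^{\mathrm{est}} = H \hat\mu^{\mathrm{att}} + N_\mu$ with

$$ H_i = 1 - \frac{\langle N\rangle (i_{\max}-i)}
                  {T_i + \langle N\rangle (i_{\max}-i)}, \qquad
   N_{\mu,i} = \frac{\langle N\rangle}{2\Delta \sum_{j>i} M_j}, $$

where $T_i$ estimates the noise-free signal sum below $i$ extended to
infinite depth. The corrected coefficient uses the SNR-weighted (Wiener-type)
inversion

$$ \hat\mu^{\mathrm{att}}_i \;=\;
   \frac{H_i\,\mathrm{SNR}_{\mu,i}}{H_i^2\,\mathrm{SNR}_{\mu,i} + 1}\,
   \hat\mu^{\mathrm{est}}_i. $$

The source method leaves $\mathrm{SNR}_\mu$ undefined. This package defines

$$ \mathrm{SNR}_{\mu,i} \;=\;
   \frac{\max(0,\, M_i - \langle N\rangle)}{\langle N\rangle\, H_i^2}, $$

i.e. the local intensity SNR of the smoothed signal referred through the
bias factor. The choice is not cosmetic: with it the gain reduces
*algebraically* to the direct noise-subtracted inversion
$(\hat\mu^{\mathrm{est}} - N_\mu)/H$ wherever the signal exceeds the noise
floor, attains both limiting cases ($H = 1,\ \mathrm{SNR}\to\infty \Rightarrow
\hat\mu^{\mathrm{att}} = \hat\mu^{\mathrm{est}}$; $\mathrm{SNR}=0 \Rightarrow
0$), and keeps the monotone-shrinkage bound
$\hat\mu^{\mathrm{att}} \le \hat\mu^{\mathrm{est}}/H$. The superficially
simpler alternative — plugging the raw local SNR
$(M-\langle N\rangle)/\langle N\rangle$ into the same gain — collapses the
estimate wherever $H \ll 1$, which on a deep scan is the *entire analysis
window* of a fast-decaying tissue: with a 4 mm scan, $\mu = 5$ mm$^{-1}$ and
a 1% noise floor, $H \approx 0.07$ at mid-window and the plug-in gain
underestimates $\mu$ by an order of magnitude. The definition used here is
therefore the one under which the published limits and the recovery of known
phantoms are simultaneously achievable; the equivalence with the direct
inversion is exercised by the tests.

**Discretization.** The sum $\sum_{j>i} M_j$ is a geometric, not an
integral, sum: on an exact exponential the raw estimator returns
$(e^{2\mu\Delta}-1)/(2\Delta) \approx \mu(1 + \mu\Delta)$ — a +2.7% bias at
$\mu = 5.3$ mm$^{-1}$ and $\Delta = 5$ µm. `attenuationVolume()` therefore
applies the exact inverse map

$$ \mu \;=\; \frac{\log\!\big(1 + 2\Delta\,\mu_{\mathrm{lin}}\big)}{2\Delta} $$

as its final step (option `discretization`, default `TRUE`).
`estimateMuNaive()` deliberately returns the raw ratio, so its hand-checkable
contract (profile `[4, 2]`, $\Delta = 1$ → 1.0) is preserved.

**Finite depth.** Truncating the sums at $i_{\max}$ biases the noise-free
estimator to $\mu / (1 - e^{-2\mu(L - z)})$ for scan depth $L$; this closed
form is the analytic oracle in the tests. The default `tailMode = "truncate"`
estimates $T_i$ by noise-subtracting the measured sum (clipped at 0), which
is adequate when the signal has decayed inside the scan; an
`"extrapolate"` mode fits an exponential tail to the last noise-subtracted
samples for shallow real volumes.

## Validity masking

Voxels are masked invalid (NA, never zero-filled) when they are above the
detected surface, at the last axial pixel, where $H \le 0$, or where the
noise-subtracted remaining-signal sum $T_i$ falls below 3 standard
deviations of the accumulated-noise fluctuation,
$\sigma_T = \langle N\rangle \sqrt{i_{\max}-i}\,/\,3$ (the factor 3 from the
3×3×3 pre-averaging; the noise deviates are exponential, so their sd equals
their mean). Below that threshold the inversion denominator is statistically
indistinguishable from zero and the per-voxel estimate is unstable with a
heavy right tail; keeping such voxels inflates depth-window *means* even
though medians stay robust. En face values and ROI statistics are computed
over valid voxels only.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| smoothing window | 3×3×3 | px | speckle pre-averaging before estimation, per the processing design |
| depth window | 0.105–0.630 | mm below surface | the map-contrast window of the imaging protocol; 21–125 px at $\Delta = 5$ µm |
| surface threshold $k$ | 4 | multiples of $\langle N\rangle$ | first crossing of the smoothed co-channel signal; 5×5 lateral median filter cleans outliers |
| noise guard band | 5 | px | separates the noise-estimation region from the surface |
| `tailSigma` | 3 | $\sigma_T$ | noise-domination mask (above) |
| ROI window | 300×300 | µm | 32×32 px at 9.375 µm pitch |
| ROI validity | ≥ 50% | valid pixels | below this the ROI is excluded with a logged reason |
| colour scale | 0–7 | mm$^{-1}$ | fixed absolute scale; <2 blue, 2–3 cyan, 4–5 yellow, >6 red |
| Bonferroni $m$ | 10 | pairs | all pairwise tests among five classes, per channel |

## The synthetic-data module

No public dataset of this kind exists, so the generator is first-class,
tested code and defines the study conditions:

* **Class calibration.** The five-class table (`defaultClassTable()`) fixes
  per-channel medians and quartiles — AT 3.9/0.9, NCT 5.3/3.7, HTS 5.1/4.7,
  LDTC 5.0/2.2, HDTC 4.3/1.0 mm$^{-1}$ (co/cross medians) — and ROI counts
  33/36/27/34/35 (165 total). Only medians and quartiles are published, so
  per-ROI attenuation is modelled as normal with sd = IQR/1.349
  (normal-theory conversion), truncated at median ± 3 sd. For AT and HDTC in
  the cross channel, median − 3 sd is negative; draws are floored at
  0.05 mm$^{-1}$ to keep attenuation positive (mass < 1.2%, median shift
  < 0.005 mm$^{-1}$).
* **Coupling.** The joint co/cross distribution is unpublished; one ROI's
  two channels share a single standard-normal deviate (comonotone coupling),
  so each pair is coherent.
* **Geometry.** Default 4 mm depth at 5 µm pixels (800 z-px), 128×128
  lateral at 9.375 µm (1.2 mm field), flat contact-probe surface at
  0.25 mm. The depth satisfies the tail bound
  $e^{-2\mu_{\min}(L - z_s)} < 0.02$ for the slowest-decaying class in the
  layout (AT cross, 0.9 mm$^{-1}$) so the truncate-mode tail is negligible.
  Single-class test phantoms apply the same bound to their own class, which
  keeps scan depth matched to the decay rate — a needlessly deep scan only
  accumulates pure noise in the depth sums and amplifies any error in the
  noise-floor estimate by the ratio of accumulated noise to remaining
  signal (a genuine sensitivity of this estimator family, stated under
  Limitations).
* **Layout and ROIs.** Five classes on a 2×3 lateral grid (the spare cell
  repeats adipose tissue, which surrounds the tumor bed in resection
  specimens); attenuation varies on a 16-px lateral patch grid within each
  region. The 165-window ROI fixture cannot be disjoint on a 128×128 grid
  (at most 16 disjoint 32×32 windows fit), so windows are laid on a
  deterministic jittered lattice and may overlap — at this small lateral
  scale that emulates dense manual ROI sampling of large stitched maps.
  Distribution-level statistics (the ROC panel) are therefore computed from
  independent `sampleROIMu()` draws, not from one phantom's overlapping
  windows.
* **What is not emulated.** Confocal gating and spectral roll-off (the
  method's stated ≤10% depth-sensitivity effect is deliberately not
  modelled, matching the processing design), birefringence, the honeycomb
  texture of adipose tissue, probe-pressure artefacts, and within-patient
  correlation of ROIs (ROIs are treated as independent, as in the original
  analysis). Passing tests show the pipeline recovers its own generating
  model — they do not certify performance on instrument data with
  depth-dependent sensitivity or non-exponential speckle statistics.

## Statistics

ROI medians use the inclusive linear-interpolation quantile convention
(type 7), fixed because the IQR feeds the calibration. Group comparison is
the two-sided Mann–Whitney U: full enumeration of assignments (midranks for
ties) when both groups have n ≤ 8, else the tie-corrected normal
approximation without continuity correction, so identical groups return
exactly p = 1; Bonferroni multiplies by the number of pairs, capped at 1.
The AUC is pairwise concordance with ties counted ½ (equal to the
trapezoidal area and to U/(n₁n₂)); its 95% CI is a stratified bootstrap
(2000 resamples, seeded). The optimal cutoff maximises Youden's Se + Sp over
midpoints between adjacent distinct values (plus sentinels beyond the
extremes), ties broken toward higher accuracy and then the lowest cutoff;
Se/Sp/Ac carry Wilson 95% CIs. Directions are fixed per contrast from the
class-distribution ordering (tumor cells attenuate less than fibrous tissue
in cross, more than adipose in co; hyalinized stroma sits above NCT in
cross and marginally below it in co) rather than auto-detected, so a
degenerate sample cannot silently flip a comparison's sign.

## Problem sizes

Defaults were chosen so the whole experiment is desk-scale: the full
(2, 800, 128, 128) phantom pipeline is a single-core, ~1-minute computation;
estimator unit checks use 8–24 px lateral grids; the ROC simulation draws
105 ROI medians per replicate for 200 replicates. These sizes are the
package's study conditions, stated here so results are read at the scale
that produced them.

## Container formats

The volume container is raw little-endian float64 stacks plus a JSON sidecar
(geometry is read from the sidecar, never guessed), because R's TIFF writer
supports only fixed-point integer samples, which cannot hold a five-decade
OCT decay to float precision. A TIFF export mode (multi-page, one file per
channel, power-of-two normalisation recorded in the sidecar) is provided for
interoperability and inspection; its ~2⁻³² absolute quantisation on the
normalised scale is documented and tested. ROI tables are plain CSV with a
provenance comment; en face maps export as CSV and PNG; run configurations
are YAML and are archived verbatim alongside every run's outputs.

## Limitations

* The noise-compensation algebra assumes a *known, stationary* noise floor.
  Its error is amplified by the ratio of accumulated noise to remaining
  signal, so for fast-decaying tissue the floor must be estimated from as
  many signal-free voxels as the geometry allows, and scan depth should not
  greatly exceed the depth at which signal is exhausted.
* Per-voxel estimates below SNR ≈ 1 are shrunk or masked, not recovered;
  quantities derived from them (window means in particular) are only as
  robust as the masking rule.
* The calibration reproduces published medians and quartiles, not full
  distributions; tail behaviour of the class-conditional laws is a modelling
  convenience (truncated normal), not a claim about tissue.
* Stitching is offset-grid only (no registration), and surface detection
  assumes a near-flat contact-probe geometry with a `flat` override.
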