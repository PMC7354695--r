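---
title: "Phasor-FLIM analysis of NAD(P)H metabolic state: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-FLIM analysis of NAD(P)H metabolic state: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorflim)
```

## The measurement and the model

Two-photon excitation near 710 nm makes the reduced coenzyme NAD(P)H the
dominant autofluorescent species in an unlabeled cell. Its fluorescence
lifetime reports its binding state: free NAD(P)H decays in about 0.4 ns,
protein-bound NAD(P)H in about 3.4 ns, so the bound/free balance is a
label-free proxy for the cell's glycolytic vs oxidative-phosphorylation
poise. Under oxidative stress a third species appears: long-lifetime
products of ROS-mediated lipid oxidation (LLS, roughly 8 ns).

The phasor approach avoids fitting multi-exponential decays. Each pixel's
photon-arrival histogram $c_k$ over one laser period $P$ is mapped to a
point in the plane at the $n$-th harmonic of the repetition rate
($\omega = 2\pi n / P$):

$$g = \frac{\sum_k c_k \cos(\omega t_k)}{\sum_k c_k}, \qquad
  s = \frac{\sum_k c_k \sin(\omega t_k)}{\sum_k c_k},$$

with $t_k$ the bin-centre times. Mono-exponential decays of lifetime
$\tau$ land on the *universal semicircle*
$g = 1/(1+(\omega\tau)^2)$, $s = \omega\tau/(1+(\omega\tau)^2)$; any
mixture lands at the intensity-weighted convex combination of its pure
components. Two species therefore span a chord, three a triangle, and
unmixing is linear geometry: orthogonal projection onto the chord for two
components, barycentric coordinates for three. Fractions are fractional
*intensities* (the quantity phasor mixing is linear in); no quantum-yield
correction is attempted, so they are not molar fractions.

A phasor can be read back as two single-exponential-equivalent lifetimes,
$\tau_\phi = \tan(\varphi)/\omega$ from the phase and
$\tau_m = \sqrt{1/(g^2+s^2) - 1}\,/\omega$ from the modulation; they agree
only for mono-exponential decays, and $\tau_\phi < \tau_m$ is the
classic signature of a lifetime mixture.

## Instrument calibration

A real detection chain adds a phase offset and demodulates the signal.
As in standard practice, the package calibrates against a measurement of
a mono-exponential reference dye of known lifetime (fluorescein at high
pH, 4 ns): the intensity-weighted mean phasor of the reference cube is
compared with the theoretical point on the universal circle, and the
polar corrections (phase difference, modulation ratio) are applied to
every subsequent pixel. `fit_calibration()` / `apply_calibration()`
implement exactly this; the correction also absorbs the small
time-binning bias discussed below.

## The synthetic acquisition model

No raw data are deposited for this experimental system, so the package
ships a first-class generator that emulates the acquisition:

* **Geometry** — non-overlapping elliptical cells (major semi-axis 14–22
  px on a 256×256 frame by default) with interior elliptical nuclei
  (axes 0.42 of the cell's). Nuclei are rendered at 0.4× the cytoplasm
  brightness, mirroring their visibly lower NAD(P)H signal; the
  cytoplasm carries a ±30% multiplicative granular texture emulating the
  patterned (mitochondria-rich) staining. Labels pair compartments
  without a second mask: nucleus $2k-1$, cytoplasm $2k$ for cell $k$.
* **Decays** — each pixel's expected histogram is
  $B \sum_i f_i E_i(t)$, where $E_i$ is the *wrapped* periodic
  mono-exponential $e^{-t/\tau_i}/(1-e^{-P/\tau_i})$ on $[0, P)$. The
  wrapped form matters: with an 80 MHz laser ($P = 12.5$ ns) an 8 ns
  species re-excites long before it has decayed, and only the wrapped
  form keeps the closed-form phasor exact. Bin contents are exact
  integrals of the delayed wrapped decay over each bin, so the injected
  instrument phase is honoured to well below a milliradian.
* **Instrument** — a configurable phase offset (default +0.35 rad) and
  demodulation factor (default 0.88) so calibration is non-trivially
  exercised, plus an optional Gaussian IRF. Demodulation is emulated by
  mixing the delayed decay with a uniform background, which keeps
  expected counts non-negative; this restricts the modulation factor to
  (0, 1], the physically relevant demodulation regime.
* **Photon budget** — the global brightness is scaled so the *expected*
  image mean equals `target_mean_counts` (default 100) times the
  condition's brightness scale, emulating the usual "acquire until ~100
  mean counts" stopping rule; counts are then Poisson.

### Condition presets

The experiment contrasts four treatments of insulin-secreting β-like
cells plus two controls. The effects being emulated are directions and
significance calls, not absolute phasor coordinates, so the presets are
chosen to reproduce orderings, with every number configurable:

| preset | cytoplasm bound fraction | nucleus | LLS | brightness |
|---|---|---|---|---|
| `maintenance` | 0.45 | 0.30 | 0 | 1 |
| `gsis` | 0.60 | 0.30 | 0 | 1.416 |
| `hyperglycemic` | 0.45 | 0.30 | 0.06 | 1.537 |
| `hyperglycemic_gsis` | 0.48 | 0.30 | 0.06 | 1.674 |
| `h2o2` | 0.45 | 0.30 | 0.25 | 1 |
| `nonresponder` | 0.45 | 0.30 | 0 | 1 |

The glucose-stimulation response is confined to the cytoplasm (the
nucleus keeps its bound fraction), which is what the compartment-resolved
analysis is designed to detect. The brightness scales encode the
intensity relationships of the emulated experiment:
hyperglycemic/maintenance intensity ratio 130.2/84.7 ≈
1.537, a 41.6% stimulated increment from maintenance and a blunted 8.9%
increment after chronic hyperglycemia. LLS is assigned to the cytoplasm
only, since lipid-oxidation products are cytoplasmic; the preset LLS
fractions (6% chronic hyperglycemia, 25% H₂O₂ positive control) are
ordered to reproduce the qualitative escalation of the oxidative-stress
signature. The `nonresponder` preset renders stimulated geometry with
maintenance fractions, emulating non-secreting control cell lines whose
phasor does not move.

### What the generator does *not* emulate

No optical point-spread blur, photobleaching, detector afterpulsing or
vendor electronics emulation. Cell boundaries are therefore razor-sharp,
which makes intensity-based segmentation somewhat easier than on real
images; passing segmentation tests show the algorithm is correct at its
operating point, not that it would hit the same recall on real
microscopy. Likewise, preset fractions are self-consistent ground truth,
so recovery tests validate the transform–calibrate–unmix chain, not the
biological values themselves.

## Numerical accuracy of the binned transform

The discrete bin-centre transform of a wrapped mono-exponential differs
from the continuous phasor by a factor whose logarithm is
$\theta^2/24 + i\,\omega\,\Delta t^2/(12\tau)$ with $\theta=\omega\Delta t$
(verified numerically across lifetimes). The modulus part is universal
and is removed inside `phasor_transform()` by the sinc correction
$\sin(\theta/2)/(\theta/2)$; the phase part depends on the (unknown)
lifetime and cannot be removed universally — at 256 bins it is
$\approx 10^{-4}/\tau$ rad and is largely absorbed by calibration.
Consequences for testing: exactness-grade assertions (closed-form
agreement to six decimals, on-circle residuals below $10^{-6}$,
containment within $10^{-9}$) are made in the fine-binning regime
(4096–8192 bins) where the residual is below tolerance, while
noise-level assertions use the realistic 256-bin configuration. Unmixing
against a basis anchored at *measured* pure-species positions is exact at
any binning and is also the recommended practice on real data.

Other numerical choices: pixels with fewer than 30 total counts are
masked (per-pixel phasors below that are noise-dominated); the mask-aware
3×3 median filter (one pass) is applied to g and s before unmixing,
standard practice for phasor maps; out-of-gamut pixels (outside the
chord/triangle, a normal consequence of photon noise) are clamped with
renormalization and flagged rather than dropped, keeping maps complete
and auditable; harmonics above $n_\text{bins}/2$ are rejected as aliased.

## Segmentation

ROIs in this kind of analysis are typically drawn by hand, picking
nuclei by their ellipsoidal shape and low NAD(P)H signal; unattended
tests need automation, and
user-supplied label masks are accepted everywhere as the manual-workflow
equivalent. `segment_cells()` uses Otsu thresholding on a lightly
smoothed intensity image with hole-filling (dim nuclei must not punch
holes in their cells) and an area filter; touching cells are analyzed as
clusters, matching the cluster-level analysis of adherent β-cells.
`segment_nuclei()` thresholds each cell at 0.7× its median intensity
(midway between the nucleus and cytoplasm brightness levels), then
applies area (≥30 px) and eccentricity (≤0.9) filters; the union of
accepted candidates forms the cell's nucleus compartment. A small
smoothing sigma (0.7 px) is deliberate: it suppresses Poisson speckle
without blurring the nucleus rim, which keeps nucleus ROIs essentially
free of bright cytoplasm contamination — important because ROI phasor
means are intensity-weighted, so a rim of cytoplasm pixels at 2.5× the
nucleus brightness would otherwise drag the nucleus summary toward the
cytoplasm and fake a nuclear metabolic response.

## Population statistics

Per-ROI summaries carry the intensity-weighted mean phasor of the ROI's
valid pixels. The conventional "90% confidence ellipsoid" of per-cell
phasor scatter plots is implemented as a 90% *coverage* ellipse of the
per-cell means: centre at the arithmetic mean, axes from the
sample-covariance eigen-decomposition scaled by
$\sqrt{\chi^2_{0.90,2}} \approx 2.146$ (coverage semantics, since the
level is stated as a population percentage). The
metabolic shift between conditions is the Euclidean distance between
ellipse centres of per-ROI means, not pooled pixel clouds, following the
"ellipsoid central points (average value)" convention. Group comparisons
use the two-sided Mann–Whitney test (exact null distribution when both
groups have ≤8 observations and no ties, tie-corrected normal
approximation otherwise); no multiple-testing correction is applied
because comparisons are single and pairwise. Percent increments
propagate standard errors to first order.

## Test design and problem sizes

The test suite regenerates every fixture in code. Scaled-down study
conditions are used where full-frame rendering would be wasteful:
direction-and-ordering checks run on 128×128 frames with 64 time bins,
2 fields × 3 cells per condition across seeds 0–9, which already gives
condition shifts 50× their standard error; desk-scale anchor checks
(calibration round-trip, mean-count contract) run at the full 256×256,
256-bin configuration. The anchors recomputed by
`scripts/acceptance.R` are: the calibrated reference-dye lifetime (4 ns),
the pure-LLS lifetime read back through the transform (8 ns), the
empirical coverage of the default confidence ellipse (90%), and the mean
photon count of a default acquisition (100 counts/pixel).

## Known limitations

NADH and NADPH are spectrally indistinguishable here; responses are
reported as bound/free fractional-intensity shifts, and changes can occur
in both numerator and denominator; fractions are intensity-weighted, not
molar; the pipeline has no single-enzyme resolution. Vendor FLIM formats
(.sdt, .fbd) are not read — the TIFF + JSON interchange format is the
extension point.
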