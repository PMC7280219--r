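---
title: "Scoring skin-condition severity from two-photon FLIM optical biopsies"
author: "flimscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring skin-condition severity from two-photon FLIM optical biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimscore)
```

## The measurement problem

Clinical grading of inflammatory skin disease (the Psoriasis Area and
Severity Index, PASI, and lesion-level scores such as the Local
Inflammation Severity, LIS) is observer-based and coarse. Two-photon
fluorescence lifetime microscopy offers a label-free alternative: a
volumetric "optical biopsy" of the epidermis in which endogenous
fluorophores -- chiefly NAD(P)H -- report both structure and metabolic
state. `flimscore` implements a fully automated analysis of such stacks
that ends in a single numerical severity score per imaging site, plus a
synthetic-cohort generator so that every stage can be validated against a
known ground truth.

The pipeline works on whole-frame statistics throughout. No cell
segmentation is attempted: segmentation of noisy in-vivo frames is
unreliable, and whole-frame statistics remain comparable even when lateral
motion distorts individual cells.

## The decay model and its fitting

Each pixel of a TCSPC frame holds a photon-arrival histogram modelled as a
two-component exponential decay

$$f(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2},$$

with the short component $\tau_1$ conventionally associated with bound/free
NAD(P)H dynamics and melanin, and the long component $\tau_2$ tracking the
metabolic state of keratinocytes. The signal-to-noise ratio of in-vivo
epidermal imaging supports two components; no third component or instrument
response deconvolution is attempted (the instrument response is treated as
an ideal delta).

Before fitting, decays are spatially binned: each pixel's trace becomes the
sum over the $(2n+1)\times(2n+1)$ window centred on it, with the default
binning factor $n = 4$ (a $9\times9$ window, the same convention as the
SPCImage software that is standard for this instrument class). The window
is clipped at frame edges.

The fit itself (`fitBiexponential`) is a weighted least-squares fit with
Poisson weights $1/\max(y_k, 1)$, solved by variable projection: for any
candidate lifetime pair the amplitudes have a closed-form non-negative
linear solution, so a deterministic Nelder-Mead search runs over
$(\log\tau_1, \log\tau_2)$ only. Numerical choices:

* lifetimes are bounded to $[0.01, 10]$ ns;
* the initializer is a log-linear fit to the decay tail (giving the
  $\tau_2$ start) with $\tau_1$ starting at $\tau_2/5$ -- deterministic, no
  random restarts;
* components are reported in ascending lifetime order;
* near-equal pairs ($\tau_2/\tau_1 < 1.1$) and negligible components
  (amplitude share $< 10^{-4}$) collapse to a single-component report with
  $a_2 = 0$, since such pairs are not identifiable;
* traces with fewer than `min_photons = 100` total counts are masked
  rather than fitted -- below that the two-component model is not
  identifiable at typical in-vivo noise levels;
* non-converged fits are masked rather than reported.

Count-based Poisson weighting is the field's standard but is known to bias
lifetimes slightly low when tail bins hold only a few photons; at the
default photon budgets (tens of thousands of photons per binned trace) the
bias on $\tau_2$ is a few percent, which is why recovery tests use a 5 %
band on frame means while noiseless traces are required to recover to
better than 1 %.

"Percentage of fluorescence from component $i$" is implemented as the
amplitude share $100\,a_i/(a_1+a_2)$, the SPCImage default; the
intensity-weighted alternative $a_i\tau_i/\sum_j a_j\tau_j$ is available
via `componentPercentages(..., intensity_weighted = TRUE)`.

## Structural texture features

Two frame-level features summarize sub-cellular structure of the
time-summed intensity image:

**Fourier parameter** (`fourierParameter`). Inflamed keratinocytes show
perinuclear clustering of mitochondria, which appears as sharp bright
puncta and raises high-spatial-frequency content. The feature is the ratio
of mean spectral magnitude $|F|$ in a high-frequency annulus
($24 \le r < 36$ px) to a medium-frequency annulus ($14 \le r < 24$ px) of
the centred 2-D FFT. Conventions worth stating: raw magnitude (not
log-magnitude) is averaged; annuli are inner-inclusive/outer-exclusive so
the shared $r = 24$ boundary is counted once; radii are quoted for a
512-pixel frame and scale proportionally for other sizes, so the same
physical frequencies are selected; the DC bin is outside every annulus,
making the ratio exactly invariant to constant offsets. The
high-over-medium direction is the default; an `invert` flag returns the
reciprocal, since only separability (not direction) matters downstream.

**Mean local entropy** (`localEntropyMean`). A per-pixel Shannon entropy
under a disk structuring element of radius 2 px (13 pixels), averaged over
the frame. Computing entropy locally and then averaging makes the feature
insensitive to slow illumination gradients. The frame is quantized to 256
grey levels over its min-max range, which makes the feature exactly
invariant to affine intensity rescaling; edge neighbourhoods are clipped.
A constant frame has zero entropy by definition (not an error).

## Depth features and the feature vectors

Layer selection is metadata-driven: the stratum granulosum (SG) and
stratum basale (SB) sections are picked as the frames whose recorded stage
depth is nearest the configured targets (`selectLayers`); automated
image-content layer detection is deliberately out of scope. "Optical
distance" between layers is the raw stage-depth difference with no
refractive-index correction. Two feature vectors are assembled:

* the 8-feature **condition vector** (one per imaging site):
  `r paste(CONDITION_FEATURES, collapse = ", ")`;
* the 5-feature **PASI vector** (one per psoriasis subject, using the
  inflamed and the contralateral non-lesional "pseudo-control" site):
  `r paste(PASI_FEATURES, collapse = ", ")`, where all ratios are
  inflamed over pseudo-control.

Sites or subjects with any unusable constituent (all pixels masked,
inconsistent layers, zero ratio denominators) are excluded and logged,
never imputed.

## Severity scoring

Features are standardized column-wise to zero mean and unit variance with
the population (divisor $N$) standard deviation -- with unit-variance
scaling the subsequent PCA is the correlation-matrix PCA. The principal
components are obtained by singular value decomposition of the centred,
scaled table (numerically preferable to forming the covariance matrix; the
test suite checks agreement with an explicit eigendecomposition). PC1 is
the severity axis. Its sign is a gauge freedom, fixed by:

* `orientPC1`: group labels are ordered (control < pseudo-control <
  eczema < psoriasis) and the sign is chosen so the least-severe present
  group has the lower mean score, ties toward $+1$;
* `orientPC1ByFeature` (used for the PASI analysis, which has no ordinal
  group label): the sign is chosen so that a feature known to increase
  with severity -- by default the inflamed-site SG-to-SB distance,
  epidermal thickening being an established psoriasis marker -- loads
  non-negatively on PC1. This avoids the circularity of orienting by the
  PASI correlation that is subsequently reported.

Cluster separation along the severity axis is quantified by the mean
silhouette width of the group labels on (PC1, PC2) plus pairwise PC1
group-mean gaps (`groupSeparation`). Correlation with clinical scores uses
the Pearson coefficient; two row units are supported, matching the two
analyses: one row per site for the condition analysis, one row per subject
for the PASI analysis.

PASI itself (`pasiTotal`) follows the standard arithmetic: per region,
severity = redness + thickness + scaling (each 0-4, so 0-12), region score
= area grade (0-6) times severity (0-72), and the total is the
body-surface-weighted sum with weights head 0.1, upper limbs 0.2, trunk
0.3, lower limbs 0.4 (the standard convention; configurable). Banding
splits at 10 (totals of 1-9 = "low", 10-29 = "high"). The combined
PASI + LIS band has no canonical clinical definition; the package provides
a configurable predicate (default: high if PASI >= 10 or LIS >= 7) and
marks it as an analysis convenience.

## What the synthetic cohort emulates

Because per-pixel clinical FLIM stacks are not publicly available, the
package ships a generator whose outputs have the statistical structure the
analysis assumes, with a stored ground truth:

* **Acquisition geometry**: 200 um x 200 um frames; 40 optical sections in
  5 um steps down to 200 um; 256 TCSPC bins over 12.5 ns (an 80 MHz
  repetition rate); default 512 x 512 px frames (configurable -- the pixel
  grid of the reference instrument class is not fixed by convention).
* **Photon physics**: per-pixel expected decay
  $A[(1-q)e^{-t/\tau_1} + q e^{-t/\tau_2}]$ with Poisson counts per bin;
  the amplitude scale $A$ is normalized so the mean per-pixel total equals
  `photons_per_pixel` (default 500 -- with the 9 x 9 binning window this
  puts ~40 000 photons in each fitted trace, where the two-component
  weighted fit recovers lifetimes to a few percent).
* **Texture**: cell-sized blobs with bright cytoplasm rings and darker
  nuclei; bright 1-2 px puncta at a group-dependent density (the
  mitochondrial-clustering proxy); smooth spatial fields modulating the
  amplitude fraction and the lifetimes themselves (metabolic
  heterogeneity). Texture is statistical, not anatomical -- no attempt at
  photorealistic skin, no motion artifacts.
* **Groups**: control, pseudo-control, eczema, psoriasis, with effect
  directions following the qualitative picture of psoriatic skin: longer
  lifetimes, deeper SG and thicker epidermis (lesional groups only --
  the pseudo-control site keeps control-like geometry because thickening
  is lesion-local, while its metabolic parameters shift, which is exactly
  the systemic-inflammation signal the condition analysis looks for),
  doubled puncta density, larger lifetime spread. Magnitudes are free
  simulation parameters, not measurements, and are all exposed in
  `cohortConfig()`.
* **Subjects**: one latent severity deviate per subject coherently scales
  all its parameters; psoriasis subjects get an inflamed site plus a
  pseudo-control site with the shift attenuated by half. PASI and LIS are
  drawn with a configurable correlation to the latent severity (default
  target r = 0.5), rounded and clamped to the clinical ranges 1-29 and
  1-10. With PASI mean 10 and SD 6 the low [1, 9] and high [10, 29] bands
  each capture about half the cohort.

Everything is a pure function of (parameters, seed): identical seeds give
bit-identical cohorts, and generation does not disturb the caller's RNG
stream.

Passing tests on these cohorts show that the pipeline recovers constructed
effects of realistic direction and size through the full measurement chain;
they cannot show robustness to optical aberrations, motion artifacts,
melanin-rich skin types, or anatomical texture that the generator does not
model.

## Problem sizes used by the shipped studies

The package's own validation studies (test suite and
`scripts/acceptance.R`) run a 10-seed cohort study with 20 control, 33
psoriasis and 20 eczema subjects per seed at reduced acquisition settings:
128 x 128 px frames, 128 time bins, section rendering restricted to the
two analysed layers, and stride-4 pixel subsampling inside
`fitFrame` (a regular subsample of ~1000 fitted pixels per frame, which
leaves frame-mean and SD statistics unbiased -- the stride-2 and stride-4
estimates of frame statistics agree to three decimals). At these sizes the
full study completes in minutes on a single core while preserving every
qualitative property of the full-resolution configuration: the expected
outcomes are that oriented PC1 group means order control < pseudo-control
< psoriasis with eczema between pseudo-control and psoriasis in at least
9 of 10 seeds, and that the PC1-PASI Pearson correlation averages inside
[0.3, 0.7] (the generator's coupling target of 0.5 minus integer
rounding/clamping of PASI, at the n = 33 sampling error of a correlation
coefficient).

## Known limitations

* The generator shares one latent severity scale across all parameters of
  a subject; real disease expression is less coherent, so PCA separation
  on synthetic cohorts is cleaner than clinical data would give.
* Count-weighted least squares (not maximum-likelihood Poisson fitting) is
  used for comparability with the standard software; its small low bias
  is documented above.
* Lifetime maps store no per-pixel uncertainty; frame SDs mix biological
  heterogeneity with estimator noise.
* The eczema group is modelled as intermediate between pseudo-control and
  psoriasis; it exists to test cluster placement, not to support
  differential diagnosis claims.
* Layer selection trusts depth metadata; no image-based layer detection.

## A short worked example

```{r example, eval = FALSE}
cfg <- cohortConfig(frame_size = 128L, n_time_bins = 128L,
                    render = "layers", fit = list(stride = 4L))
cohort <- generateCohort(c(control = 5, psoriasis = 5), cfg, seed = 7)
res <- runSeverityPipeline(cohort, cfg)
res$condition$separation$pc1_group_means
res$pasi$pearson_r_pasi
```
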