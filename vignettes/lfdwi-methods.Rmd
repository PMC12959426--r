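---
title: "Trace diffusion imaging at low field: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trace diffusion imaging at low field: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Point-of-care MRI at very low field strength (~0.064 T) can bring
diffusion-weighted imaging (DWI) to settings without a conventional
scanner, but the low signal-to-noise ratio makes small acute ischemic
lesions hard to see. Early low-field protocols acquire diffusion weighting
along a *single* gradient direction (SD). Signal in such an image depends
on the directional diffusivity $g^\top D g$ of each voxel's diffusion
tensor $D$, so coherent white-matter tracts — whose tensors are strongly
anisotropic — produce bright and dark streaks that vary with the angle
between the tract and the gradient. An acute ischemic lesion is an
*isotropic* region of restricted diffusion; in an SD image it competes
with this anatomical texture. Acquiring three orthogonal directions (MD)
and combining them into a trace-weighted image removes the directional
term: the geometric mean of the three signals depends only on the mean
diffusivity $\bar D = \mathrm{tr}(D)/3$, which is rotation invariant.
`lfdwi` implements this processing chain, a synthetic diffusion-tensor
head phantom to exercise it, and the statistics used to compare SD and MD
protocols: region-wise signal-uniformity comparison and lesion-detection
diagnostic accuracy.

## Signal model

Each voxel carries a symmetric positive semi-definite tensor $D$
(mm²/s) and a proton-density-weighted equilibrium signal $S_0$. A
diffusion acquisition with weighting $b$ (s/mm², here 900) along unit
direction $g$ measures

$$ S(g) = S_0 \exp(-b\, g^\top D g), $$

plus Rician noise: the magnitude of a complex Gaussian channel pair,
$M = \sqrt{(S+n_1)^2 + n_2^2}$ with $n_i \sim N(0,\sigma^2)$. On
background ($S=0$) this is Rayleigh with mean $\sigma\sqrt{\pi/2}$; at
high SNR it approaches additive Gaussian. The ADC map inverts the decay,
$\mathrm{ADC} = -\ln(S_b/S_0)/b$, with signals clamped at
$\varepsilon = 10^{-6}\max(S_0)$ before the log and the output clamped to
$[0, 4\times10^{-3}]$ mm²/s; clamp counts are reported as QA rather than
letting noise-driven log blow-ups reach downstream statistics.

The trace DWI is the geometric mean $(S_x S_y S_z)^{1/3}$ of the three
coregistered direction images, and the trace ADC is (by default) the
arithmetic mean of the three per-direction ADC maps. Where all signals
exceed $\varepsilon$ the two routes are identical:
$-\ln(\mathrm{trace}/S_0)/b = \overline{\mathrm{ADC}}$. Both routes are
exposed (`compute_trace_maps(method =)`) because printed pipelines rarely
say which one they used; they only differ at clamped voxels.

## The phantom

`build_phantom()` rasterises an ellipsoidal head (semi-axes 62 × 70 × 58
mm) into a cortical shell, two ventricular CSF bodies, four deep-gray
nuclei, and a white-matter interior carrying two anisotropic tract
systems: a pair of vertical corticospinal-like tubes (fibers along z) and
a corona-radiata-like fan whose fiber direction tilts smoothly away from
z with lateral position, in a plane set by a per-subject azimuth. Tissue
values are literature-typical adult values, not fitted to any dataset:

| class           | $S_0$ (a.u.) | eigenvalues ($10^{-3}$ mm²/s) |
|-----------------|---------------|-------------------------------|
| white matter    | 800           | isotropic 0.733               |
| tract           | 800           | (1.4, 0.4, 0.4)               |
| cortical gray   | 1000          | isotropic 0.8                 |
| deep gray       | 950           | isotropic 0.8                 |
| CSF             | 1600          | isotropic 3.0                 |
| lesion          | 1000          | isotropic 0.4                 |

Non-tract white matter is given the *same* mean diffusivity as the tract
(0.733e-3) so that, on trace maps, tract and surrounding white matter are
indistinguishable — exactly the anisotropy-suppression property under
study — while on single-direction maps the tract spans the full
$[\lambda_\perp, \lambda_\parallel]$ range with orientation. Lesions are
spheres of isotropic restricted diffusion (ADC 0.4e-3, below every
tissue's mean diffusivity) with mildly T2-hyperintense $S_0$.

The default grid is 96 × 96 × 48 voxels of 1.5 × 1.5 × 3 mm —
deliberately anisotropic so isotropic resampling is a real operation —
and the default noise targets a b=0 white-matter SNR of 15 for the
"v1-like" preset and 20 for the "v2-like" preset ($\sigma = S_0^{wm} /
\mathrm{SNR}$). The acquisition tables of the source hardware are not
public in the text this package draws on; these values are the package's
own, chosen once, and express only the direction "newer hardware, higher
SNR". Inter-series motion defaults to a small rigid transform (≤3 mm,
≤3° per axis, drawn per diffusion series), which makes coregistration a
meaningful, verifiable stage.

What the phantom deliberately does **not** model: real cortical folding
and anatomy, partial-volume mixtures at tissue boundaries, T1/T2
relaxation, eddy-current and susceptibility distortion, FLAIR contrast.
Tests passing on this phantom therefore validate the *pipeline
machinery* (map algebra, registration, resampling, statistics) and the
*mechanism* (anisotropy suppression), not clinical performance on human
brains.

## Processing chain

Mirroring the stated order of the source pipeline: each diffusion volume
is coregistered to its b=0 with a 12-parameter affine (translations,
rotations, scales, shears composed $T\,R_z R_y R_x\, S\, Sh$ about the
grid's world center); maps are computed on the native grid; maps and
masks are then interpolated to 1 mm isotropic (trilinear for images,
nearest-neighbour for masks).

Registration minimises the sum of squared differences (same subject, same
modality; the moving image is globally rescaled to the fixed image's mean
absolute intensity so a b=0 can serve as reference). It is
multi-resolution over block-averaged pyramids at factors 4, 2, 1 with
staged degrees of freedom: rigid at the coarse levels, the full affine
released only at the finest level. Two numerical choices matter and were
set by experiment during design:

* the rotation search is multi-started (±2° patterns) and the start is
  *selected at the middle pyramid level* — on a quasi-symmetric head the
  coarsest block-averaged level visibly aliases in-plane rotations and
  its cost ranking cannot be trusted;
* the finest level samples the fixed image on a stride-2 subgrid (the
  moving image stays full-resolution), and per-level iteration caps
  (50/33/20) replace a single large cap; on the recovery suite (20 random
  rigid transforms ≤3 mm/≤3°) this configuration recovers every
  transform to about 0.01 mm / 0.01° at about a fifth of the cost of the
  naive configuration.

Known limitation: on *noisy, diffusion-weighted* volumes the SSD surface
acquires near-degenerate minima a few degrees apart, because the moving
image's tract contrast differs from the b=0's. Residual misalignment of
that size blurs the trace maps slightly but does not change any result
direction in the analyses; same-contrast registration (what the
recovery suite checks) is unaffected.

## Uniformity analysis

For each subject passing the segmentation QC gate (supratentorial score
> 0.7 and infratentorial score > 0.1, strict; scores are synthetic
pass-through values here since the neural segmenter is out of scope), the
per-region sample standard deviation (n−1) of the 1 mm maps is computed
over each region of interest *minus the lesion mask*, for both sequence
types and both map kinds (DWI image and ADC map). SD-vs-MD pairs are
compared with the Wilcoxon matched-pairs signed-rank test: zero
differences dropped, exact tie-aware null distribution (midranks, shift
algorithm) up to n = 25 informative pairs, otherwise the
continuity-corrected normal approximation with the midrank variance
$\sum r_i^2/4$. The exact branch is validated against full enumeration of
all $2^n$ sign assignments.

## Detection analysis

The interactive threshold segmentation of the source workflow is
re-specified as a deterministic rule so it can be tested: threshold =
centre + k × spread of "normal-appearing brain" (the brain mask minus
the seed region), segmentation = the 6-connected suprathreshold
component containing the hottest seed-region voxel, components under 3
voxels discarded, default k = 3. The generic operation uses mean and SD
(`segment_lesion()`, bright polarity), matching the conventional
formulation.

The cohort *reading* wraps this operation with three choices that emerged
from design pilots and were then frozen:

* **Map and polarity.** Lesions are read on the ADC map, dark polarity,
  on the 1 mm interpolated maps — the interpretation images. (The DWI
  bright reading is exposed as an option.)
* **Reader smoothing.** The reading map is box-smoothed (3 mm
  half-width) with mask normalisation (smoothing `map × mask` and `mask`
  separately and dividing), emulating the visual integration scale of a
  human reader and preventing CSF/background values from bleeding across
  the parenchyma edge. Without this, single-voxel noise minima dominate
  seeded segmentation at SNR 15.
* **Robust spread.** The reading threshold uses median and 1.4826 × MAD
  instead of mean and SD. This is a deliberate deviation from the plain
  mean + k·SD reading: on single-direction maps the anisotropic tract
  voxels form a heavy tail that inflates the SD estimate so far that the
  dark threshold becomes unreachable and *no* lesion of any size is ever
  segmented — a degenerate reader contradicting the observed behaviour
  of single-direction protocols. The MAD variant keeps the threshold
  anchored to the normal-tissue mass while the anisotropy tail still
  (correctly) penalises the SD map relative to the trace map.

A lesion subject's reading is seeded at the true lesion neighbourhood
(ground truth stands in for the conventional-MRI-informed reader) and
counts as detected when the segmentation overlaps the truth mask by at
least one voxel; a mimic's reading is seeded at the most suspicious
(smoothed-extreme) spot and any surviving component counts as a false
positive.

Under the frozen defaults the simulated cohort reproduces the structure
of the clinical findings: the MD detection floor sits near 0.16 mL and
the SD floor near 0.3 mL; detection rises monotonically with lesion
volume on both sequences; and a 0.2 mL lesion placed 1 mm from the
corticospinal-like tube is detected on the trace maps but missed on the
single-z-direction maps in the large majority of noise realizations —
the single-direction miss being driven by the tract-inflated threshold
and by partial-volume contamination from the adjacent bright tract.

Diagnostic statistics are standard: ROC of detection against true lesion
volume (thresholds at observed volumes, trapezoid AUC ≡ pairwise
concordance with ties at 0.5, verified to 1e-12 against brute force),
Youden-index cut point with smallest-threshold tie-break, sensitivity /
specificity / PPV / NPV as percentages with exact Clopper–Pearson 95%
CIs (via `binom.test`, cross-checked against the beta-quantile closed
form), Fleiss κ between two synthetic raters (the same reading at k = 3
and k = 3.5, restricted to lesions > 1 mL plus mimics) with a
500-resample subject bootstrap percentile CI, and the conventional
interpretation bands (< 0 poor, ≤ 0.2 slight, ≤ 0.4 fair, ≤ 0.6
moderate, ≤ 0.8 substantial, ≤ 1 almost perfect; upper boundaries
inclusive).

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; per-subject seeds derive
from the base seed by addition, and noise seeds are drawn from the
seeded subject stream, so cohorts are bit-reproducible.
`generate_cohort()` writes a manifest recording the configuration, its
hash, all seeds and produced files. The shipped analyses use desk-scale
problem sizes chosen as the package's defaults: 12 subjects for the
uniformity comparison, 24 lesion subjects + 8 mimics for the detection
cohort (40 subjects in the monotonicity check of the test suite), 10
noise seeds for the mechanism case, and the default 96 × 96 × 48
acquisition grid throughout. Persisted volumes are float32; statistics
are computed in float64. Numerical tie-breaks and degenerate-input rules
(log clamping, zero-difference drops, degenerate bootstrap resamples,
single-category κ) are stated in the respective function documentation
and exercised by the test suite.
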