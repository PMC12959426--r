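# lfdwi — trace diffusion-weighted imaging and lesion detection at low field

Portable MRI scanners operating near 0.064 T promise stroke imaging at the
bedside, but their diffusion-weighted images (DWI) are noisy, and protocols
that acquire a single diffusion direction superimpose white-matter-tract
texture on the image: the signal along gradient direction `g` is

    S(g) = S0 · exp(−b · gᵀ D g),        b = 900 s/mm²

so anisotropic tract tensors `D` shade the image with orientation-dependent
contrast that can hide a small isotropic ischemic lesion. Acquiring three
orthogonal directions and combining them into a trace-weighted image,

    trace DWI = (Sx · Sy · Sz)^(1/3),    trace ADC = (ADCx + ADCy + ADCz)/3,

cancels the directional term — the contrast depends only on the mean
diffusivity tr(D)/3, which is rotation invariant — and so improves signal
uniformity and the detection of small lesions.

`lfdwi` is an R package plus analysis workflow that implements and tests
this processing chain end to end on a synthetic diffusion-tensor head
phantom:

* **Phantom + simulator** — ellipsoidal head with cortex, deep gray
  nuclei, ventricles, anisotropic tract systems (a vertical
  corticospinal-like tube pair and a fanning bundle with smoothly varying
  fiber orientation), spherical restricted-diffusion lesions (0.05–5 mL),
  tensor signal model, Rician noise, per-series rigid motion.
* **Map synthesis** — per-direction ADC with log-safety clamping, trace
  DWI/ADC, 12-parameter affine coregistration of each direction volume to
  its b=0 (multi-resolution SSD), interpolation to 1 mm isotropic.
* **Uniformity analysis** — QC gating, per-region signal standard
  deviation with lesion subtraction, paired Wilcoxon signed-rank test
  (exact tie-aware branch up to n = 25).
* **Detection analysis** — seeded threshold segmentation, lesion volumes,
  ROC of detection against true lesion volume with Youden cut points,
  sensitivity/specificity/PPV/NPV with exact Clopper–Pearson CIs, Fleiss
  κ between synthetic raters with a 500-resample bootstrap CI and
  Landis–Koch bands.

NIfTI I/O is handled by RNifti; resampling runs in compiled code (Rcpp);
everything else is base R.

## Worked example

Simulate one subject under the default low-field conditions (96×96×48 grid
at 1.5×1.5×3 mm, b = 900 s/mm², white-matter SNR 15, ≤3 mm/3° inter-series
motion), run the processing chain, and compare white-matter uniformity:

```r
library(lfdwi)
cfg  <- as_run_config(list(seed = 1))
sub  <- simulate_subject(cfg, 1)        # phantom + SD and MD series
proc <- process_subject(sub, cfg)       # register, maps, 1 mm interpolation

region_sd(proc$iso$adc_sd,    proc$iso$masks["white_matter"], proc$iso$lesion)
#> white_matter
#> 0.0002163          # single-direction ADC, mm^2/s
region_sd(proc$iso$trace_adc, proc$iso$masks["white_matter"], proc$iso$lesion)
#> white_matter
#> 6.55e-05           # trace ADC: ~3x more uniform
read_subject(proc, sub, "md")$detected  # lesion reading on the trace ADC
#> TRUE
```

The tract voxels span directional diffusivities 0.4–1.4 ×10⁻³ mm²/s on
single-direction maps but collapse to the white-matter mean diffusivity
0.733 ×10⁻³ on the trace maps — the standard deviation ratio above is that
mechanism, measured.

The cohort-level analyses are the numbered drivers:

```sh
Rscript analysis/01_simulate_cohort.R   # writes scratch/cohort_demo + manifest
Rscript analysis/02_trace_maps.R        # registration + trace maps, physics check
Rscript analysis/03_uniformity.R        # 12 subjects: per-region SD + Wilcoxon
Rscript analysis/04_detection.R         # 24 lesions + 8 mimics: ROC, kappa, CIs
```

Their tables land under `results/`. On the shipped seeds the uniformity
run reports the trace maps more uniform than the single-direction maps in
the white matter of all 12 subjects (paired Wilcoxon p = 0.000488), and
the detection run reports a lower detection floor on the
multi-direction maps (smallest detected lesion 0.13 mL vs 0.24 mL on
single-direction).

## Layout

```
R/                  package code (phantom, simulation, maps, registration,
                    uniformity and detection statistics, cohort drivers)
src/                Rcpp resampling/SSD kernel
analysis/           numbered workflow drivers (thin wrappers over R/)
scripts/acceptance.R  end-to-end reproduction script
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette: models, parameters, design choices
```
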