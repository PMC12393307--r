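# laminarbold

Cortical-depth-dependent ("laminar") analysis of block-design BOLD fMRI,
aimed at developmental questions: how does the haemodynamic response to a
sensorimotor stimulus differ across cortical depths, and between preterm,
term and adult brains? The package is built for methodologists who want to
exercise and validate the full analysis chain on synthetic data with known
ground truth — there is a forward generator for every quantity the pipeline
estimates.

## What it implements

* **Synthetic 4D BOLD generator** — curved or flat cortical ribbon at
  0.8 mm isotropic, 26.6 s on/off blocks at TR 2.66 s, age-specific response
  shapes (preterm: delayed biphasic peaks near 13 s and 27 s; term: single
  peak, plateau and post-stimulus undershoot; adult: peak at 8 s, undershoot
  near 32 s), depth-dependent peak amplitudes (e.g. 3.0/1.5/1.0 % at
  superficial/middle/deep depths), drift, thermal noise and head-motion
  events, all recorded in a reproducible ground-truth object.
* **Preprocessing** — slice-timing interpolation, denoising hook,
  translation registration or known-motion ingestion, motion-parameter
  regression, 0.02 Hz high-pass (Gaussian running-line; DCT option), RMS
  outlier detection, and trial censoring at 0.8 mm displacement.
* **GLM activation mapping** — age-specific response basis, optional AR(1)
  prewhitening, z > 3.1 thresholding, percent-signal-change conversion by
  the peak-to-peak regressor-height convention.
* **Laminar machinery** — in-plane upsampling to 0.16 × 0.16 × 0.8 mm,
  three equivolume depth bins (equal-volume split of the sorted normalized
  depth), seven tangential columns per slice, and final-ROI selection of the
  top 40 % of columns ranked by *deep-bin* percent signal change, which
  counteracts the superficial (pial-vein) bias of gradient-echo BOLD.
* **Depth-ratio statistics** — per-trial maximum PSC per depth bin,
  superficial:middle / superficial:deep / middle:deep ratios, Kruskal–Wallis
  across age groups with Dunn post-hoc tests and Bonferroni adjustment.
* **Vessel biophysics** — the infinite-cylinder extravascular field model:

  outside a vessel of radius R at angle θ to B0,
  ΔB = Δχ/2 · (R/r)² · cos(2φ) · sin²θ (in ppm), with
  Δχ = Hct · (1 − Y) · Δχ_do for whole blood, and the closed-form distance
  r* = R · sqrt(Δχ sin²θ / 2τ) at which the field falls to a negligibility
  threshold τ.

## Worked example

How far does the field perturbation of a large pial vein reach? Sweeping the
blood–tissue susceptibility difference at a 32.5 µm vessel radius,
perpendicular to B0, and asking where the field drops to 0.02 ppm:

```r
library(laminarbold)
sapply(c(0.5, 1.0, 1.5, 2.0), function(dc)
  threshold_distance(vessel_model(32.5, dc, theta = 90), 0.02)$distance_mm)
#> [1] 0.08 0.13 0.17 0.20
```

So even a four-fold susceptibility increase keeps the perturbation within
0.2 mm of the vessel wall — and because the distance scales with vessel
radius, a neonate-like vein (half the adult diameter, double the Δχ) has a
*smaller* footprint (0.13 mm) than an adult-like one.

Running the full synthetic study for a preterm and an adult group:

```r
cfg <- default_config(seed = 1)
cfg$groups <- c("preterm", "adult")
res <- run_pipeline(cfg)

avg <- res$groups$preterm$average
sapply(split(avg, avg$depth_bin), function(d) max(d$mean))
#>    1    2    3
#> 2.21 1.37 1.01        # peak PSC per depth bin, superficial -> deep

res$tests$sup_mid
#> Kruskal-Wallis: H(1) = 9.80, p = 0.00175
#> Dunn post-hoc (Bonferroni-adjusted):
#>  group1  group2     z       p   p_adj
#>   adult preterm -3.13 0.00175 0.00175
```

The preterm per-bin peaks (2.21/1.37/1.01 %) recover the generated
3.0/1.5/1.0 % profile up to the attenuation a 0.8 mm acquisition imposes on
0.67 mm depth bins (the superficial bin, flush against the pial boundary,
loses the most); at finer simulation resolution the recovery is within a few
percent (see the vignette). The rank test detects the group difference in
the superficial:middle ratio.

A thin CLI wraps the same functions
(`exec/laminarbold biophys|simulate|run-all`).

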