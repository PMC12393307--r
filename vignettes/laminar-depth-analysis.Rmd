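---
title: "Cortical-depth-dependent BOLD analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical-depth-dependent BOLD analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarbold)
```

## What this package models

High-field BOLD fMRI can resolve haemodynamic responses across the depth of
the cortical sheet. In developmental applications the question is whether the
response to a sensorimotor stimulus differs across cortical depths — and
between preterm, term and adult brains — after accounting for the superficial
("pial") bias of gradient-echo BOLD, which is dominated by draining veins at
the cortical surface. `laminarbold` implements the analysis machinery for
this question on synthetic data: a forward generator of 4D BOLD acquisitions
over a cortical ribbon, a minimal preprocessing chain, block-design GLM
activation mapping, equivolume depth binning with column-based ROI selection,
depth-resolved trial statistics, and an infinite-cylinder model of the
extravascular fields around pial veins.

Everything runs on simulated data whose ground truth is recorded, so each
stage can be tested by parameter recovery.

## The vessel field model

A vein is modelled as an infinite cylinder of radius $R$ at angle $\theta$ to
the main field $B_0$, with a whole-blood-to-tissue susceptibility difference
$\Delta\chi$. The field offset at distance $r$ from the axis and azimuth
$\varphi$ is

$$
\Delta B_z =
\begin{cases}
  \dfrac{\Delta\chi}{2}\left(\dfrac{R}{r}\right)^2 \cos(2\varphi)\,\sin^2\theta,
    & r \ge R\\[2ex]
  \dfrac{\Delta\chi}{6}\left(3\cos^2\theta - 1\right), & r < R
\end{cases}
$$

in ppm of $B_0$. The azimuth $\varphi = 0$ maximises the outside field, and a
perpendicular vessel ($\theta = 90^\circ$) maximises it over orientations, so
profiles and threshold distances are evaluated there: they bound the spatial
extent of the perturbation. The whole-blood value follows
$\Delta\chi = \mathrm{Hct}\,(1 - Y)\,\Delta\chi_{\mathrm{do}}$ with
$\Delta\chi_{\mathrm{do}} = 0.264$ ppm between fully deoxygenated and fully
oxygenated blood on the cgs scale; because tabulated blood-tissue values of
0.5–2 ppm presuppose the rationalised-SI scale (cgs values carry an extra
$4\pi$), `blood_properties()` carries an explicit convention flag and
`blood_tissue_susceptibility()` applies the $4\pi$ only under
`"rationalised-SI"`. Sweep values in ppm are otherwise taken as direct inputs.

The "negligibility distance" inverts the outside branch in closed form,

$$r^* = R\sqrt{\Delta\chi \sin^2\theta / (2\,\tau)},$$

for a threshold $\tau$ (0.02 ppm by default) and reports $(r^* - R)$ in mm,
rounded to two decimals for display while the exact value is kept in the
result object. If the wall field does not exceed $\tau$ the distance is
reported as 0 with an `exceeded = FALSE` flag rather than an error. Because
$r^*$ scales with $R$ and with $\sqrt{\Delta\chi}$, halving the vessel radius
halves the distance at fixed $\Delta\chi$ — which is why a neonate-like vein
(32.5 µm radius, 1 ppm) has a *smaller* field footprint (0.13 mm) than an
adult-like vein (65 µm, 0.5 ppm; ≈0.17 mm by this closed form), despite the
doubled susceptibility difference.

```{r}
threshold_distance(vessel_model(radius = 32.5, delta_chi = 1.0, theta = 90),
                   threshold = 0.02)
```

Whether published figures of this quantity used the $\varphi = 0$ profile or
an azimuthal average is generally not stated; we use $\varphi = 0$
(the maximising azimuth) and interpret "negligible" as the azimuth-maximised
magnitude falling to the threshold. Intravascular signal, diffusion
narrowing, and vessel networks are out of scope.

## The synthetic generator

`make_ribbon()` builds a voxelised grey-matter ribbon, either a flat slab or
a quarter-annulus slice replicated across slices (pial surface = outer
radius, white matter = inner). The annulus is the default study geometry:
curvature makes voxel centres sample depth continuously, as gyral anatomy
does. The stored depth field is *volume-normalized* (equivolume) depth — the
fraction of ribbon volume superficial to the voxel — so equal-volume layers
are equal intervals of depth; on the annulus
$d = (b^2 - r^2)/(b^2 - a^2)$.

`make_paradigm()` encodes the block design: 26.6 s of stimulation alternating
with 26.6 s of rest at TR 2.66 s (10 volumes per phase), 7 blocks by default
(7–12 in typical sessions), with a leading rest block.

`make_response_model()` provides the age-specific response to one block as a
sum of gamma-shaped components plus a smoothed plateau and a negative
post-stimulus component, normalised to unit peak. Only landmark times are
treated as constrained; the functional form is a modelling convenience:

| group       | onset | peak(s)    | plateau | undershoot minimum |
|-------------|-------|------------|---------|--------------------|
| preterm     | 5 s   | 13 s, 27 s | none    | none (baseline ~43 s) |
| early-term  | 4 s   | 13 s       | yes     | ~ -0.12 of peak, ~33 s |
| late-term   | 3.5 s | 13 s       | yes     | ~ -0.17 of peak, ~33 s |
| adult       | 1 s   | 8 s        | yes     | ~ -0.20 of peak, ~32 s |

The depth-amplitude profile assigns a peak percent signal change (PSC) to
each equivolume depth third: 3.0 / 1.5 / 1.0 % (superficial / middle / deep)
for the neonatal groups and 2.5 / 2.0 / 1.5 % for adults. The default profile
is a *step* over the three depth thirds, so the per-bin ground truth is
exactly the anchor value; a piecewise-linear profile between bin-centre
anchors is available (`profile = "linear"`) for sensitivity analyses, with
the caveat that bin means then differ from the anchors by construction
(≈ ±7 %). Whether a post-stimulus undershoot should scale with depth
amplitude or be depth-independent is unsettled; the shape undershoot is a
fraction of peak, so it scales with the depth amplitude by default, and a
depth-independent variant can be built through `shape_params` overrides.

`simulate_bold()` composes signal = baseline × (1 + PSC(depth) ×
shape(t)/100), a linear plus half-cosine drift, i.i.d. Gaussian thermal noise
(sd in percent of the 1000-unit baseline, default 0.2 %), and discrete
head-motion events applied as whole-volume nearest-voxel translations. White
matter is simulated at 80 % and exterior at 10 % of baseline. The generator
is bit-reproducible under its seed, and everything it used is returned as a
`ground_truth` object.

What the generator does **not** emulate: EPI distortion, physiological
(cardiac/respiratory) noise, spatially correlated thermal noise, multi-coil
reconstruction artefacts, rotational motion (available in the motion trace
but not in image formation), partial-volume structure within acquisition
voxels, or realistic cortical folding. Passing recovery tests therefore shows
pipeline fidelity under idealised acquisition physics, not robustness to all
real-data failure modes.

## Preprocessing

The chain mirrors minimal laminar practice (no spatial smoothing, to
preserve spatial specificity): slice-timing interpolation to the middle
slice, a denoising hook, motion handling, motion-parameter regression, and
0.02 Hz high-pass filtering.

Two choices deserve comment.

**High-pass kernel.** The default filter is a Gaussian-weighted running-line
(local weighted linear fit, temporal sd = half the cutoff period, i.e. 25 s
at 0.02 Hz) subtracted from the data, with the mean re-added. A sharp
discrete-cosine projection at the same nominal cutoff would *remove* the
block-design fundamental (1/53.2 s = 0.0188 Hz < 0.02 Hz) and with it most
task power; the running line passes it at ≈95 % while removing linear drift
exactly (a local linear fit reproduces polynomials of degree one, edges
included). The DCT projection is retained as `method = "dct"` for designs
whose task frequencies sit well above the cutoff.

**Motion.** Full rigid-body registration is out of scope; the package offers
translation-only correlation registration over a small integer-voxel search
window (`register_translation()`), and the pipeline can ingest the
generator's known motion trace instead. The censoring displacement is the
Euclidean norm of the three translations (rotation-to-displacement conversion
at a 50 mm radius is available but off by default, since the metric behind a
published "0.8 mm" criterion is rarely stated). A trial is dropped when any
of its volumes exceeds the threshold *strictly*, so a displacement of exactly
0.8 mm (one acquisition voxel) is retained. Volume outliers are flagged by
root-mean-square intensity difference to the reference (first) volume with a
boxplot rule (75th percentile + 1.5 IQR) — a reasonable stand-in for a
tool-specific default the source pipelines leave unstated. The NORDIC-style
thermal denoising stage of magnitude data is represented by a pass-through
hook (with an optional simple temporal-PCA soft threshold, off by default):
the method itself is published elsewhere and is not re-implemented here.

## GLM and percent signal change

The task regressor is the superposition of the age-group block response at
every stimulus onset (equivalently, the onset impulse train convolved with
the block response; a delta-like basis reduces it to the stimulus boxcar).
Since the data are high-pass filtered, the pipeline applies the same filter
to the task column. Voxelwise OLS yields the effect size; `prewhiten = TRUE`
estimates a global AR(1) from residuals and refits after Cochrane–Orcutt
transformation — a deliberately simple stand-in for richer autocorrelation
models, adequate at these run lengths. The t statistic maps to z through the
normal quantile (log-scale tail probabilities, capped at |z| = 40), and
activation masks threshold at z > 3.1, strict. PSC conversion follows the
peak-to-peak regressor-height convention:
psc = 100 · β · ptp(task) / voxel temporal mean, with non-positive means
masked. Cluster-extent correction and group-level mapping are out of scope —
group inference happens on depth ratios, not maps.

## Depth bins, columns and ROI selection

Analysis happens on a refined grid (0.16 × 0.16 × 0.8 mm, a ×5 in-plane
refinement of the 0.8 mm acquisition). Labels are upsampled by
nearest-neighbour block replication (area-exact); analytic ribbons are
regenerated from their boundary descriptors at the finer grid, mirroring
manual ROI refinement at high resolution. The 4D data and psc map are
resampled by nearest-neighbour by default (matching the common resampling
tool's default and adding no artificial partial-volume mixing); linear
interpolation is available.

`equivolume_bins()` sorts ROI voxels by normalized depth within each slice
and splits them into equal voxel-count (hence equal-volume) groups — the
equivolume principle without any external tool. On a flat slab this reduces
to equal-thickness thirds; on an annulus the discrete boundaries converge to
the closed-form equal-area radii $\sqrt{a^2 + k(b^2 - a^2)/n}$, which the
test suite verifies within one voxel on randomised annuli. The split is
per-slice rather than per-column: on the analytic geometries used the two
coincide (columns are angular sectors of an annulus with identical depth
structure), and a per-slice split is stable for the narrow columns a 7-way
segmentation produces.

`segment_columns()` divides each slice's ROI into seven contiguous columns
of equal tangential extent (equal x-span for a slab, equal angular span for
an annulus), each crossing all depth bins. Equal extent rather than equal
voxel count is a free choice; it keeps columns geometrically comparable.

`select_columns()` ranks columns by the mean psc over their deepest-bin
voxels and keeps the top 40 % (k = ceiling(0.4 × n) columns, ties at the
threshold kept), then takes the union over all depth bins as the final ROI.
Ranking on the *deep* bin counteracts the pial bias: superficial psc is
inflated near draining veins, so selecting on deep-bin signal favours columns
whose activation reaches the depth of the cortex. "Top 40th centile" is
ambiguous between "top 40 % of columns" and "above the 40th percentile"
(top 60 %); the anti-pial-bias motivation fits the stricter reading, which is
the one implemented (the centile is configurable). Selection is invariant
under monotone rescaling of the psc map.

## Trial statistics

`extract_trials()` averages the (preprocessed, refined-grid) signal over
each depth bin's final-ROI voxels at the 20 TRs of each trial (10 on + 10
off). `baseline_psc()` applies the age-specific baseline conventions exactly
as stated for the source pipelines: neonates use the mean of the *first
stimulus-on* TR and the last stimulus-off TR of the trial (the response
onset delay makes the first on-TR effectively pre-response); adults use the
mean of the last two stimulus-off TRs. A pre-stimulus baseline mode is
provided for sensitivity analysis. Group trial averages are pointwise means
± SEM over kept (uncensored) trials.

The depth-ratio statistic takes, per trial and depth bin, the maximum PSC
over the trial (model-free, no smoothing — peak timing is similar across
depths, and a model-based "active window" would import response-shape
assumptions), and forms superficial:middle, superficial:deep and middle:deep
ratios; non-positive denominators flag the row rather than erroring. Trials
are pooled across subjects within a group as independent observations — the
convention of the trial-level comparison this mirrors — with the caveat that
pooling ignores within-subject correlation; a subject-level aggregation is a
straightforward pre-step (average ratios per subject before testing).

`kruskal_dunn()` runs the tie-corrected Kruskal–Wallis test (via
`stats::kruskal.test`) and Dunn's pairwise z tests on mean ranks with the
tie-corrected variance; each pairwise p is multiplied by the number of pairs
(6 for four groups) and capped at 1 (Bonferroni). All observations identical
returns H = 0, p = 1 rather than NaN.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based in world-coordinate arithmetic, time intervals
  half-open [onset, onset + duration); block and rest durations must be
  integer multiples of TR.
* Equal-count bin splits place boundaries between adjacent sorted depths;
  label upsampling is nearest-neighbour to avoid label mixing.
* The z cap (|z| ≤ 40) keeps noiseless fits finite; rank-deficient confound
  matrices drop collinear columns with a warning; an all-zero response
  override yields an all-zero shape rather than dividing by zero.
* Determinism: every stochastic component draws from the seed recorded in
  the ground truth / config; identical seeds give bit-identical volumes.

## Problem sizes

The shipped tests and demonstrations use deliberately small grids: annulus
ribbons of a few hundred grey-matter voxels per slice, two slices, 2–14
blocks, and 10,000 replicates for null-calibration checks. These sizes are
chosen so the whole suite runs in seconds while leaving the discrete
geometry coarse enough to exercise the voxel-rounding paths. The
parameter-recovery experiment simulates the acquisition at the analysis
in-plane resolution (0.16 mm): at the acquisition default (0.8 mm voxels on
a 2 mm ribbon, bins ≈0.67 mm) per-bin amplitudes are physically attenuated
by voxel-scale smearing — the superficial bin most, since it abuts the pial
boundary — which is a property of the measurement, not of the pipeline, and
is visible in the study-scale demonstration below.

```{r}
cfg <- default_config(seed = 1)
cfg$groups <- "preterm"
res <- run_pipeline(cfg)
avg <- res$groups$preterm$average
sapply(split(avg, avg$depth_bin), function(d) max(d$mean))
```

## Known limitations

* Translation-only motion model and registration; no rotations in image
  formation.
* AR(1) prewhitening only; no spatial autocorrelation modelling.
* One ROI, one hemisphere; no surface meshes or atlas anatomy.
* Trial pooling across subjects treats trials as exchangeable within group.
* The equivolume split is per-slice; strongly asymmetric ROIs would need the
  per-column variant.
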