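---
title: "MitoPulse: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MitoPulse: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoPulse)
```

## The biological setting

During spontaneous maturation of a mouse oocyte — from release of the
IBMX block, through germinal vesicle breakdown (GVBD, ~1 h), spindle
migration (~5–7 h), to first polar body extrusion and metaphase II
(~11–12 h) — cytosolic and mitochondrial ATP levels rise in three distinct
pulses. ATP is read out as firefly-luciferase luminescence (photon counts
per 30-s bin over a 13–16 h recording). In parallel, the mitochondria
themselves remodel: they aggregate into large clusters and form a dense
peri-nuclear ring at phases of high ATP production, and disperse into many
small clusters in between. MitoPulse implements both arms of that analysis —
pulse detection in luminescence traces, and cluster/ring quantification in
equatorial confocal sections — together with synthetic-data generators that
provide ground truth for validating every step.

## The trace model

A non-maturing (IBMX-arrested) oocyte produces a smooth luminescence curve
reflecting luciferase expression from injected cRNA followed by destruction
of the protein. We model the expected photon count per bin as a scaled
Weibull density plus a dark-count offset:

$$
m(t) = b + A \, \frac{k}{\lambda}\Big(\frac{t-t_0}{\lambda}\Big)^{k-1}
  e^{-((t-t_0)/\lambda)^k} \,\Delta t
  \quad (t > t_0; \; m(t) = b \text{ otherwise}),
$$

where $A$ is the total photon budget of the expression episode, $k$ and
$\lambda$ (hours) shape the rise and decay, $t_0$ is the expression onset
and $b$ is the flat offset in counts/bin. The factor $\Delta t$ (the bin
width in hours) makes $A$ a photon total rather than a rate; with the
default $A = 2\times 10^6$, $k = 2.2$, $\lambda = 9$ h, $b = 50$, the curve
peaks near 1,700 counts/bin — a realistic operating point for an
intensified-CCD photon-counting camera. A log-normal density is available
as an alternative baseline family (`model = "lognormal"`); the choice is
left to the caller, with no automatic selection.

ATP pulses are superimposed multiplicatively as raised-cosine bumps:
pulse $j$ with center $c_j$, half-width $w_j$ and fractional amplitude
$a_j$ multiplies the baseline by
$1 + a_j\,\tfrac12(1 + \cos(\pi (t - c_j)/w_j))$ on $|t - c_j| \le w_j$.
The default schedule places pulses at 1.5, 6.0 and 11.5 h (half-widths
0.5, 1.0, 0.5 h; amplitudes 0.15), matching the observed timing of GVBD,
spindle migration, and the MI–MII transition. Whether the underlying
physiology is multiplicative or additive is not knowable from the
recordings; we chose multiplicative (ATP production scales the luciferase
flux) and expose an additive mode. Counts are drawn as independent
Poisson variables per bin — the physically correct noise model for photon
counting — or returned noiseless for oracle tests.

Treatment presets edit the schedule: `ibmx_arrest` retains no pulses;
`nocodazole` and `enucleation` retain only the first two (the third pulse
requires completion of meiosis I); `cytochalasin_b` removes the first two
and retains a ×0.3-attenuated third pulse in 14/36 of the cohort (assigned
deterministically to the first `round(14/36 * n)` oocytes so that an arm is
reproducible from its seed alone).

## Baseline fitting and pulse detection

`fitBaseline()` fits the five parameters by bounded Levenberg–Marquardt
least squares (`minpack.lm`), starting from moment-based guesses ($t_0$ at
the first bin, $\lambda$ at the smoothed count peak, $k = 2$, $A$ the total
count, $b$ the minimum count). On a noiseless trace the generator
parameters are recovered to well below $10^{-3}$ relative error. The fit is
single-pass on the raw trace, pulses included; the pulses occupy a small
fraction of the recording and bias the baseline only slightly (the
detection margins absorb it). A non-converged fit is flagged and refused by
the detector unless forced.

`detectPulses()` normalizes residuals on the Poisson scale,
$z_i = r_i / \sqrt{\max(\hat m_i, 1)}$ — counts span orders of magnitude
along the expression curve, so a global residual SD would be badly
miscalibrated at both ends — then smooths $z$ with a centered moving
average (default 21 bins ≈ 10 min) and reports maximal runs of smoothed
$z > \tau$ (default $\tau = 2$) lasting at least 15 min. Runs separated by
at most 30 min are merged (closed interval: a gap of exactly 30 min
merges), and the first and last 30 min of the recording are ignored, where
the moving average is edge-biased and expression onset transients live. The
duration filter is applied before merging. Each pulse reports its start,
peak and end times, peak smoothed $z$, and the integrated raw residual
(excess photons). `summarizeTrace()` classifies a trace as maturing-like
(≥ 3 pulses), partial (1–2) or arrested-like (0).

Under the default study conditions the detector recovers exactly three
pulses on maturing simulations and zero on arrested ones in ≥ 95/100 seeds
(in our runs, 100/100 for maturing, nocodazole and arrested arms), with
peak times within ±0.5 h of the scheduled centers. These rates are computed
by the test suite and the cohort runner, not asserted from memory.

## The image model

`simulateImage()` emulates a mitotracker-stained equatorial section:
a 720 × 720 px field at 0.1 µm/px holding a 35-µm-radius ooplasm disc
(a ~70 µm mouse oocyte), flat background (level 100), and clusters rendered
as filled ellipses (axis ratio U(1, 2), random orientation) of intensity
1000 with additive Gaussian noise of SD 50 (5% of cluster intensity).
Cluster areas are log-normal with preset arithmetic mean and CV 0.4,
truncated below at 0.2 µm² — the single-mitochondrion floor: one
mitochondrion is ~0.5–1 µm across, i.e. 0.2–0.8 µm² in section, so nothing
smaller than 0.2 µm² can be a real cluster. Placement is by rejection
sampling with overlap forbidden (including diagonal contact, so
ground-truth components can never merge under 8-connectivity); an
over-crowded configuration fails loudly with the achieved density after a
bounded number of retries.

Presets encode the two printed regimes: `aggregated` (66 clusters, mean
4.7 µm²) and `dispersed` (102 clusters, mean 2.6 µm²); `gvbd_ring` adds a
peri-nuclear ring — 60% of the clusters confined to a 6-µm-wide annulus
starting at 13 µm radius, around a 12-µm GV exclusion disc; `cytochalasin`
reuses the dispersed pattern (the drug fragments large clusters; the
cortical microfilament clefts it also causes are out of scope). The CV of
0.4, the cell and ring geometry, and the intensity levels are not printed
anywhere and were fixed once at values a microscopist would call
plausible; they are exposed in `imageSimConfig()`.

The generator emulates cluster count, size distribution, spatial regime and
counting noise. It does not emulate optical blur (no PSF convolution),
intensity variation within clusters, uneven illumination, out-of-focus
light or touching clusters — so passing recovery tests shows the
quantification pipeline is correct and well-calibrated on geometry and
noise, not that it is robust to every confocal artefact.

## Image quantification

`thresholdImage()` supports a fixed cut and Otsu's method on a 256-bin
histogram of the intensity range (invariant under increasing affine
intensity maps; a constant image is an explicit error).
`labelClusters()` performs connected-component labelling — 8-connectivity
by default, the ImageJ "Analyse Particles" convention, with 4-connectivity
available — and then applies the 0.2 µm² particle floor; border-touching
clusters are retained (no exclusion rule is part of the protocol). Areas
are always `pixel_count × pixel_size_um²`. The labelling is backed by
`igraph` components over a pixel-adjacency edge list and is validated
against an independent flood-fill oracle in the tests; Otsu is validated
against an exhaustive between-class-variance scan.

`ringScore()` operationalizes the visual "dense mito-ring" call: the mean
intensity in the annulus $[r, r+w]$ divided by the mean intensity of the
remaining cytoplasm (cell disc minus annulus minus nucleus disc), with the
ring called present at a ratio ≥ 1.5. The geometry must be supplied (or
taken from simulation ground truth); automatic nucleus detection is out of
scope. `classifyPattern()` calls a section aggregated (mean area > 3.5 µm²
and < 85 clusters), dispersed (< 3.5 µm² and > 85), or intermediate —
the thresholds are the midpoints of the printed group means and are
configurable.

## Cohort statistics and the experiment runner

`unpairedTTest()` is the two-sided pooled-variance Student test (Welch
behind a flag), the test used for cluster number/area contrasts; no
multiple-testing correction is applied, matching the original analysis.
Incidence fractions ("29/31 oocytes lost the third pulse") are reported
with binomial standard errors. `runExperiment()` chains
simulate → fit → detect → classify per trace arm and
simulate → threshold → label → classify → ring-score per image arm, from a
single validated config (YAML/JSON; unknown keys rejected), and is
bit-reproducible from its seed; every run logs package version, config
hash and seed.

## Numerical choices and degenerate inputs

* Parameter bounds: $A, b \ge 0$, $k \in [0.2, 20]$,
  $\lambda \in [10^{-3}, 10^3]$ h, $t_0 \in [0, t_{max}]$; the density
  argument is floored at $10^{-9}$ h to keep $k < 1$ evaluable at onset.
* A constant trace collapses to $A \to 0$ with $b$ at the constant level.
* Non-uniform time grids are rejected at construction, never resampled.
* Ties at the detector: runs separated by exactly the merge gap are
  merged; the smoothing window is rounded up to odd.
* Otsu on a two-valued image returns the lower value, so strictly-above
  masking retains exactly the upper class.
* The moving average shrinks its window at the trace edges rather than
  emitting NA; the edge-trim rule excludes those bins from detection
  anyway.

## Problem sizes

The validation suite runs cohorts of 100 single-oocyte seeds per treatment
for detection-rate checks, 20 images per preset for cluster-statistic
recovery, 100 random 64 × 64 masks for the labelling oracle, and ≤ 200-bin
traces for the exhaustive run-scan oracle — sizes chosen to estimate each
rate or bound comfortably while keeping a full run in tens of seconds on a
laptop.

## Known limitations

* Luminescence is a relative ATP readout; no absolute calibration, pH
  correction or luciferin-kinetics modelling is attempted.
* The baseline families (Weibull/log-normal) are descriptive, not
  mechanistic; model choice is the caller's.
* The detector's defaults are tuned to 30-s bins and multi-hour pulses;
  very short or overlapping pulses will merge.
* Image analysis is 2-D and per-section; no 3-D reconstruction,
  per-mitochondrion segmentation within clusters, or colocalization.
* Synthetic images are idealized (see above); real-data performance
  depends on threshold quality and debris, which the floor only partially
  removes.
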