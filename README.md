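# MitoPulse

Analysis of ATP dynamics and mitochondrial remodelling during mouse oocyte
maturation, for labs doing live luminescence imaging of oocytes and
quantitative confocal microscopy of mitochondrial distribution.

During spontaneous maturation (release from IBMX arrest through germinal
vesicle breakdown, spindle migration, and polar body extrusion) an oocyte
produces three distinct bursts of ATP, visible as supra-baseline pulses in
firefly-luciferase luminescence, and its mitochondria cycle between an
*aggregated* pattern (few large clusters, ~66/section at ~4.7 µm²) and a
*dispersed* one (many small clusters, ~102/section at ~2.6 µm²), with a
dense peri-nuclear "mito-ring" at high-ATP phases. MitoPulse implements
both quantification arms plus synthetic-data generators with ground truth.

## The model

**Traces.** Photon counts per 30-s bin over a 13–16 h recording are modelled
as Poisson draws around

```
m(t) = [ b + A (k/λ) ((t−t₀)/λ)^(k−1) exp(−((t−t₀)/λ)^k) Δt ] × (1 + Σⱼ pulseⱼ(t))
```

— a scaled Weibull density (luciferase expression then destruction; a
log-normal alternative is available) with total photon budget `A`, shape
`k`, scale `λ` (h), onset `t₀`, offset `b` counts/bin, and raised-cosine
pulses at ~1.5, 6 and 11.5 h. `fitBaseline()` recovers the five baseline
parameters by bounded Levenberg–Marquardt least squares;
`detectPulses()` finds maximal runs of the smoothed Poisson-scaled residual
`z = r/√max(fitted, 1)` above `τ = 2` lasting ≥ 15 min (gap-merged, edge
trimmed).

**Images.** `quantifyImage()` runs Otsu (or fixed) thresholding,
8-connected component labelling, and a 0.2 µm² particle floor (one
mitochondrion is 0.5–1 µm across, so 0.2–0.8 µm² in section — nothing
smaller is a cluster), reporting counts, areas in µm², the
aggregated/dispersed classification and a peri-nuclear ring score
(annulus/cytoplasm mean-intensity ratio, present at ≥ 1.5).

**Cohorts.** `simulateCohort()` applies treatment presets (`maturing`,
`ibmx_arrest`, `nocodazole`, `cytochalasin_b`, `enucleation`) that edit the
pulse schedule; `runExperiment()` chains simulation, fitting, detection and
image quantification into a reproducible `CohortReport` with pooled-variance
t-tests and binomial incidence fractions.

## Worked example

```r
library(MitoPulse)

tr <- simulateTrace(traceSimConfig(), seed = 1)
tr
#> LuminescenceTrace: 1680 bins of 30s (14.00 h), counts 44-2067
#>   ground-truth pulses: 3

fit <- fitBaseline(tr, model = "weibull")
fit
#> BaselineFit (weibull), 1680 bins, converged: TRUE, 8 iterations
#>   params: A=1.941e+06, k=2.199, lam=8.729, t0=0.1663, b=99.78
#>   rss: 7.49229e+06

detectPulses(fit)
#>     start_h    peak_h     end_h   peak_z excess_counts
#> 1  1.312500  1.445833  1.712500 2.723761      2852.499
#> 2  5.545833  6.104167  6.445833 4.773585     17696.993
#> 3 11.270833 11.512500 11.754167 4.665730      7121.177
```

The three detected pulses peak at 1.45, 6.10 and 11.51 h — the GVBD,
spindle-migration and MI–MII windows — and the trace is classified
`maturing-like` by `summarizeTrace()`. `excess_counts` is the integrated
supra-baseline photon count of each burst.

```r
sim <- simulateImage(imagePreset("aggregated"), seed = 1)
q <- quantifyImage(sim$image)
q$summary
#> $n_clusters
#> [1] 66
#> $mean_area_um2
#> [1] 4.86
#> $sem_area_um2
#> [1] 0.204
q$pattern
#> [1] "aggregated"
```

The quantification recovers all 66 simulated clusters with a mean area of
4.86 ± 0.20 µm², and the section is classified as the aggregated pattern.

A thin CLI over the same functions ships in `inst/cli/mitopulse`
(`simulate-trace`, `simulate-cohort`, `simulate-image`, `analyze-trace`,
`quantify-image`, `run-experiment`); an example experiment config is in
`inst/extdata/example-experiment.yaml`.

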