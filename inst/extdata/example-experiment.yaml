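# Example experiment configuration for runExperiment() / `mitopulse
# run-experiment`. Arm sizes mirror the reference cohorts; shrink n for a
# quick look.
seed: 1
model: weibull
detector:
  tau: 2.0
trace_arms:
  - preset: maturing
    n: 30
  - preset: ibmx_arrest
    n: 17
  - preset: nocodazole
    n: 31
  - preset: cytochalasin_b
    n: 36
image_arms:
  - preset: aggregated
    n: 5
  - preset: dispersed
    n: 5
  - preset: gvbd_ring
    n: 5
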