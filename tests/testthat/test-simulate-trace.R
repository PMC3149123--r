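test_that("trace dimensions, identity case and configuration validation", {
  tr <- simulateTrace(traceSimConfig(duration_h = 14, bin_s = 30), seed = 1)
  expect_equal(nBins(tr), 1680L)  # 14 * 3600 / 30
  expect_equal(binSeconds(tr), 30)

  # no pulses + no noise: counts equal the baseline mean exactly
  cfg <- traceSimConfig(pulses = defaultPulseSchedule()[0, ],
                        poisson_noise = FALSE)
  tr0 <- simulateTrace(cfg)
  expect_identical(traceCounts(tr0), traceMeta(tr0)$baseline_counts)

  expect_error(traceSimConfig(duration_h = 14, bin_s = 31),
               "whole number of bins")
  expect_error(traceSimConfig(baseline = c(A = 1, k = -1, lam = 9,
                                           t0 = 0, b = 0)),
               "out of bounds")
  expect_error(
    traceSimConfig(pulses = pulseSpec(20, 0.5, 0.1)),
    "within the trace duration")
})

test_that("identical config and seed reproduce a trace bit for bit", {
  a <- simulateTrace(traceSimConfig(), seed = 42)
  b <- simulateTrace(traceSimConfig(), seed = 42)
  expect_identical(traceCounts(a), traceCounts(b))
  expect_identical(traceTimes(a), traceTimes(b))
  c2 <- simulateTrace(traceSimConfig(), seed = 43)
  expect_false(identical(traceCounts(a), traceCounts(c2)))
})

test_that("counts obey the Poisson law at constant mean over >= 1e4 bins", {
  # flat baseline: A = 0, b = 500 counts/bin; 5-s bins give 10080 bins
  cfg <- traceSimConfig(duration_h = 14, bin_s = 5,
                        baseline = c(A = 0, k = 2, lam = 9, t0 = 0, b = 500),
                        pulses = defaultPulseSchedule()[0, ])
  tr <- simulateTrace(cfg, seed = 7)
  y <- traceCounts(tr)
  n <- length(y)
  m <- 500
  expect_gte(n, 1e4)
  se_mean <- sqrt(m / n)
  se_var <- sqrt((m + 2 * m^2) / n)
  expect_lt(abs(mean(y) - m), 3 * se_mean)
  expect_lt(abs(var(y) - m), 3 * se_var)
})

test_that("pulse-2 window counts/baseline ratio matches the schedule", {
  # Monte-Carlo oracle: over replicate seeds the mean counts/baseline ratio
  # at the pulse-2 center approaches 1 + frac_amplitude * bump
  cfg <- traceSimConfig()
  gt <- traceMeta(simulateTrace(cfg, seed = 1))
  t <- traceTimes(simulateTrace(cfg, seed = 1))
  win <- which(abs(t - 6.0) <= 0.05)  # near-peak bins, bump ~ 1
  f <- gt$baseline_counts[win]
  bump <- 0.5 * (1 + cos(pi * (t[win] - 6.0) / 1.0))
  expected <- mean(1 + 0.15 * bump)
  ratios <- unlist(lapply(1:200, function(s) {
    traceCounts(simulateTrace(cfg, seed = s))[win] / f
  }))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - expected), 3 * se)
})

test_that("treatment presets edit the ground-truth pulse schedule", {
  arrest <- simulateCohort("ibmx_arrest", 17, base_seed = 1)
  expect_length(arrest, 17L)
  expect_true(all(vapply(arrest, function(tr)
    nrow(traceMeta(tr)$pulses) == 0L, logical(1))))

  noc <- simulateCohort("nocodazole", 31, base_seed = 1)
  for (tr in noc) {
    p <- traceMeta(tr)$pulses
    expect_equal(p$center_h, c(1.5, 6.0))
  }

  enu <- simulateCohort("enucleation", 12, base_seed = 1)
  expect_true(all(vapply(enu, function(tr)
    nrow(traceMeta(tr)$pulses) == 2L, logical(1))))

  mat <- simulateCohort("maturing", 5, base_seed = 1)
  expect_true(all(vapply(mat, function(tr)
    nrow(traceMeta(tr)$pulses) == 3L, logical(1))))

  # cytochalasin B: first two pulses gone; an attenuated third pulse in
  # round(14/36 * n) of the arm, none elsewhere
  cb <- simulateCohort("cytochalasin_b", 36, base_seed = 1)
  n_pulses <- vapply(cb, function(tr) nrow(traceMeta(tr)$pulses), integer(1))
  expect_equal(sum(n_pulses == 1L), 14L)
  expect_equal(sum(n_pulses == 0L), 22L)
  with_third <- cb[[1]]
  p <- traceMeta(with_third)$pulses
  expect_equal(p$center_h, 11.5)
  expect_equal(p$frac_amplitude, 0.15 * 0.3)

  expect_error(simulateCohort("vehicle", 3), "'arg' should be one of")

  # determinism of a cohort member
  m1 <- simulateCohort("maturing", 1, base_seed = 5)[[1]]
  m2 <- simulateCohort("maturing", 1, base_seed = 5)[[1]]
  expect_identical(traceCounts(m1), traceCounts(m2))
})
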