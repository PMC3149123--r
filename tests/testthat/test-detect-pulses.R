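test_that("zero residuals yield no pulses and defaults round the window odd", {
  fitted <- rep(100, 400)
  fit <- fitFromZ(rep(0, 400), fitted)
  expect_equal(nrow(detectPulses(fit)), 0L)
  expect_equal(detectorParams(smooth_bins = 20)$smooth_bins, 21L)
})

test_that("a non-converged fit is refused unless forced", {
  fit <- fitFromZ(rep(0, 400), rep(100, 400))
  fit@converged <- FALSE
  expect_error(detectPulses(fit), "did not converge")
  expect_equal(nrow(detectPulses(fit, force = TRUE)), 0L)
})

test_that("an injected rectangular excess on an arrested trace is one pulse", {
  cfg <- traceSimConfig(pulses = defaultPulseSchedule()[0, ],
                        poisson_noise = FALSE)
  tr <- simulateTrace(cfg)
  y <- traceCounts(tr)
  t <- traceTimes(tr)
  win <- t >= 5 & t <= 6
  y[win] <- y[win] + 5 * sqrt(y[win])
  fit <- fitBaseline(LuminescenceTrace(t, y, bin_s = binSeconds(tr)))
  pulses <- detectPulses(fit)
  expect_equal(nrow(pulses), 1L)
  expect_gte(pulses$peak_h, 5)
  expect_lte(pulses$peak_h, 6)
  expect_gt(pulses$excess_counts, 0)
})

test_that("raising tau or min_dur_min never increases the pulse count", {
  for (seed in 1:5) {
    tr <- simulateTrace(traceSimConfig(), seed = seed)
    fit <- fitBaseline(tr)
    n_tau <- vapply(c(1.5, 2, 2.5, 3, 4), function(tau)
      nrow(detectPulses(fit, detectorParams(tau = tau))), integer(1))
    expect_true(all(diff(n_tau) <= 0))
    n_dur <- vapply(c(5, 15, 25, 40), function(d)
      nrow(detectPulses(fit, detectorParams(min_dur_min = d))), integer(1))
    expect_true(all(diff(n_dur) <= 0))
  }
})

test_that("run finding matches the exhaustive window-scan oracle", {
  pars <- detectorParams(tau = 1, smooth_bins = 5, min_dur_min = 5,
                         merge_gap_min = 5, edge_trim_min = 5)
  set.seed(99)
  for (rep in 1:40) {
    n <- 200L
    z <- rnorm(n, 0, 1)
    # inject a few rectangular excursions of random width/height
    for (k in seq_len(sample(0:3, 1))) {
      s <- sample(1:(n - 30), 1); w <- sample(5:30, 1)
      z[s:(s + w)] <- z[s:(s + w)] + runif(1, 1, 4)
    }
    fitted <- rep(400, n)
    fit <- fitFromZ(z, fitted)
    got <- detectPulses(fit, pars)
    t <- fit@times
    oracle <- runScanOracle(z, t, 30, pars$tau, pars$smooth_bins,
                            pars$min_dur_min, pars$merge_gap_min,
                            pars$edge_trim_min)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(got$start_h, t[oracle$start])
      expect_equal(got$end_h, t[oracle$end])
    }
  }
})

test_that("runs separated by exactly the merge gap are merged (closed rule)", {
  # two 40-bin runs separated by exactly 60 bins = 30 min at 30-s bins
  z <- rep(0, 500)
  z[101:140] <- 5
  z[201:240] <- 5
  fit <- fitFromZ(z, rep(400, 500))
  merged <- detectPulses(fit, detectorParams(smooth_bins = 1,
                                             merge_gap_min = 30))
  expect_equal(nrow(merged), 1L)
  split <- detectPulses(fit, detectorParams(smooth_bins = 1,
                                            merge_gap_min = 29.4))
  expect_equal(nrow(split), 2L)
})

test_that("maturing simulations yield three pulses at the scheduled times", {
  for (seed in 1:10) {
    tr <- simulateTrace(traceSimConfig(), seed = seed)
    pulses <- detectPulses(fitBaseline(tr))
    expect_equal(nrow(pulses), 3L)
    expect_lt(max(abs(pulses$peak_h - c(1.5, 6.0, 11.5))), 0.5)
  }
})

test_that("trace summaries classify by pulse count", {
  none <- data.frame(start_h = numeric(0), peak_h = numeric(0),
                     end_h = numeric(0), peak_z = numeric(0),
                     excess_counts = numeric(0))
  s0 <- summarizeTrace(none)
  expect_equal(s0$n_pulses, 0L)
  expect_equal(s0$classification, "arrested-like")

  three <- data.frame(start_h = c(1, 5.5, 11), peak_h = c(1.5, 6, 11.5),
                      end_h = c(2, 6.5, 12), peak_z = 3,
                      excess_counts = 100)
  s3 <- summarizeTrace(three)
  expect_equal(s3$classification, "maturing-like")
  expect_equal(s3$pulse_times, c(1.5, 6, 11.5))

  s2 <- summarizeTrace(three[1:2, ])
  expect_equal(s2$classification, "partial")
})
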