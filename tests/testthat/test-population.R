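test_that("unpaired t-test closed-form and degenerate cases", {
  r <- unpairedTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.2247449, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.2878641, tolerance = 1e-6)

  same <- unpairedTTest(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(unpairedTTest(c(5, 5), c(6, 6)), "zero variance")
  expect_error(unpairedTTest(1, c(1, 2)), "length")
})

test_that("t-test antisymmetry, p range, and Welch df bound", {
  set.seed(41)
  for (rep in 1:20) {
    a <- rnorm(8, 0, 1); b <- rnorm(12, 0.5, 2)
    r1 <- unpairedTTest(a, b); r2 <- unpairedTTest(b, a)
    expect_equal(r1$t, -r2$t)
    expect_equal(r1$p, r2$p)
    expect_gte(r1$p, 0); expect_lte(r1$p, 1)
    w <- unpairedTTest(a, b, welch = TRUE)
    expect_lte(w$df, r1$df + 1e-9)
  }
})

test_that("aggregated vs dispersed cluster areas separate at P < 0.01", {
  # Monte-Carlo over replicate pairs of n = 50 draws from the two area
  # distributions, mirroring the reported contrast
  set.seed(51)
  hits <- 0L
  for (rep in 1:100) {
    a <- MitoPulse:::rlnormMeanCv(50, 4.7, 0.4, floor = 0.2)
    b <- MitoPulse:::rlnormMeanCv(50, 2.6, 0.4, floor = 0.2)
    if (unpairedTTest(a, b)$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("cohort summaries report binomial incidence fractions", {
  df <- data.frame(treatment = "nocodazole",
                   n_pulses = c(rep(2, 29), rep(3, 2)))
  s <- summarizeCohort(df)
  # 29/31 with the third pulse ablated
  expect_equal(mean(df$n_pulses == 2), 29 / 31)
  expect_equal(s$modal_pulse_count, 2L)
  expect_equal(s$incidence_any_pulse, 1)

  arrested <- data.frame(treatment = "ibmx_arrest", n_pulses = rep(0, 17))
  s0 <- summarizeCohort(arrested)
  expect_equal(s0$incidence_any_pulse, 0)
  expect_equal(s0$modal_pulse_count, 0L)

  cb <- data.frame(treatment = "cytochalasin_b",
                   n_pulses = c(rep(0, 27), rep(1, 9)))
  expect_equal(mean(cb$n_pulses == 0), 0.75)  # 27/36 fully suppressed
  i <- incidence(27, 36)
  expect_equal(i$frac, 0.75)
  expect_equal(i$se, sqrt(0.75 * 0.25 / 36))
})

test_that("report fractions equal hand-counted fractions on small cohorts", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(2:10, 1)
    df <- data.frame(
      treatment = "x",
      n_pulses = sample(0:3, n, replace = TRUE),
      classification = sample(c("maturing-like", "partial",
                                "arrested-like"), n, replace = TRUE))
    s <- summarizeCohort(df)
    expect_equal(s$incidence_any_pulse, sum(df$n_pulses >= 1) / n)
    expect_equal(s$frac_partial,
                 sum(df$classification == "partial") / n)
    expect_equal(s$mean_pulses, mean(df$n_pulses))
  }
})

test_that("runExperiment reproduces arm-level expectations and reruns identically", {
  cfg <- list(seed = 1,
              trace_arms = list(list(preset = "maturing", n = 6),
                                list(preset = "ibmx_arrest", n = 5),
                                list(preset = "nocodazole", n = 6)))
  rep1 <- runExperiment(cfg, quiet = TRUE)
  ts <- traceSummary(rep1)
  expect_equal(ts$modal_pulse_count[ts$treatment == "maturing"], 3L)
  expect_equal(ts$incidence_any_pulse[ts$treatment == "ibmx_arrest"], 0)
  expect_equal(ts$modal_pulse_count[ts$treatment == "nocodazole"], 2L)

  rep2 <- runExperiment(cfg, quiet = TRUE)
  expect_identical(perOocyte(rep1), perOocyte(rep2))
  expect_identical(traceSummary(rep1), traceSummary(rep2))
})

test_that("runExperiment quantifies image arms and tests the area contrast", {
  cfg <- list(seed = 2,
              image_arms = list(list(preset = "aggregated", n = 3),
                                list(preset = "dispersed", n = 3)))
  rep <- runExperiment(cfg, quiet = TRUE)
  im <- imageSummary(rep)
  expect_equal(nrow(im), 2L)
  ag <- im[im$preset == "aggregated", ]
  di <- im[im$preset == "dispersed", ]
  expect_equal(ag$frac_aggregated, 1)
  expect_equal(di$frac_dispersed, 1)
  expect_equal(ag$ring_fraction, 0)
  tests <- reportTests(rep)
  expect_length(tests, 1L)
  expect_lt(tests[[1]]$p, 0.05)
})
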