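## Synthetic luminescence traces with ground truth.

#' Default ATP pulse schedule
#'
#' Three pulses timed to the maturation events they accompany: germinal
#' vesicle breakdown (~1-2 h after IBMX washout), spindle migration
#' (~5-7 h) and the MI-to-MII transition (~11-12 h).
#'
#' @return data.frame with columns `center_h`, `half_width_h`,
#'   `frac_amplitude`.
#' @examples
#' defaultPulseSchedule()
#' @export
defaultPulseSchedule <- function() {
  data.frame(
    center_h = c(1.5, 6.0, 11.5),
    half_width_h = c(0.5, 1.0, 0.5),
    frac_amplitude = c(0.15, 0.15, 0.15)
  )
}

#' Pulse specification
#'
#' @param center_h pulse center (hours into the recording).
#' @param half_width_h half-width of the raised-cosine bump (hours, > 0).
#' @param frac_amplitude peak amplitude as a fraction of the local baseline
#'   (>= 0).
#' @return one-row data.frame compatible with [defaultPulseSchedule()].
#' @export
pulseSpec <- function(center_h, half_width_h, frac_amplitude) {
  stopifnot(half_width_h > 0, frac_amplitude >= 0)
  data.frame(center_h = center_h, half_width_h = half_width_h,
             frac_amplitude = frac_amplitude)
}

#' Trace simulation configuration
#'
#' @param duration_h recording length in hours (default 14; recordings in
#'   this assay run 13-16 h).
#' @param bin_s photon-count bin width in seconds (default 30).
#' @param baseline named numeric: `A` total photons, `k` Weibull shape,
#'   `lam` Weibull scale (hours), `t0` onset (hours), `b` counts/bin offset.
#' @param pulses data.frame of pulse specs (see [pulseSpec()]); may have
#'   zero rows.
#' @param poisson_noise draw Poisson counts around the mean (default TRUE);
#'   if FALSE the trace equals the mean function exactly.
#' @param pulse_mode `"multiplicative"` (bump scales the baseline) or
#'   `"additive"` (bump adds `frac_amplitude * baseline(center)` counts).
#' @return validated configuration list of class `TraceSimConfig`.
#' @examples
#' cfg <- traceSimConfig()
#' tr <- simulateTrace(cfg, seed = 1)
#' @export
traceSimConfig <- function(duration_h = 14, bin_s = 30,
                           baseline = c(A = 2e6, k = 2.2, lam = 9,
                                        t0 = 0, b = 50),
                           pulses = defaultPulseSchedule(),
                           poisson_noise = TRUE,
                           pulse_mode = c("multiplicative", "additive")) {
  pulse_mode <- match.arg(pulse_mode)
  n_bins <- duration_h * 3600 / bin_s
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("configuration error: duration_h/(bin_s/3600) = ", n_bins,
         " is not a whole number of bins")
  need <- c("A", "k", "lam", "t0", "b")
  if (!all(need %in% names(baseline)))
    stop("baseline must name parameters A, k, lam, t0, b")
  if (baseline[["k"]] <= 0 || baseline[["lam"]] <= 0 ||
      baseline[["t0"]] < 0 || baseline[["b"]] < 0 || baseline[["A"]] < 0)
    stop("baseline parameters out of bounds (k>0, lam>0, t0>=0, b>=0, A>=0)")
  pulses <- as.data.frame(pulses)
  if (nrow(pulses)) {
    stopifnot(all(c("center_h", "half_width_h", "frac_amplitude") %in%
                    names(pulses)))
    if (any(pulses$half_width_h <= 0) || any(pulses$frac_amplitude < 0))
      stop("pulses require half_width_h > 0 and frac_amplitude >= 0")
    if (any(pulses$center_h < 0 | pulses$center_h > duration_h))
      stop("pulse centers must lie within the trace duration")
  }
  structure(list(duration_h = duration_h, bin_s = bin_s,
                 baseline = baseline, pulses = pulses,
                 poisson_noise = poisson_noise, pulse_mode = pulse_mode),
            class = "TraceSimConfig")
}

#' Raised-cosine pulse factor at times t
#' @noRd
pulseBump <- function(t, center, half_width) {
  out <- numeric(length(t))
  inside <- abs(t - center) <= half_width
  out[inside] <- 0.5 * (1 + cos(pi * (t[inside] - center) / half_width))
  out
}

#' Expected counts per bin for a configuration
#' @noRd
traceMeanFunction <- function(config) {
  n <- as.integer(round(config$duration_h * 3600 / config$bin_s))
  bin_h <- config$bin_s / 3600
  t <- (seq_len(n) - 0.5) * bin_h
  f <- baselineMean(t, config$baseline, bin_h, model = "weibull")
  m <- f
  if (nrow(config$pulses)) {
    if (config$pulse_mode == "multiplicative") {
      bump <- numeric(n)
      for (j in seq_len(nrow(config$pulses))) {
        p <- config$pulses[j, ]
        bump <- bump + p$frac_amplitude *
          pulseBump(t, p$center_h, p$half_width_h)
      }
      m <- f * (1 + bump)
    } else {
      for (j in seq_len(nrow(config$pulses))) {
        p <- config$pulses[j, ]
        amp <- p$frac_amplitude *
          baselineMean(p$center_h, config$baseline, bin_h, "weibull")
        m <- m + amp * pulseBump(t, p$center_h, p$half_width_h)
      }
    }
  }
  list(times = t, mean = m, baseline = f)
}

#' Simulate a luminescence trace
#'
#' Draws photon counts per bin from `Poisson(m(t))` where
#' `m(t) = f(t) * (1 + sum of raised-cosine bumps)` and `f(t)` is the scaled
#' Weibull expression/destruction baseline. With `poisson_noise = FALSE` the
#' counts equal `m(t)` exactly.
#'
#' @param config a [traceSimConfig()] object.
#' @param seed integer seed; identical config + seed reproduce the trace
#'   bit for bit.
#' @return [LuminescenceTrace-class] whose `meta` holds the ground truth:
#'   `pulses` (the schedule), `baseline` (parameters), `expected` (m(t))
#'   and `baseline_counts` (f(t)).
#' @examples
#' tr <- simulateTrace(traceSimConfig(), seed = 1)
#' nBins(tr)  # 14 h at 30 s bins = 1680
#' @export
simulateTrace <- function(config = traceSimConfig(), seed = NULL) {
  stopifnot(inherits(config, "TraceSimConfig"))
  if (!is.null(seed)) set.seed(seed)
  mf <- traceMeanFunction(config)
  counts <- if (config$poisson_noise) stats::rpois(length(mf$mean), mf$mean)
            else mf$mean
  LuminescenceTrace(mf$times, counts, bin_s = config$bin_s,
                    meta = list(pulses = config$pulses,
                                baseline = config$baseline,
                                expected = mf$mean,
                                baseline_counts = mf$baseline,
                                pulse_mode = config$pulse_mode,
                                seed = seed))
}

#' Treatment presets
#'
#' Which of the three default pulses each experimental arm retains:
#' untreated maturing oocytes show all three; IBMX-arrested oocytes show
#' none; nocodazole-treated and enucleated oocytes show only the first two
#' (the third requires completion of meiosis I); cytochalasin B suppresses
#' the first two and leaves a reduced third pulse in a minority of oocytes.
#'
#' @return character vector of preset names.
#' @export
treatmentPresets <- function() {
  c("maturing", "ibmx_arrest", "nocodazole", "cytochalasin_b", "enucleation")
}

#' Ground-truth pulse schedule for one oocyte under a treatment
#' @noRd
presetPulses <- function(preset, i, n, base_pulses,
                         cb_attenuation = 0.3, cb_third_fraction = 14 / 36) {
  switch(preset,
    maturing = base_pulses,
    ibmx_arrest = base_pulses[0, ],
    nocodazole = base_pulses[1:2, ],
    enucleation = base_pulses[1:2, ],
    cytochalasin_b = {
      keep_third <- i <= round(cb_third_fraction * n)
      if (keep_third) {
        p3 <- base_pulses[3, ]
        p3$frac_amplitude <- p3$frac_amplitude * cb_attenuation
        p3
      } else base_pulses[0, ]
    },
    stop("unknown treatment preset: ", preset)
  )
}

#' Simulate a treatment cohort of traces
#'
#' @param preset one of [treatmentPresets()].
#' @param n cohort size (>= 1).
#' @param base_seed integer; oocyte i uses seed `base_seed + i - 1`.
#' @param config base [traceSimConfig()]; its pulse schedule is edited per
#'   the preset.
#' @param cb_attenuation amplitude factor for the residual third pulse under
#'   cytochalasin B (default 0.3).
#' @param cb_third_fraction fraction of the cytochalasin-B arm retaining the
#'   attenuated third pulse (default 14/36); assigned to the first
#'   `round(fraction * n)` oocytes.
#' @return list of [LuminescenceTrace-class] objects with per-oocyte ground
#'   truth in `meta`.
#' @examples
#' coh <- simulateCohort("nocodazole", n = 3, base_seed = 1)
#' sapply(coh, function(tr) nrow(traceMeta(tr)$pulses))  # all 2
#' @export
simulateCohort <- function(preset, n, base_seed = 1,
                           config = traceSimConfig(),
                           cb_attenuation = 0.3,
                           cb_third_fraction = 14 / 36) {
  preset <- match.arg(preset, treatmentPresets())
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    pulses <- presetPulses(preset, i, n, config$pulses,
                           cb_attenuation, cb_third_fraction)
    cfg_i <- config
    cfg_i$pulses <- pulses
    tr <- simulateTrace(cfg_i, seed = base_seed + i - 1L)
    tr@meta$treatment <- preset
    tr@meta$oocyte <- i
    tr
  })
}
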