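## End-to-end cohort experiment runner: simulate -> analyse -> summarise.

#' Run a simulated cohort experiment
#'
#' For each trace arm, simulates the cohort under its treatment preset,
#' fits the baseline, detects pulses and classifies each oocyte; for each
#' image arm, simulates equatorial sections, quantifies clusters (Otsu
#' threshold, 0.2 um^2 floor), classifies the aggregation pattern and scores
#' the peri-nuclear ring. Everything is reproducible from `config$seed`:
#' trace arm `j` uses per-oocyte seeds `seed + 1000*j + i`, image arm `j`
#' uses `seed + 500000 + 1000*j + i`.
#'
#' @param config configuration list (see [validateRunConfig()]), e.g.
#'   `list(seed = 1, trace_arms = list(list(preset = "maturing", n = 30)))`.
#' @param quiet suppress the run log line (version, config hash, seed).
#' @return a [CohortReport-class].
#' @examples
#' rep <- runExperiment(list(seed = 1, trace_arms = list(
#'   list(preset = "ibmx_arrest", n = 2))), quiet = TRUE)
#' traceSummary(rep)$incidence_any_pulse
#' @export
runExperiment <- function(config, quiet = FALSE) {
  config <- validateRunConfig(config)
  if (!quiet)
    message(sprintf("MitoPulse %s | config %s | seed %d",
                    as.character(utils::packageVersion("MitoPulse")),
                    objectHash(config), config$seed))
  det <- do.call(detectorParams, config$detector)

  per_oocyte <- data.frame()
  for (j in seq_along(config$trace_arms)) {
    arm <- config$trace_arms[[j]]
    base_seed <- config$seed + 1000L * j
    cohort <- simulateCohort(arm$preset, arm$n, base_seed = base_seed)
    rows <- lapply(seq_along(cohort), function(i) {
      tr <- cohort[[i]]
      fit <- fitBaseline(tr, model = config$model)
      pulses <- if (isConverged(fit)) detectPulses(fit, det)
                else detectPulses(fit, det, force = TRUE)
      s <- summarizeTrace(pulses)
      data.frame(treatment = arm$preset, oocyte = i,
                 n_pulses = s$n_pulses,
                 peak_times_h = paste(sprintf("%.3f", s$pulse_times),
                                      collapse = ";"),
                 classification = s$classification,
                 converged = isConverged(fit),
                 stringsAsFactors = FALSE)
    })
    per_oocyte <- rbind(per_oocyte, do.call(rbind, rows))
  }
  trace_summary <- if (nrow(per_oocyte)) summarizeCohort(per_oocyte)
                   else data.frame()

  per_image <- data.frame()
  image_areas <- list()
  for (j in seq_along(config$image_arms)) {
    arm <- config$image_arms[[j]]
    cfg <- imagePreset(arm$preset)
    areas_j <- numeric(0)
    rows <- lapply(seq_len(arm$n), function(i) {
      sim <- simulateImage(cfg, seed = config$seed + 500000L + 1000L * j + i)
      q <- quantifyImage(sim$image)
      ring <- tryCatch(
        ringScore(sim$image, r_um = 13, width_um = 6,
                  cell_radius_um = cfg$cell_radius_um,
                  nucleus_radius_um = cfg$nucleus_radius_um %||% 12),
        error = function(e) list(score = NA_real_, present = NA))
      data.frame(preset = arm$preset, image = i,
                 n_clusters = q$summary$n_clusters,
                 mean_area_um2 = q$summary$mean_area_um2,
                 pattern = q$pattern,
                 ring_score = ring$score, ring_present = ring$present,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    per_image <- rbind(per_image, rows)
  }
  image_summary <- if (nrow(per_image)) {
    do.call(rbind, lapply(split(per_image, per_image$preset), function(d) {
      ri <- incidence(sum(d$ring_present, na.rm = TRUE),
                      max(sum(!is.na(d$ring_present)), 1))
      data.frame(preset = d$preset[1], n = nrow(d),
                 mean_n_clusters = mean(d$n_clusters),
                 mean_area_um2 = mean(d$mean_area_um2),
                 frac_aggregated = mean(d$pattern == "aggregated"),
                 frac_dispersed = mean(d$pattern == "dispersed"),
                 ring_fraction = ri$frac, ring_fraction_se = ri$se,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame()
  if (nrow(image_summary)) rownames(image_summary) <- NULL

  tests <- list()
  if (nrow(per_image) && length(unique(per_image$preset)) >= 2) {
    ps <- unique(per_image$preset)[1:2]
    a <- per_image$mean_area_um2[per_image$preset == ps[1]]
    b <- per_image$mean_area_um2[per_image$preset == ps[2]]
    if (length(a) >= 2 && length(b) >= 2)
      tests[[paste0("area_", ps[1], "_vs_", ps[2])]] <- unpairedTTest(a, b)
  }

  report <- new("CohortReport", traceSummary = trace_summary,
                imageSummary = image_summary,
                perOocyte = if (nrow(per_oocyte)) per_oocyte
                            else data.frame(),
                tests = tests, config = config)
  if (!is.null(config$out)) writeCohortReport(report, config$out)
  report
}

#' Convert a CohortReport to a plain list (for JSON serialization)
#'
#' @param report a [CohortReport-class].
#' @return a nested list.
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "CohortReport"))
  list(trace_summary = report@traceSummary,
       image_summary = report@imageSummary,
       per_oocyte = report@perOocyte,
       tests = report@tests,
       config = report@config)
}

#' Write a CohortReport as JSON plus CSV tables
#'
#' Writes `report.json`, `trace_summary.csv`, `image_summary.csv` and
#' `per_oocyte.csv` under `dir`.
#'
#' @param report a [CohortReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortReport <- function(report, dir) {
  stopifnot(is(report, "CohortReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeResults(report, file.path(dir, "report.json"))
  if (nrow(report@traceSummary))
    utils::write.csv(report@traceSummary,
                     file.path(dir, "trace_summary.csv"), row.names = FALSE)
  if (nrow(report@imageSummary))
    utils::write.csv(report@imageSummary,
                     file.path(dir, "image_summary.csv"), row.names = FALSE)
  if (nrow(report@perOocyte))
    utils::write.csv(report@perOocyte,
                     file.path(dir, "per_oocyte.csv"), row.names = FALSE)
  invisible(dir)
}
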