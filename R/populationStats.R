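## Group statistics and cohort summaries.

#' Unpaired two-sample t-test
#'
#' Two-sided Student's t-test with pooled variance by default (the
#' convention for comparing cluster counts/areas between patterns here);
#' Welch's unequal-variance form behind a flag. Degenerate zero-variance
#' inputs are resolved before delegating to [stats::t.test()]: identical
#' constant groups give `t = 0, p = 1`; constant groups with different
#' means are an error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use Welch's approximation (default FALSE = pooled).
#' @return list with `t`, `df`, `p`.
#' @examples
#' unpairedTTest(c(1, 2, 3), c(2, 3, 4))  # t = -1.225, df = 4
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero variance in both groups with unequal means: ",
         "t statistic is undefined (infinite)")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Summarize a cohort of analysed oocytes
#'
#' Input is one row per oocyte with at least `treatment` and `n_pulses`
#' columns (as produced by [runExperiment()]); optional columns
#' `classification`, `ring_present` and `pattern` are summarised when
#' present. Incidence fractions carry binomial standard errors
#' `sqrt(p(1-p)/n)`; continuous measures are reported mean +/- SEM.
#'
#' @param per_oocyte data.frame, one row per oocyte.
#' @return data.frame, one row per treatment, with `n`, `modal_pulse_count`,
#'   `mean_pulses`, `incidence_any_pulse` (+ `incidence_se`), and optional
#'   classification/ring/pattern fractions.
#' @examples
#' df <- data.frame(treatment = "noc", n_pulses = c(2, 2, 2, 0))
#' summarizeCohort(df)$incidence_any_pulse  # 0.75
#' @export
summarizeCohort <- function(per_oocyte) {
  stopifnot(nrow(per_oocyte) >= 1,
            all(c("treatment", "n_pulses") %in% names(per_oocyte)))
  arms <- split(per_oocyte, per_oocyte$treatment)
  rows <- lapply(arms, function(d) {
    n <- nrow(d)
    counts <- d$n_pulses
    tab <- table(counts)
    modal <- as.integer(names(tab)[which.max(tab)])
    inc <- incidence(sum(counts >= 1), n)
    row <- data.frame(
      treatment = d$treatment[1], n = n,
      modal_pulse_count = modal,
      mean_pulses = mean(counts),
      sem_pulses = if (n >= 2) stats::sd(counts) / sqrt(n) else NA_real_,
      incidence_any_pulse = inc$frac,
      incidence_se = inc$se
    )
    if ("classification" %in% names(d)) {
      row$frac_maturing_like <- mean(d$classification == "maturing-like")
      row$frac_partial <- mean(d$classification == "partial")
      row$frac_arrested_like <- mean(d$classification == "arrested-like")
    }
    if ("ring_present" %in% names(d) && !all(is.na(d$ring_present))) {
      ri <- incidence(sum(d$ring_present, na.rm = TRUE),
                      sum(!is.na(d$ring_present)))
      row$ring_fraction <- ri$frac
      row$ring_fraction_se <- ri$se
    }
    if ("pattern" %in% names(d)) {
      row$frac_aggregated <- mean(d$pattern == "aggregated")
      row$frac_dispersed <- mean(d$pattern == "dispersed")
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
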