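## Residual-based pulse detection.

#' Detector parameters
#'
#' @param tau threshold on the smoothed, Poisson-normalized residual
#'   (default 2.0).
#' @param smooth_bins moving-average window in bins (default 20; rounded up
#'   to the next odd number, i.e. 21 bins = 10.5 min at 30-s bins).
#' @param min_dur_min minimum run duration in minutes (default 15).
#' @param merge_gap_min runs separated by at most this many minutes are
#'   merged, closed interval (default 30).
#' @param edge_trim_min bins within this many minutes of either end of the
#'   recording are ignored (default 30).
#' @return validated parameter list of class `DetectorParams`.
#' @export
detectorParams <- function(tau = 2.0, smooth_bins = 20L, min_dur_min = 15,
                           merge_gap_min = 30, edge_trim_min = 30) {
  stopifnot(tau > 0, smooth_bins > 0, min_dur_min > 0, merge_gap_min > 0,
            edge_trim_min > 0)
  w <- as.integer(round(smooth_bins))
  if (w %% 2L == 0L) w <- w + 1L
  structure(list(tau = tau, smooth_bins = w, min_dur_min = min_dur_min,
                 merge_gap_min = merge_gap_min,
                 edge_trim_min = edge_trim_min),
            class = "DetectorParams")
}

#' Detect supra-baseline ATP pulses in baseline-fit residuals
#'
#' Normalizes residuals on the Poisson scale,
#' `z_i = residual_i / sqrt(max(fitted_i, 1))` (counts are heteroscedastic:
#' they span orders of magnitude along the expression curve), smooths `z`
#' with a centered moving average, and reports maximal runs of smoothed
#' `z > tau` that last at least `min_dur_min`, merging runs separated by at
#' most `merge_gap_min` and ignoring the first and last `edge_trim_min` of
#' the recording.
#'
#' @param fit a converged [BaselineFit-class].
#' @param params a [detectorParams()] list.
#' @param force analyse a non-converged fit anyway (default FALSE; a
#'   non-converged baseline makes the residuals meaningless, so the default
#'   is to refuse).
#' @return data.frame of pulses ordered by start time, with columns
#'   `start_h`, `peak_h`, `end_h`, `peak_z` (max smoothed z) and
#'   `excess_counts` (integrated raw residual over the run).
#' @examples
#' tr <- simulateTrace(traceSimConfig(), seed = 1)
#' detectPulses(fitBaseline(tr))
#' @export
detectPulses <- function(fit, params = detectorParams(), force = FALSE) {
  stopifnot(is(fit, "BaselineFit"), inherits(params, "DetectorParams"))
  if (!isConverged(fit) && !force)
    stop("baseline fit did not converge; refusing pulse detection ",
         "(use force = TRUE to override)")
  t <- fit@times
  bin_s <- fit@binSeconds
  z <- fit@residuals / sqrt(pmax(fit@fitted, 1))
  zs <- movingAverage(z, params$smooth_bins)
  above <- zs > params$tau
  trim_h <- params$edge_trim_min / 60
  above[t < t[1] + trim_h | t > t[length(t)] + 1e-12 - trim_h] <- FALSE

  runs <- findRuns(above, bin_s, params$min_dur_min, params$merge_gap_min)
  if (!nrow(runs))
    return(data.frame(start_h = numeric(0), peak_h = numeric(0),
                      end_h = numeric(0), peak_z = numeric(0),
                      excess_counts = numeric(0)))
  pulses <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    pk <- s - 1L + which.max(zs[s:e])
    data.frame(start_h = t[s], peak_h = t[pk], end_h = t[e],
               peak_z = zs[pk],
               excess_counts = sum(fit@residuals[s:e]))
  }))
  pulses <- pulses[pulses$excess_counts > 0, , drop = FALSE]
  pulses <- pulses[order(pulses$start_h), , drop = FALSE]
  rownames(pulses) <- NULL
  pulses
}

#' Maximal TRUE runs, duration-filtered then gap-merged
#' @noRd
findRuns <- function(above, bin_s, min_dur_min, merge_gap_min) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * bin_s / 60 >= min_dur_min)
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(data.frame(start = integer(0),
                                         end = integer(0)))
  # merge runs whose gap (in minutes) is <= merge_gap_min, closed interval
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      gap_min <- (starts[i] - me - 1L) * bin_s / 60
      if (gap_min <= merge_gap_min) {
        me <- ends[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start = out_s, end = out_e)
}

#' Summarize the pulses of one trace
#'
#' Classification rule: three or more pulses is "maturing-like" (full
#' maturation shows pulses at GVBD, spindle migration and the MI-MII
#' transition), one or two is "partial" (e.g. nocodazole arms lose the third
#' pulse), none is "arrested-like".
#'
#' @param pulses data.frame from [detectPulses()].
#' @return list with `n_pulses`, `pulse_times` (peak hours) and
#'   `classification`.
#' @examples
#' summarizeTrace(data.frame(start_h = 1, peak_h = 1.5, end_h = 2,
#'                           peak_z = 3, excess_counts = 100))$classification
#' @export
summarizeTrace <- function(pulses) {
  n <- nrow(pulses)
  list(
    n_pulses = n,
    pulse_times = pulses$peak_h,
    classification = if (n >= 3) "maturing-like"
                     else if (n >= 1) "partial"
                     else "arrested-like"
  )
}
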