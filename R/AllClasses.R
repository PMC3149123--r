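#' @import methods
NULL

## Central data containers. All times are hours, all areas are um^2,
## image coordinates have the origin at the top-left corner with x running
## rightward (columns) and y downward (rows).

#' LuminescenceTrace: a time-binned photon-count recording
#'
#' Container for a single-oocyte luciferase luminescence recording:
#' photon counts per acquisition bin on a uniform time grid.
#'
#' @slot times numeric, bin-center times in hours, strictly increasing and
#'   uniformly spaced at `binSeconds/3600`.
#' @slot counts numeric, photons per bin (non-negative; integer for real
#'   recordings, possibly fractional for noiseless model traces).
#' @slot binSeconds numeric(1), bin width in seconds.
#' @slot meta list, free-form metadata (simulation ground truth, treatment,
#'   source file, ...).
#'
#' @seealso [simulateTrace()], [fitBaseline()], [readTraceCsv()]
#' @exportClass LuminescenceTrace
setClass("LuminescenceTrace",
  representation(
    times = "numeric",
    counts = "numeric",
    binSeconds = "numeric",
    meta = "list"
  )
)

setValidity("LuminescenceTrace", function(object) {
  msg <- character()
  if (length(object@binSeconds) != 1L || !is.finite(object@binSeconds) ||
      object@binSeconds <= 0)
    msg <- c(msg, "binSeconds must be a single positive number")
  if (length(object@times) != length(object@counts))
    msg <- c(msg, "times and counts must have equal length")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (length(object@times) >= 2L) {
    d <- diff(object@times)
    bin_h <- object@binSeconds / 3600
    if (any(d <= 0))
      msg <- c(msg, "times must be strictly increasing")
    else if (max(abs(d - bin_h)) > 1e-6 * bin_h)
      msg <- c(msg, "times must be uniformly spaced at binSeconds")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LuminescenceTrace
#'
#' @param times bin-center times in hours (uniform grid).
#' @param counts photon counts per bin.
#' @param bin_s bin width in seconds (default 30).
#' @param meta optional metadata list.
#' @return A [LuminescenceTrace-class] object.
#' @examples
#' tr <- LuminescenceTrace(times = (1:10 - 0.5) / 120, counts = rep(5, 10))
#' nBins(tr)
#' @export
LuminescenceTrace <- function(times, counts, bin_s = 30, meta = list()) {
  new("LuminescenceTrace", times = as.numeric(times),
      counts = as.numeric(counts), binSeconds = as.numeric(bin_s),
      meta = meta)
}

#' BaselineFit: a fitted expression/decay baseline
#'
#' Result of fitting the smooth luciferase expression-and-destruction curve
#' (scaled Weibull or log-normal density plus offset) to a trace by
#' nonlinear least squares. Carries the data it was fitted to so that pulse
#' detection is self-contained.
#'
#' @slot model character(1), `"weibull"` or `"lognormal"`.
#' @slot params named numeric: `A` (total photons), `k`/`lam` (Weibull shape
#'   and scale, hours) or `mu`/`sigma` (log-normal log-scale parameters),
#'   `t0` (onset, hours), `b` (counts/bin offset).
#' @slot times,counts the fitted trace (hours; counts/bin).
#' @slot fitted per-bin fitted baseline values.
#' @slot residuals `counts - fitted`.
#' @slot rss residual sum of squares.
#' @slot converged logical(1), solver convergence status.
#' @slot nIter integer(1), solver iterations used.
#' @slot binSeconds numeric(1), bin width in seconds.
#'
#' @seealso [fitBaseline()], [detectPulses()]
#' @exportClass BaselineFit
setClass("BaselineFit",
  representation(
    model = "character",
    params = "numeric",
    times = "numeric",
    counts = "numeric",
    fitted = "numeric",
    residuals = "numeric",
    rss = "numeric",
    converged = "logical",
    nIter = "integer",
    binSeconds = "numeric"
  )
)

setValidity("BaselineFit", function(object) {
  msg <- character()
  n <- length(object@counts)
  if (length(object@fitted) != n || length(object@residuals) != n ||
      length(object@times) != n)
    msg <- c(msg, "times, counts, fitted and residuals must share a length")
  if (!object@model %in% c("weibull", "lognormal"))
    msg <- c(msg, "model must be 'weibull' or 'lognormal'")
  if (n > 0) {
    rss <- sum(object@residuals^2)
    if (abs(object@rss - rss) > 1e-6 * max(rss, 1))
      msg <- c(msg, "rss inconsistent with residuals")
    if (max(abs(object@counts - object@fitted - object@residuals)) >
        1e-6 * max(abs(object@counts), 1))
      msg <- c(msg, "residuals must equal counts - fitted")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BaselineFit
#'
#' Normally produced by [fitBaseline()]; the constructor is exported so that
#' synthetic fits can be assembled directly (e.g. to feed [detectPulses()]
#' with hand-crafted residuals).
#'
#' @param model `"weibull"` or `"lognormal"`.
#' @param params named numeric parameter vector.
#' @param times,counts,fitted numeric vectors of equal length.
#' @param bin_s bin width in seconds.
#' @param converged logical convergence flag.
#' @param nIter iterations used.
#' @return A [BaselineFit-class] object; residuals and rss are derived.
#' @export
BaselineFit <- function(model, params, times, counts, fitted, bin_s = 30,
                        converged = TRUE, nIter = 0L) {
  res <- counts - fitted
  new("BaselineFit", model = model, params = params,
      times = as.numeric(times), counts = as.numeric(counts),
      fitted = as.numeric(fitted), residuals = as.numeric(res),
      rss = sum(res^2), converged = converged, nIter = as.integer(nIter),
      binSeconds = as.numeric(bin_s))
}

#' MitoImage: a single-channel intensity raster with physical pixel size
#'
#' @slot pixels numeric matrix of non-negative intensities; rows are y
#'   (downward), columns are x (rightward).
#' @slot pixelSizeUm numeric(1), micrometres per pixel edge.
#' @slot meta list, free-form metadata (preset, seed, sidecar contents, ...).
#'
#' @seealso [simulateImage()], [thresholdImage()], [readMitoImage()]
#' @exportClass MitoImage
setClass("MitoImage",
  representation(
    pixels = "matrix",
    pixelSizeUm = "numeric",
    meta = "list"
  )
)

setValidity("MitoImage", function(object) {
  msg <- character()
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (!is.numeric(object@pixels))
    msg <- c(msg, "pixels must be a numeric matrix")
  else if (any(!is.finite(object@pixels)) || any(object@pixels < 0))
    msg <- c(msg, "pixel intensities must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a MitoImage
#'
#' @param pixels numeric intensity matrix (rows = y, columns = x).
#' @param pixel_size_um micrometres per pixel.
#' @param meta optional metadata list.
#' @return A [MitoImage-class] object.
#' @export
MitoImage <- function(pixels, pixel_size_um, meta = list()) {
  storage.mode(pixels) <- "double"
  new("MitoImage", pixels = pixels, pixelSizeUm = as.numeric(pixel_size_um),
      meta = meta)
}

#' ClusterSet: labelled mitochondrial clusters and their measurements
#'
#' Result of connected-component labelling of a thresholded image with the
#' single-mitochondrion area floor applied.
#'
#' @slot labels integer matrix, 0 = background, 1..n = retained clusters
#'   (numbered in raster order of their first pixel).
#' @slot clusters data.frame with columns `id`, `pixel_count`, `area_um2`,
#'   `centroid_x`, `centroid_y` (pixel coordinates).
#' @slot pixelSizeUm numeric(1), micrometres per pixel.
#' @slot minAreaUm2 numeric(1), the particle floor applied (um^2).
#' @slot droppedPixels integer(1), foreground pixels removed by the floor.
#' @slot droppedClusters integer(1), components removed by the floor.
#'
#' @seealso [labelClusters()], [classifyPattern()]
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(
    labels = "matrix",
    clusters = "data.frame",
    pixelSizeUm = "numeric",
    minAreaUm2 = "numeric",
    droppedPixels = "integer",
    droppedClusters = "integer"
  )
)

setValidity("ClusterSet", function(object) {
  msg <- character()
  cl <- object@clusters
  need <- c("id", "pixel_count", "area_um2", "centroid_x", "centroid_y")
  if (!all(need %in% names(cl)))
    msg <- c(msg, "clusters must have columns id, pixel_count, area_um2, centroid_x, centroid_y")
  else if (nrow(cl)) {
    if (max(abs(cl$area_um2 - cl$pixel_count * object@pixelSizeUm^2)) >
        1e-9 * max(cl$area_um2))
      msg <- c(msg, "area_um2 must equal pixel_count * pixelSizeUm^2")
    if (!isTRUE(all.equal(sort(unique(as.vector(object@labels))),
                          sort(c(0L, cl$id)))) &&
        !isTRUE(all.equal(sort(unique(as.vector(object@labels))),
                          sort(cl$id))))
      msg <- c(msg, "label raster must contain exactly the cluster ids (plus background)")
  }
  if (length(msg)) msg else TRUE
})

#' CohortReport: per-treatment summaries of a simulated or measured cohort
#'
#' @slot traceSummary data.frame, one row per treatment arm (pulse incidence,
#'   modal pulse count, classification fractions, mean peak times).
#' @slot imageSummary data.frame, one row per image arm (cluster counts,
#'   mean areas, pattern fractions, ring fraction); zero rows if no image
#'   arms were run.
#' @slot perOocyte data.frame, one row per analysed oocyte/image.
#' @slot tests list of hypothesis-test results.
#' @slot config list, the configuration the report was produced from.
#'
#' @seealso [runExperiment()], [summarizeCohort()]
#' @exportClass CohortReport
setClass("CohortReport",
  representation(
    traceSummary = "data.frame",
    imageSummary = "data.frame",
    perOocyte = "data.frame",
    tests = "list",
    config = "list"
  )
)

setValidity("CohortReport", function(object) {
  ts <- object@traceSummary
  fracCols <- intersect(
    c("incidence_any_pulse", "frac_maturing_like", "frac_partial",
      "frac_arrested_like"), names(ts))
  for (cc in fracCols) {
    v <- ts[[cc]]
    if (any(is.finite(v) & (v < 0 | v > 1)))
      return(sprintf("column %s must lie in [0, 1]", cc))
  }
  TRUE
})
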