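## Accessor generics and show methods.

#' @rdname LuminescenceTrace-class
#' @param object,x a \code{LuminescenceTrace}.
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname LuminescenceTrace-class
#' @export
setGeneric("traceCounts", function(x) standardGeneric("traceCounts"))

#' @rdname LuminescenceTrace-class
#' @export
setGeneric("binSeconds", function(x) standardGeneric("binSeconds"))

#' @rdname LuminescenceTrace-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname LuminescenceTrace-class
#' @export
setGeneric("traceMeta", function(x) standardGeneric("traceMeta"))

#' @rdname LuminescenceTrace-class
setMethod("traceTimes", "LuminescenceTrace", function(x) x@times)

#' @rdname LuminescenceTrace-class
setMethod("traceCounts", "LuminescenceTrace", function(x) x@counts)

#' @rdname LuminescenceTrace-class
setMethod("binSeconds", "LuminescenceTrace", function(x) x@binSeconds)

#' @rdname LuminescenceTrace-class
setMethod("nBins", "LuminescenceTrace", function(x) length(x@counts))

#' @rdname LuminescenceTrace-class
setMethod("traceMeta", "LuminescenceTrace", function(x) x@meta)

setMethod("show", "LuminescenceTrace", function(object) {
  n <- length(object@counts)
  cat(sprintf(
    "LuminescenceTrace: %d bins of %gs (%.2f h), counts %g-%g\n",
    n, object@binSeconds, n * object@binSeconds / 3600,
    if (n) min(object@counts) else NA, if (n) max(object@counts) else NA))
  if (!is.null(object@meta$treatment))
    cat("  treatment:", object@meta$treatment, "\n")
  if (!is.null(object@meta$pulses))
    cat("  ground-truth pulses:", nrow(object@meta$pulses), "\n")
})

#' @rdname BaselineFit-class
#' @param x,object a \code{BaselineFit}.
#' @export
setGeneric("baselineModel", function(x) standardGeneric("baselineModel"))

#' @rdname BaselineFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname BaselineFit-class
setMethod("baselineModel", "BaselineFit", function(x) x@model)

#' @rdname BaselineFit-class
setMethod("isConverged", "BaselineFit", function(x) x@converged)

#' @rdname BaselineFit-class
setMethod("traceTimes", "BaselineFit", function(x) x@times)

#' @rdname BaselineFit-class
setMethod("traceCounts", "BaselineFit", function(x) x@counts)

#' @rdname BaselineFit-class
setMethod("binSeconds", "BaselineFit", function(x) x@binSeconds)

#' @rdname BaselineFit-class
#' @importFrom stats coef
#' @export
setMethod("coef", "BaselineFit", function(object, ...) object@params)

#' @rdname BaselineFit-class
#' @importFrom stats fitted
#' @export
setMethod("fitted", "BaselineFit", function(object, ...) object@fitted)

#' @rdname BaselineFit-class
#' @importFrom stats residuals
#' @export
setMethod("residuals", "BaselineFit", function(object, ...) object@residuals)

setMethod("show", "BaselineFit", function(object) {
  cat(sprintf("BaselineFit (%s), %d bins, converged: %s, %d iterations\n",
              object@model, length(object@counts), object@converged,
              object@nIter))
  cat("  params:", paste(sprintf("%s=%.4g", names(object@params),
                                 object@params), collapse = ", "), "\n")
  cat(sprintf("  rss: %.6g\n", object@rss))
})

#' @rdname MitoImage-class
#' @param x,object a \code{MitoImage}.
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname MitoImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname MitoImage-class
setMethod("imagePixels", "MitoImage", function(x) x@pixels)

#' @rdname MitoImage-class
setMethod("pixelSize", "MitoImage", function(x) x@pixelSizeUm)

#' @rdname MitoImage-class
setMethod("dim", "MitoImage", function(x) dim(x@pixels))

setMethod("show", "MitoImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "MitoImage: %d x %d px at %g um/px (%.1f x %.1f um), intensity %g-%g\n",
    d[1], d[2], object@pixelSizeUm, d[2] * object@pixelSizeUm,
    d[1] * object@pixelSizeUm, min(object@pixels), max(object@pixels)))
})

#' @rdname ClusterSet-class
#' @param x,object a \code{ClusterSet}.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterSummary", function(x) standardGeneric("clusterSummary"))

#' @rdname ClusterSet-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusterSet-class
setMethod("labelMatrix", "ClusterSet", function(x) x@labels)

#' @rdname ClusterSet-class
setMethod("clusterTable", "ClusterSet", function(x) x@clusters)

#' @rdname ClusterSet-class
setMethod("nClusters", "ClusterSet", function(x) nrow(x@clusters))

#' @rdname ClusterSet-class
setMethod("clusterSummary", "ClusterSet", function(x) {
  a <- x@clusters$area_um2
  n <- length(a)
  list(
    n_clusters = n,
    mean_area_um2 = if (n) mean(a) else NA_real_,
    sem_area_um2 = if (n >= 2) stats::sd(a) / sqrt(n) else NA_real_
  )
})

#' @rdname ClusterSet-class
setMethod("pixelSize", "ClusterSet", function(x) x@pixelSizeUm)

setMethod("show", "ClusterSet", function(object) {
  s <- clusterSummary(object)
  cat(sprintf(
    "ClusterSet: %d clusters >= %g um2 (mean %.3g +/- %.2g um2); %d components (%d px) below floor\n",
    s$n_clusters, object@minAreaUm2,
    s$mean_area_um2, s$sem_area_um2,
    object@droppedClusters, object@droppedPixels))
})

setMethod("show", "CohortReport", function(object) {
  cat("CohortReport\n")
  if (nrow(object@traceSummary)) {
    cat(sprintf("  trace arms (%d):\n", nrow(object@traceSummary)))
    print(object@traceSummary, row.names = FALSE)
  }
  if (nrow(object@imageSummary)) {
    cat(sprintf("  image arms (%d):\n", nrow(object@imageSummary)))
    print(object@imageSummary, row.names = FALSE)
  }
  if (length(object@tests))
    cat("  tests:", paste(names(object@tests), collapse = ", "), "\n")
})

#' @rdname CohortReport-class
#' @param x,object a \code{CohortReport}.
#' @export
setGeneric("traceSummary", function(x) standardGeneric("traceSummary"))

#' @rdname CohortReport-class
#' @export
setGeneric("imageSummary", function(x) standardGeneric("imageSummary"))

#' @rdname CohortReport-class
#' @export
setGeneric("perOocyte", function(x) standardGeneric("perOocyte"))

#' @rdname CohortReport-class
#' @export
setGeneric("reportTests", function(x) standardGeneric("reportTests"))

#' @rdname CohortReport-class
setMethod("traceSummary", "CohortReport", function(x) x@traceSummary)

#' @rdname CohortReport-class
setMethod("imageSummary", "CohortReport", function(x) x@imageSummary)

#' @rdname CohortReport-class
setMethod("perOocyte", "CohortReport", function(x) x@perOocyte)

#' @rdname CohortReport-class
setMethod("reportTests", "CohortReport", function(x) x@tests)
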