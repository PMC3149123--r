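## Threshold -> label -> measure pipeline for equatorial-section images.

#' Otsu threshold of an intensity raster
#'
#' Builds a 256-bin histogram over the intensity range and returns the bin
#' edge maximizing the between-class variance. Invariant under increasing
#' affine intensity transforms.
#'
#' @param x numeric matrix or vector of intensities.
#' @param levels number of histogram bins (default 256).
#' @return the threshold value; pixels strictly above it are foreground.
#' @examples
#' otsuThreshold(c(rep(0, 50), rep(100, 50)))
#' @export
otsuThreshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  r <- range(x)
  if (r[1] == r[2])
    stop("constant image: Otsu thresholding has no separable classes")
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  # bin pixels; clamp the max value into the last bin
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              levels)
  h <- tabulate(bin, nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_tot <- mu[levels]
  w1 <- 1 - w0
  # between-class variance at a cut after bin i
  sb <- (mu_tot * w0 - mu)^2 / (w0 * w1)
  sb[!is.finite(sb)] <- -Inf
  i <- which.max(sb[-levels])  # cutting after the last bin is no cut
  breaks[i + 1L]
}

#' Threshold an image to a foreground mask
#'
#' @param img a [MitoImage-class] or a numeric matrix.
#' @param method `"otsu"` (256-bin between-class-variance maximization) or
#'   `"fixed"`.
#' @param value threshold for `method = "fixed"`.
#' @return logical matrix, TRUE where intensity is strictly above the
#'   threshold; the threshold used is attached as attribute `"threshold"`.
#' @examples
#' m <- matrix(c(40, 40, 60, 60), 2)
#' thresholdImage(m, "fixed", value = 50)
#' @export
thresholdImage <- function(img, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  px <- if (is(img, "MitoImage")) imagePixels(img) else img
  stopifnot(is.matrix(px), length(px) > 0)
  thr <- switch(method,
    otsu = otsuThreshold(px),
    fixed = {
      if (is.null(value)) stop("method = 'fixed' requires a threshold value")
      value
    })
  mask <- px > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Pixel-adjacency edges of a foreground mask
#' @noRd
maskEdges <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  M <- matrix(seq_len(nr * nc), nr, nc)
  from <- integer(0); to <- integer(0)
  if (nc > 1) {  # horizontal
    A <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
    from <- c(from, M[, -nc, drop = FALSE][A])
    to <- c(to, M[, -1, drop = FALSE][A])
  }
  if (nr > 1) {  # vertical
    A <- mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE]
    from <- c(from, M[-nr, , drop = FALSE][A])
    to <- c(to, M[-1, , drop = FALSE][A])
  }
  if (connectivity == 8L && nr > 1 && nc > 1) {
    A <- mask[-nr, -nc, drop = FALSE] & mask[-1, -1, drop = FALSE]
    from <- c(from, M[-nr, -nc, drop = FALSE][A])
    to <- c(to, M[-1, -1, drop = FALSE][A])
    A <- mask[-nr, -1, drop = FALSE] & mask[-1, -nc, drop = FALSE]
    from <- c(from, M[-nr, -1, drop = FALSE][A])
    to <- c(to, M[-1, -nc, drop = FALSE][A])
  }
  cbind(from, to)
}

#' Label connected clusters and measure their areas
#'
#' Connected-component labelling of a foreground mask (8-connectivity by
#' default, the ImageJ "Analyse Particles" convention) followed by the
#' physical-unit particle floor: components smaller than `min_area_um2`
#' cannot be a single mitochondrion (~0.5-1 um diameter, i.e. 0.2-0.8 um^2
#' in section) and are discarded as noise. Border-touching clusters are
#' retained.
#'
#' @param mask logical matrix from [thresholdImage()].
#' @param pixel_size_um micrometres per pixel.
#' @param connectivity 8 (default) or 4.
#' @param min_area_um2 particle floor in um^2 (default 0.2); applied after
#'   labelling.
#' @return a [ClusterSet-class]; retained clusters are renumbered 1..n in
#'   raster order of their first pixel.
#' @examples
#' mask <- matrix(FALSE, 12, 12); mask[2:11, 2:11] <- TRUE
#' clusterSummary(labelClusters(mask, 0.1))  # one 1.0-um2 cluster
#' @export
labelClusters <- function(mask, pixel_size_um, connectivity = 8L,
                          min_area_um2 = 0.2) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size_um > 0,
            connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  empty <- data.frame(id = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0))
  if (!length(fg))
    return(new("ClusterSet", labels = matrix(0L, nr, nc), clusters = empty,
               pixelSizeUm = pixel_size_um, minAreaUm2 = min_area_um2,
               droppedPixels = 0L, droppedClusters = 0L))

  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  e <- maskEdges(mask, as.integer(connectivity))
  g <- igraph::make_graph(edges = as.vector(t(cbind(vid[e[, 1]],
                                                    vid[e[, 2]]))),
                          n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership

  px_per_comp <- tabulate(comp)
  area <- px_per_comp * pixel_size_um^2
  keep <- area >= min_area_um2
  dropped_px <- sum(px_per_comp[!keep])
  dropped_n <- sum(!keep)

  # renumber retained components in raster (column-major) order of first pixel
  first_px <- rep(NA_integer_, length(px_per_comp))
  first_seen <- !duplicated(comp)
  first_px[comp[first_seen]] <- fg[first_seen]
  kept_ids <- which(keep)[order(first_px[keep])]
  newid <- integer(length(px_per_comp))
  newid[kept_ids] <- seq_along(kept_ids)

  lab <- matrix(0L, nr, nc)
  lab[fg] <- newid[comp]

  if (!length(kept_ids)) {
    clusters <- empty
  } else {
    labv <- newid[comp]
    sel <- labv > 0L
    rows <- ((fg - 1L) %% nr) + 1L
    cols <- ((fg - 1L) %/% nr) + 1L
    cnt <- tabulate(labv[sel], nbins = length(kept_ids))
    cx <- rowsum(as.numeric(cols[sel]), labv[sel])[, 1] / cnt
    cy <- rowsum(as.numeric(rows[sel]), labv[sel])[, 1] / cnt
    clusters <- data.frame(id = seq_along(kept_ids), pixel_count = cnt,
                           area_um2 = cnt * pixel_size_um^2,
                           centroid_x = as.numeric(cx),
                           centroid_y = as.numeric(cy))
  }
  new("ClusterSet", labels = lab, clusters = clusters,
      pixelSizeUm = pixel_size_um, minAreaUm2 = min_area_um2,
      droppedPixels = as.integer(dropped_px),
      droppedClusters = as.integer(dropped_n))
}

#' Score a peri-nuclear mitochondrial ring
#'
#' The score is the mean intensity inside the annulus `[r, r+width]` divided
#' by the mean intensity of the remaining cytoplasm (cell mask minus annulus
#' minus the nucleus disc). A dense mito-ring around the GV/spindle region
#' concentrates dye in the annulus, pushing the ratio above 1.
#'
#' @param img a [MitoImage-class] or numeric matrix.
#' @param center_px ring center `c(x, y)` in pixels (default: image center).
#' @param r_um inner ring radius (um).
#' @param width_um ring width (um).
#' @param cell_mask logical matrix delimiting the cell, or NULL to build a
#'   disc of `cell_radius_um` around `center_px`.
#' @param cell_radius_um cell radius used when `cell_mask` is NULL.
#' @param nucleus_radius_um nucleus-disc radius excluded from the cytoplasm
#'   reference (default: the inner ring radius `r_um`).
#' @param theta ring-presence threshold on the score (default 1.5).
#' @param pixel_size_um pixel size, required when `img` is a bare matrix.
#' @return list with `score`, `present` (`score >= theta`) and `theta`.
#' @examples
#' img <- MitoImage(matrix(100, 200, 200), 0.1)
#' ringScore(img, r_um = 4, width_um = 2, cell_radius_um = 9)$score  # 1
#' @export
ringScore <- function(img, center_px = NULL, r_um, width_um,
                      cell_mask = NULL, cell_radius_um = NULL,
                      nucleus_radius_um = NULL, theta = 1.5,
                      pixel_size_um = NULL) {
  if (is(img, "MitoImage")) {
    px <- imagePixels(img)
    psz <- pixelSize(img)
  } else {
    px <- img
    if (is.null(pixel_size_um))
      stop("pixel_size_um is required when img is a plain matrix")
    psz <- pixel_size_um
  }
  d <- dim(px)
  if (is.null(center_px)) center_px <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  dist <- distanceUm(d, center_px, psz)
  if (is.null(cell_mask)) {
    if (is.null(cell_radius_um))
      stop("supply either cell_mask or cell_radius_um")
    cell_mask <- dist <= cell_radius_um
  }
  stopifnot(identical(dim(cell_mask), d))
  annulus <- dist >= r_um & dist <= r_um + width_um
  if (!any(annulus)) stop("empty annulus")
  if (any(annulus & !cell_mask))
    stop("annulus extends outside the cell mask")
  nuc_r <- nucleus_radius_um %||% r_um
  cyto <- cell_mask & !annulus & dist >= nuc_r
  if (!any(cyto)) stop("empty cytoplasm reference region")
  score <- mean(px[annulus]) / mean(px[cyto])
  list(score = score, present = score >= theta, theta = theta)
}

#' Classify the mitochondrial aggregation pattern
#'
#' Aggregated sections show few large clusters (~66/section, ~4.7 um^2);
#' dispersed sections show many small ones (~102/section, ~2.6 um^2). The
#' default thresholds are the midpoints of those group means; anything not
#' clearly on one side of both is "intermediate".
#'
#' @param x a [ClusterSet-class], a [clusterSummary()]-style list, or the
#'   mean cluster area (um^2) with `n_clusters` given separately.
#' @param n_clusters cluster count when `x` is the mean area.
#' @param area_threshold_um2 area cut (default 3.5).
#' @param count_threshold count cut (default 85).
#' @return `"aggregated"`, `"dispersed"` or `"intermediate"`.
#' @examples
#' classifyPattern(4.7, 66)   # aggregated
#' classifyPattern(2.6, 102)  # dispersed
#' @export
classifyPattern <- function(x, n_clusters = NULL, area_threshold_um2 = 3.5,
                            count_threshold = 85) {
  if (is(x, "ClusterSet")) {
    s <- clusterSummary(x)
    mean_area <- s$mean_area_um2
    n_clusters <- s$n_clusters
  } else if (is.list(x)) {
    mean_area <- x$mean_area_um2
    n_clusters <- x$n_clusters
  } else {
    mean_area <- x
    if (is.null(n_clusters)) stop("n_clusters is required")
  }
  if (is.na(mean_area) || is.na(n_clusters)) return("intermediate")
  if (mean_area > area_threshold_um2 && n_clusters < count_threshold)
    "aggregated"
  else if (mean_area < area_threshold_um2 && n_clusters > count_threshold)
    "dispersed"
  else "intermediate"
}

#' One-call image quantification
#'
#' Threshold, label, measure and classify a single image.
#'
#' @param img a [MitoImage-class].
#' @param method threshold method, `"otsu"` or `"fixed"`.
#' @param value fixed threshold value.
#' @param connectivity 8 (default) or 4.
#' @param min_area_um2 particle floor (default 0.2).
#' @return list with `clusters` ([ClusterSet-class]), `summary`
#'   (n/mean/sem), `pattern` and `threshold`.
#' @examples
#' sim <- simulateImage(imagePreset("aggregated", n_clusters = 4,
#'                                  field_px = 160, cell_radius_um = 7),
#'                      seed = 2)
#' quantifyImage(sim$image)$summary$n_clusters
#' @export
quantifyImage <- function(img, method = c("otsu", "fixed"), value = NULL,
                          connectivity = 8L, min_area_um2 = 0.2) {
  method <- match.arg(method)
  mask <- thresholdImage(img, method, value)
  cs <- labelClusters(mask, pixelSize(img), connectivity = connectivity,
                      min_area_um2 = min_area_um2)
  s <- clusterSummary(cs)
  list(clusters = cs, summary = s, pattern = classifyPattern(cs),
       threshold = attr(mask, "threshold"))
}
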