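## Synthetic equatorial-section images with ground truth.

#' Image simulation configuration
#'
#' Describes a single-channel equatorial confocal section of an oocyte
#' stained with a mitochondrion-accumulating dye: elliptical clusters of
#' high intensity on a flat background, optionally concentrated into a
#' peri-nuclear ring, with additive Gaussian read noise.
#'
#' @param field_px image edge length in pixels (square field).
#' @param pixel_size_um micrometres per pixel (default 0.1).
#' @param cell_radius_um ooplasm radius (default 35, i.e. a ~70 um oocyte).
#' @param n_clusters number of mitochondrial clusters to place.
#' @param mean_area_um2,area_cv arithmetic mean and coefficient of variation
#'   of the log-normal cluster-area distribution (um^2); samples are
#'   truncated below at `min_area_um2`.
#' @param cluster_intensity,background_level intensity of cluster pixels and
#'   of everything else (arbitrary camera units).
#' @param noise_sd additive Gaussian noise SD (default 5% of
#'   `cluster_intensity`); 0 gives a noiseless image.
#' @param ring optional list `list(radius_um=, width_um=, fraction=)`:
#'   `fraction` of the clusters are centred inside the annulus
#'   `[radius, radius+width]` around the image centre.
#' @param nucleus_radius_um optional germinal-vesicle exclusion radius;
#'   no cluster pixel is placed inside this disc.
#' @param min_area_um2 single-mitochondrion floor for sampled areas
#'   (default 0.2 um^2).
#' @param max_tries placement attempts per cluster before giving up.
#' @return configuration list of class `ImageSimConfig`.
#' @examples
#' cfg <- imagePreset("aggregated")
#' cfg$n_clusters
#' @export
imageSimConfig <- function(field_px = 720, pixel_size_um = 0.1,
                           cell_radius_um = 35, n_clusters = 66,
                           mean_area_um2 = 4.7, area_cv = 0.4,
                           cluster_intensity = 1000, background_level = 100,
                           noise_sd = 0.05 * cluster_intensity,
                           ring = NULL, nucleus_radius_um = NULL,
                           min_area_um2 = 0.2, max_tries = 5000) {
  stopifnot(field_px >= 8, pixel_size_um > 0, cell_radius_um > 0,
            n_clusters >= 0, mean_area_um2 > 0, area_cv >= 0,
            cluster_intensity > 0, background_level >= 0, noise_sd >= 0,
            min_area_um2 >= 0)
  if (!is.null(ring)) {
    stopifnot(all(c("radius_um", "width_um", "fraction") %in% names(ring)))
    if (ring$fraction < 0 || ring$fraction > 1)
      stop("ring fraction must lie in [0, 1]")
    stopifnot(ring$radius_um > 0, ring$width_um > 0)
  }
  if (2 * cell_radius_um / pixel_size_um > field_px)
    stop("cell does not fit in the field: increase field_px")
  structure(list(field_px = as.integer(field_px),
                 pixel_size_um = pixel_size_um,
                 cell_radius_um = cell_radius_um,
                 n_clusters = as.integer(n_clusters),
                 mean_area_um2 = mean_area_um2, area_cv = area_cv,
                 cluster_intensity = cluster_intensity,
                 background_level = background_level, noise_sd = noise_sd,
                 ring = ring, nucleus_radius_um = nucleus_radius_um,
                 min_area_um2 = min_area_um2,
                 max_tries = as.integer(max_tries)),
            class = "ImageSimConfig")
}

#' Named image presets
#'
#' `aggregated`: the pattern of GV-stage and high-ATP phases -- fewer, larger
#' clusters (66 per section, mean 4.7 um^2). `dispersed`: the 3 h / 9 h
#' pattern -- many small clusters (102 per section, mean 2.6 um^2).
#' `gvbd_ring`: aggregated plus a dense peri-nuclear ring holding 60% of the
#' clusters around a 12-um GV disc. `cytochalasin`: dispersed clusters (the
#' drug fragments large clusters; cortical clefts are not modelled).
#'
#' @param name one of `"aggregated"`, `"dispersed"`, `"gvbd_ring"`,
#'   `"cytochalasin"`.
#' @param ... overrides passed on to [imageSimConfig()].
#' @return an `ImageSimConfig`.
#' @export
imagePreset <- function(name = c("aggregated", "dispersed", "gvbd_ring",
                                 "cytochalasin"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    aggregated = list(n_clusters = 66, mean_area_um2 = 4.7),
    dispersed = list(n_clusters = 102, mean_area_um2 = 2.6),
    gvbd_ring = list(n_clusters = 66, mean_area_um2 = 4.7,
                     ring = list(radius_um = 13, width_um = 6,
                                 fraction = 0.6),
                     nucleus_radius_um = 12),
    cytochalasin = list(n_clusters = 102, mean_area_um2 = 2.6)
  )
  over <- list(...)
  args[names(over)] <- over
  cfg <- do.call(imageSimConfig, args)
  attr(cfg, "preset") <- name
  cfg
}

#' Pixel footprint of an ellipse (linear indices into the field matrix)
#' @noRd
ellipsePixels <- function(cx, cy, area_px, ratio, angle, field_px) {
  b <- sqrt(area_px / (pi * ratio))  # minor semi-axis (px)
  a <- ratio * b                     # major semi-axis (px)
  r <- ceiling(a) + 1L
  xs <- max(1L, floor(cx - r)):min(field_px, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(field_px, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(integer(0))
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  row <- rep(ys, times = length(xs))[inside]
  col <- rep(xs, each = length(ys))[inside]
  (col - 1L) * field_px + row
}

#' 8-neighbourhood dilation of a set of linear indices (clipped to field)
#' @noRd
dilateIdx <- function(idx, field_px) {
  row <- ((idx - 1L) %% field_px) + 1L
  col <- ((idx - 1L) %/% field_px) + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    r2 <- row + dr; c2 <- col + dc
    ok <- r2 >= 1L & r2 <= field_px & c2 >= 1L & c2 <= field_px
    out <- c(out, (c2[ok] - 1L) * field_px + r2[ok])
  }
  unique(out)
}

#' Simulate an equatorial-section image
#'
#' Samples cluster areas from the truncated log-normal, renders each cluster
#' as a filled ellipse (axis ratio U(1,2), random orientation) at a
#' rejection-sampled position, forbids overlap (including diagonal contact,
#' so ground-truth components never merge), adds Gaussian noise, and returns
#' the image together with a consistent ground-truth label mask.
#'
#' @param config an [imageSimConfig()] / [imagePreset()] object.
#' @param seed integer seed; identical config + seed reproduce the image
#'   bit for bit.
#' @return list with elements `image` ([MitoImage-class]), `labels`
#'   (integer matrix, 0 = background), `clusters` (data.frame: `id`,
#'   `area_um2` sampled, `pixel_count` rendered, `centroid_x`, `centroid_y`,
#'   `in_ring`), and `config`.
#' @examples
#' sim <- simulateImage(imagePreset("aggregated", n_clusters = 5,
#'                                  field_px = 200, cell_radius_um = 9),
#'                      seed = 1)
#' max(sim$labels)  # 5
#' @export
simulateImage <- function(config = imageSimConfig(), seed = NULL) {
  stopifnot(inherits(config, "ImageSimConfig"))
  if (!is.null(seed)) set.seed(seed)
  fp <- config$field_px
  psz <- config$pixel_size_um
  center <- (fp + 1) / 2  # both x and y (square field)
  cell_r_px <- config$cell_radius_um / psz
  nuc_r_px <- if (is.null(config$nucleus_radius_um)) 0 else
    config$nucleus_radius_um / psz

  labels <- matrix(0L, fp, fp)
  n <- config$n_clusters
  clusters <- data.frame(id = integer(0), area_um2 = numeric(0),
                         pixel_count = integer(0), centroid_x = numeric(0),
                         centroid_y = numeric(0), in_ring = logical(0))

  if (n > 0) {
    areas <- rlnormMeanCv(n, config$mean_area_um2, config$area_cv,
                          floor = config$min_area_um2)
    ratios <- stats::runif(n, 1, 2)
    angles <- stats::runif(n, 0, pi)
    n_ring <- if (is.null(config$ring)) 0L else
      as.integer(round(config$ring$fraction * n))
    in_ring <- seq_len(n) <= n_ring
    # place big clusters first within each group: eases packing at high
    # ring densities without changing the sampled area distribution
    ord <- order(!in_ring, -areas)
    occupied <- matrix(FALSE, fp, fp)
    ids <- integer(n); cxs <- numeric(n); cys <- numeric(n)
    pixlist <- vector("list", n)
    placed_px <- 0
    for (jj in seq_len(n)) {
      j <- ord[jj]
      area_px <- areas[j] / psz^2
      ok <- FALSE
      for (try in seq_len(config$max_tries)) {
        if (in_ring[j]) {
          rad <- stats::runif(1, config$ring$radius_um,
                              config$ring$radius_um + config$ring$width_um) /
            psz
          th <- stats::runif(1, 0, 2 * pi)
          cx <- center + rad * cos(th)
          cy <- center + rad * sin(th)
        } else {
          cx <- stats::runif(1, center - cell_r_px, center + cell_r_px)
          cy <- stats::runif(1, center - cell_r_px, center + cell_r_px)
          d <- sqrt((cx - center)^2 + (cy - center)^2)
          if (d > cell_r_px || d < nuc_r_px) next
        }
        px <- ellipsePixels(cx, cy, area_px, ratios[j], angles[j], fp)
        if (!length(px)) next
        row <- ((px - 1L) %% fp) + 1L
        col <- ((px - 1L) %/% fp) + 1L
        dcell <- sqrt((col - center)^2 + (row - center)^2)
        if (any(dcell > cell_r_px)) next          # inside the cell mask
        if (nuc_r_px > 0 && any(dcell < nuc_r_px)) next  # outside the GV
        grown <- dilateIdx(px, fp)
        if (any(occupied[grown])) next            # no contact with others
        occupied[px] <- TRUE
        labels[px] <- jj
        ids[jj] <- jj
        cxs[jj] <- mean(col); cys[jj] <- mean(row)
        pixlist[[jj]] <- px
        placed_px <- placed_px + length(px)
        ok <- TRUE
        break
      }
      if (!ok) {
        region <- if (in_ring[j]) "ring annulus" else "cell"
        stop(sprintf(paste0(
          "cluster placement failed after %d tries (cluster %d of %d, ",
          "%.2f um2, %s): achievable density reached at %d clusters / ",
          "%.0f um2 foreground"), config$max_tries, jj, n, areas[j],
          region, jj - 1L, placed_px * psz^2))
      }
    }
    clusters <- data.frame(
      id = seq_len(n),
      area_um2 = areas[ord],
      pixel_count = vapply(pixlist, length, integer(1)),
      centroid_x = cxs, centroid_y = cys,
      in_ring = in_ring[ord]
    )
  }

  pixels <- matrix(config$background_level, fp, fp)
  pixels[labels > 0L] <- config$cluster_intensity
  if (config$noise_sd > 0)
    pixels <- pmax(pixels + matrix(stats::rnorm(fp * fp, 0, config$noise_sd),
                                   fp, fp), 0)
  img <- MitoImage(pixels, psz,
                   meta = list(preset = attr(config, "preset"), seed = seed,
                               center_px = c(center, center),
                               cell_radius_um = config$cell_radius_um,
                               nucleus_radius_um = config$nucleus_radius_um,
                               ring = config$ring))
  list(image = img, labels = labels, clusters = clusters, config = config)
}
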