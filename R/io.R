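## Readers, writers and run configuration.

RESULTS_SCHEMA_VERSION <- "1.0"

#' Read a luminescence trace from CSV
#'
#' Expects the two-column format `time_h,counts`, one row per acquisition
#' bin: times are bin centers in hours on a uniform grid, counts are
#' non-negative integers.
#'
#' @param path CSV file path.
#' @return a [LuminescenceTrace-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeTraceCsv(simulateTrace(traceSimConfig(), seed = 1), f)
#' tr <- readTraceCsv(f)
#' @export
readTraceCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "time_h,counts"))
    stop("line 1: expected header 'time_h,counts', got '", header, "'")
  df <- utils::read.csv(path, colClasses = "character")
  if (!nrow(df)) stop("no data rows in ", path)
  time_h <- suppressWarnings(as.numeric(df$time_h))
  counts <- suppressWarnings(as.numeric(df$counts))
  for (i in seq_len(nrow(df))) {  # line i+1 in the file (header is line 1)
    if (is.na(time_h[i]) || is.na(counts[i]))
      stop("line ", i + 1L, ": malformed row '",
           paste(df[i, ], collapse = ","), "'")
    if (counts[i] < 0)
      stop("line ", i + 1L, ": negative counts (", counts[i], ")")
    if (abs(counts[i] - round(counts[i])) > 1e-9)
      stop("line ", i + 1L, ": counts must be integers (", counts[i], ")")
  }
  if (length(time_h) >= 2) {
    d <- diff(time_h)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-6 * d[1]) {
      bad <- which(abs(d - d[1]) > 1e-6 * d[1] | d <= 0)[1]
      stop("line ", bad + 2L, ": non-uniform time grid")
    }
    bin_s <- d[1] * 3600
  } else {
    bin_s <- 30
  }
  LuminescenceTrace(time_h, counts, bin_s = bin_s,
                    meta = list(source = path))
}

#' Write a luminescence trace to CSV
#'
#' @param trace a [LuminescenceTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "LuminescenceTrace"))
  df <- data.frame(time_h = traceTimes(trace), counts = traceCounts(trace))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 16-bit grayscale image plus its pixel-size sidecar
#'
#' Supported rasters are TIFF and PNG; a JSON sidecar carrying
#' `pixel_size_um` is mandatory because cluster areas are meaningless
#' without it.
#'
#' @param path raster path (`.tif`, `.tiff` or `.png`).
#' @param sidecar JSON sidecar path (default `paste0(path, ".json")`).
#' @return a [MitoImage-class]; intensities are on the stored integer scale
#'   (0..65535 for 16-bit files).
#' @export
readMitoImage <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(sidecar))
    stop("missing sidecar '", sidecar,
         "': pixel_size_um is required (areas would be meaningless)")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um))
    stop("sidecar '", sidecar, "' lacks pixel_size_um")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    png = round(png::readPNG(path) * 65535),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(px)) == 3L) px <- px[, , 1]
  MitoImage(px, meta$pixel_size_um, meta = as.list(meta))
}

#' Write an image as 16-bit grayscale TIFF (or PNG) plus JSON sidecar
#'
#' @param img a [MitoImage-class]; intensities are clamped to 0..65535 and
#'   rounded.
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @param preset,seed optional provenance recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
writeMitoImage <- function(img, path, preset = NULL, seed = NULL) {
  stopifnot(is(img, "MitoImage"))
  v <- round(pmin(pmax(imagePixels(img), 0), 65535))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L),
    png = png::writePNG(v / 65535, path),
    stop("unsupported raster format: .", ext)
  )
  sidecar <- list(pixel_size_um = pixelSize(img),
                  preset = preset %||% (img@meta$preset %||% NA),
                  seed = seed %||% (img@meta$seed %||% NA))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a label raster as 16-bit TIFF
#'
#' Labels up to 65535 round-trip exactly.
#'
#' @param labels integer matrix (0 = background).
#' @param path TIFF path.
#' @return `path` (write) or the integer label matrix (read).
#' @export
writeLabelTiff <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) <= 65535, min(labels) >= 0)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelTiff
#' @export
readLabelTiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Write a results object as versioned JSON
#'
#' @param obj a list, data.frame, or [CohortReport-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(obj, path) {
  if (is(obj, "CohortReport")) obj <- reportAsList(obj)
  out <- list(schema_version = RESULTS_SCHEMA_VERSION, results = obj)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

## Run configuration ---------------------------------------------------------

runConfigKeys <- function() {
  c("seed", "model", "detector", "trace_arms", "image_arms", "out")
}

#' Validate an experiment run configuration
#'
#' Schema: `seed` (integer), `model` ("weibull"/"lognormal"), `detector`
#' (overrides for [detectorParams()]), `trace_arms` (list of
#' `{preset, n}`), `image_arms` (list of `{preset, n}`), `out` (optional
#' output directory). Unknown keys are rejected.
#'
#' @param config a list.
#' @return the validated config (with defaults filled in).
#' @export
validateRunConfig <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), runConfigKeys())
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$model <- match.arg(config$model %||% "weibull",
                            c("weibull", "lognormal"))
  det <- config$detector %||% list()
  unknown <- setdiff(names(det),
                     c("tau", "smooth_bins", "min_dur_min", "merge_gap_min",
                       "edge_trim_min"))
  if (length(unknown))
    stop("unknown detector keys: ", paste(unknown, collapse = ", "))
  config$detector <- det
  for (arm in config$trace_arms %||% list()) {
    if (!all(c("preset", "n") %in% names(arm)))
      stop("each trace arm needs 'preset' and 'n'")
    match.arg(arm$preset, treatmentPresets())
  }
  for (arm in config$image_arms %||% list()) {
    if (!all(c("preset", "n") %in% names(arm)))
      stop("each image arm needs 'preset' and 'n'")
    match.arg(arm$preset,
              c("aggregated", "dispersed", "gvbd_ring", "cytochalasin"))
  }
  config
}

#' Read / write an experiment configuration (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported config format: .", ext)
  )
  validateRunConfig(config)
}

#' @rdname readRunConfig
#' @param config a configuration list.
#' @export
writeRunConfig <- function(config, path) {
  config <- validateRunConfig(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(config, path),
    json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop("unsupported config format: .", ext)
  )
  invisible(path)
}
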