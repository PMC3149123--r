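## Internal numerical helpers.

#' Centered moving average with shrinking edge windows
#' @noRd
movingAverage <- function(x, w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L  # enforce odd window
  if (w <= 1L) return(x)
  out <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  # shrink the window at the edges instead of returning NA
  h <- (w - 1L) %/% 2L
  n <- length(x)
  for (i in seq_len(min(h, n))) {
    out[i] <- mean(x[1:min(i + h, n)])
    j <- n - i + 1L
    out[j] <- mean(x[max(1L, j - h):n])
  }
  out
}

#' Baseline mean function: counts per bin
#'
#' Scaled Weibull (or log-normal) density plus a flat offset, modelling
#' luciferase expression followed by destruction. `A` is the total photon
#' budget, so the per-bin expectation carries the bin width:
#' `b + A * pdf(t - t0) * bin_h`.
#' @noRd
baselineMean <- function(t, params, bin_h, model = "weibull") {
  t0 <- params[["t0"]]
  b <- params[["b"]]
  A <- params[["A"]]
  x <- pmax(t - t0, 1e-9)
  dens <- switch(model,
    weibull = stats::dweibull(x, shape = params[["k"]],
                              scale = params[["lam"]]),
    lognormal = stats::dlnorm(x, meanlog = params[["mu"]],
                              sdlog = params[["sigma"]]),
    stop("unknown baseline model: ", model)
  )
  dens[t <= t0] <- 0
  b + A * dens * bin_h
}

#' Sample a log-normal with given arithmetic mean and CV, truncated below
#' @noRd
rlnormMeanCv <- function(n, mean, cv, floor = 0) {
  sigma2 <- log(1 + cv^2)
  mu <- log(mean) - sigma2 / 2
  x <- stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
  for (i in 1:100) {
    bad <- x < floor
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog = mu, sdlog = sqrt(sigma2))
  }
  x[x < floor] <- floor
  x
}

#' Binomial proportion with its standard error
#'
#' @param k number of events.
#' @param n number of trials.
#' @return list with `frac` (k/n) and `se` (`sqrt(p(1-p)/n)`).
#' @examples
#' incidence(29, 31)
#' @export
incidence <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  p <- k / n
  list(frac = p, se = sqrt(p * (1 - p) / n))
}

#' Squared-distance matrix (um^2) from a pixel-coordinate center
#' @noRd
distanceUm <- function(dims, center_px, pixel_size_um) {
  # center_px = c(x, y) in pixel units; rows are y, columns are x
  rows <- seq_len(dims[1])
  cols <- seq_len(dims[2])
  dy <- (rows - center_px[2]) * pixel_size_um
  dx <- (cols - center_px[1]) * pixel_size_um
  sqrt(outer(dy^2, dx^2, `+`))
}

#' md5 hash of an R object (via temporary file)
#' @noRd
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(x, vec.len = 1e6,
                                              digits.d = 15)), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
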