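# Independent brute-force oracles used to validate the fast implementations.

# Queue-based flood fill; labels connected components one seed at a time.
floodFillLabel <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# TRUE iff two label matrices define the same partition of the foreground.
samePartition <- function(lab1, lab2) {
  if (!identical(lab1 > 0, lab2 > 0)) return(FALSE)
  fg <- which(lab1 > 0)
  if (!length(fg)) return(TRUE)
  key <- paste(lab1[fg], lab2[fg])
  length(unique(key)) == length(unique(lab1[fg])) &&
    length(unique(key)) == length(unique(lab2[fg]))
}

# Naive Otsu: same 256-bin histogram contract, scalar loop over every cut.
otsuOracle <- function(x, levels = 256L) {
  x <- as.numeric(x)
  r <- range(x)
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              levels)
  h <- tabulate(bin, nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  best <- -Inf; best_i <- 1L
  for (i in 1:(levels - 1L)) {
    n0 <- sum(h[1:i]); n1 <- sum(h[(i + 1):levels])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(h[1:i] * mids[1:i]) / n0
    m1 <- sum(h[(i + 1):levels] * mids[(i + 1):levels]) / n1
    sb <- (n0 / length(x)) * (n1 / length(x)) * (m0 - m1)^2
    if (sb > best) { best <- sb; best_i <- i }
  }
  breaks[best_i + 1L]
}

# Exhaustive pulse-run oracle: naive smoothing, all-window maximal-run scan,
# then the same duration/merge/trim rules applied with plain loops.
runScanOracle <- function(z, times, bin_s, tau, smooth_bins, min_dur_min,
                          merge_gap_min, edge_trim_min) {
  n <- length(z)
  w <- as.integer(smooth_bins); if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  zs <- vapply(seq_len(n), function(i)
    mean(z[max(1, i - h):min(n, i + h)]), numeric(1))
  above <- zs > tau
  trim_h <- edge_trim_min / 60
  above[times < times[1] + trim_h |
        times > times[n] + 1e-12 - trim_h] <- FALSE
  # all maximal windows with every bin above threshold
  runs <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (all(above[i:j]) &&
        (i == 1 || !above[i - 1]) && (j == n || !above[j + 1])) {
      runs[[length(runs) + 1L]] <- c(i, j)
    }
    if (!above[j]) break
  }
  if (!length(runs)) return(data.frame(start = integer(0), end = integer(0)))
  runs <- do.call(rbind, runs)
  runs <- unique(runs)
  keep <- (runs[, 2] - runs[, 1] + 1L) * bin_s / 60 >= min_dur_min
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(data.frame(start = integer(0), end = integer(0)))
  runs <- runs[order(runs[, 1]), , drop = FALSE]
  out <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap_min <- (runs[i, 1] - out[nrow(out), 2] - 1L) * bin_s / 60
    if (gap_min <= merge_gap_min) out[nrow(out), 2] <- runs[i, 2]
    else out <- rbind(out, runs[i, , drop = FALSE])
  }
  data.frame(start = out[, 1], end = out[, 2])
}

# A BaselineFit whose residuals realize a prescribed z-series.
fitFromZ <- function(z, fitted, bin_s = 30) {
  n <- length(z)
  times <- (seq_len(n) - 0.5) * bin_s / 3600
  resid <- z * sqrt(pmax(fitted, 1))
  BaselineFit(model = "weibull",
              params = c(A = 0, k = 2, lam = 1, t0 = 0, b = fitted[1]),
              times = times, counts = fitted + resid, fitted = fitted,
              bin_s = bin_s, converged = TRUE)
}

# Small, quick image configuration for structural tests.
smallImageConfig <- function(...) {
  args <- list(field_px = 200, cell_radius_um = 9, n_clusters = 12,
               mean_area_um2 = 2.5)
  over <- list(...)
  args[names(over)] <- over
  do.call(imageSimConfig, args)
}

# Drop attributes (e.g. the recorded threshold) for mask comparisons.
bareMask <- function(m) matrix(as.vector(m), nrow(m), ncol(m))
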