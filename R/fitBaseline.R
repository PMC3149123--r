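## Baseline regression: scaled Weibull / log-normal expression-decay curve.

#' Fit the luciferase expression/destruction baseline
#'
#' Fits `counts ~ b + A * pdf(t - t0) * bin_h` by Levenberg-Marquardt
#' nonlinear least squares, where `pdf` is a Weibull or log-normal density.
#' The recording from a non-maturing (IBMX-arrested) oocyte follows this
#' smooth curve; in a maturing oocyte the supra-baseline ATP pulses remain
#' in the residuals.
#'
#' Starting values are moment-based: `t0` at the first bin, `lam` at the
#' (smoothed) time of peak counts, `k = 2`, `A` the total photon count,
#' `b` the minimum count. Parameters are bounded (`A, b >= 0`,
#' `0.2 <= k <= 20`, `1e-3 <= lam <= 1e3`, `0 <= t0 <= max(t)`).
#'
#' @param trace a [LuminescenceTrace-class] with at least 100 bins.
#' @param model `"weibull"` (default) or `"lognormal"`. The choice is left
#'   to the caller; no automatic selection is performed.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return a [BaselineFit-class]. If the solver fails to converge the fit is
#'   returned with `converged = FALSE`; [detectPulses()] then refuses it
#'   unless forced.
#' @examples
#' tr <- simulateTrace(traceSimConfig(pulses = defaultPulseSchedule()[0, ],
#'                                    poisson_noise = FALSE))
#' fit <- fitBaseline(tr)
#' coef(fit)["k"]
#' @export
fitBaseline <- function(trace, model = c("weibull", "lognormal"),
                        max_iter = 200L) {
  model <- match.arg(model)
  stopifnot(is(trace, "LuminescenceTrace"))
  t <- traceTimes(trace)
  y <- traceCounts(trace)
  if (length(y) < 100L)
    stop("baseline fitting requires at least 100 bins")
  if (all(y == 0))
    stop("counts are all zero; nothing to fit")
  bin_h <- binSeconds(trace) / 3600

  b0 <- min(y)
  A0 <- max(sum(y) - b0 * length(y), 1)
  lam0 <- max(t[which.max(movingAverage(y, 21L))], 10 * bin_h)
  start <- if (model == "weibull") {
    c(A = A0, k = 2, lam = lam0, t0 = t[1], b = b0)
  } else {
    c(A = A0, mu = log(lam0), sigma = 0.5, t0 = t[1], b = b0)
  }
  lower <- if (model == "weibull") {
    c(A = 0, k = 0.2, lam = 1e-3, t0 = 0, b = 0)
  } else {
    c(A = 0, mu = -10, sigma = 0.01, t0 = 0, b = 0)
  }
  upper <- if (model == "weibull") {
    c(A = Inf, k = 20, lam = 1e3, t0 = max(t), b = Inf)
  } else {
    c(A = Inf, mu = 10, sigma = 10, t0 = max(t), b = Inf)
  }

  fn <- function(p) baselineMean(t, p, bin_h, model = model)
  resid_fn <- function(p) {
    names(p) <- names(start)
    y - fn(p)
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)

  if (is.null(out)) {
    params <- start
    converged <- FALSE
    n_iter <- 0L
  } else {
    params <- stats::setNames(as.numeric(out$par), names(start))
    # info codes 1-3 are the documented success statuses of MINPACK lmdif
    converged <- out$info %in% 1:3
    n_iter <- as.integer(out$niter)
  }
  fitted <- fn(params)
  BaselineFit(model = model, params = params, times = t, counts = y,
              fitted = fitted, bin_s = binSeconds(trace),
              converged = converged, nIter = n_iter)
}
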