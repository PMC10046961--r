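#' Single-well fluorescence trace
#'
#' A `calosc_trace` holds one well's whole-well fluorescence time series for
#' one recording window, together with its sampling metadata. Times are in
#' seconds from the start of the window, values in relative light units (RLU).
#'
#' @param values Numeric vector of fluorescence values (RLU), length >= 2.
#' @param rate_hz Sampling rate in samples/s; 2 (monolayer recordings) or
#'   10 (spheroid recordings).
#' @param well_id Well label, row letter plus column number (e.g. `"B2"`).
#' @param window Recording window, `"baseline"` or `"post"`.
#' @param times Optional explicit time vector in seconds; must be uniformly
#'   spaced (to within 1e-9 s) and consistent with `rate_hz`. Defaults to
#'   `(0:(n-1))/rate_hz`.
#'
#' @return An object of class `calosc_trace`: a list with elements
#'   `well_id`, `times`, `values`, `rate_hz`, `window`.
#' @examples
#' tr <- new_trace(sin(seq(0, 20, by = 0.5)), rate_hz = 2)
#' tr
#' @export
new_trace <- function(values, rate_hz, well_id = "B2", window = "baseline",
                      times = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("a trace needs at least 2 samples")
  if (!rate_hz %in% c(2, 10)) stop("rate_hz must be 2 or 10 samples/s")
  if (anyNA(values)) stop("trace values contain NA")
  if (is.null(times)) {
    times <- seq(0, by = 1 / rate_hz, length.out = n)
  } else {
    times <- as.numeric(times)
    if (length(times) != n) stop("times and values differ in length")
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(abs(dt - 1 / rate_hz)) > 1e-9)
      stop("times are not uniform at 1/rate_hz spacing (tolerance 1e-9 s)")
  }
  window <- match.arg(window, c("baseline", "post"))
  structure(
    list(well_id = well_id, times = times, values = values,
         rate_hz = rate_hz, window = window),
    class = "calosc_trace"
  )
}

#' @export
print.calosc_trace <- function(x, ...) {
  cat(sprintf("<calosc_trace> well %s, %s window: %d samples at %g Hz (%.1f s)\n",
              x$well_id, x$window, length(x$values), x$rate_hz,
              length(x$values) / x$rate_hz))
  invisible(x)
}

is_trace <- function(x) inherits(x, "calosc_trace")

trace_duration <- function(trace) length(trace$values) / trace$rate_hz

#' Moving-average smoothing of a trace
#'
#' Centered moving average with an odd window of approximately
#' `window * rate_hz` samples. At the edges the window is truncated to the
#' available samples and the missing weight is reassigned to the center
#' sample, which keeps the smoothing matrix doubly stochastic: the mean of
#' the output equals the mean of the input exactly, constants are fixed
#' points, and affine signals are preserved on the interior.
#'
#' @param trace A [new_trace()] object.
#' @param window Smoothing window length in seconds (default 2.5 s: 5 samples
#'   at 2 Hz, 25 samples at 10 Hz). Must span at least 2 sampling intervals.
#' @return A `calosc_trace` with smoothed values.
#' @examples
#' tr <- new_trace(c(0, 0, 10, 0, 0, 0, 0, 0), rate_hz = 2)
#' smooth_trace(tr, window = 2.5)$values
#' @export
smooth_trace <- function(trace, window = 2.5) {
  stopifnot(is_trace(trace))
  dt <- 1 / trace$rate_hz
  if (window < 2 * dt)
    stop("smoothing window must span at least 2 sampling intervals")
  x <- trace$values
  n <- length(x)
  h <- max(1L, floor(window * trace$rate_hz / 2))
  w <- 2L * h + 1L
  cs <- cumsum(x)
  i <- seq_len(n)
  hi <- pmin(n, i + h)
  lo <- pmax(1L, i - h)
  winsum <- cs[hi] - c(0, cs)[lo]
  count <- hi - lo + 1L
  out <- (winsum + (w - count) * x) / w
  trace$values <- out
  trace
}

#' Numerical derivative of a trace
#'
#' Central differences on the interior, one-sided differences at the
#' boundaries. Exact for affine signals.
#'
#' @param trace A [new_trace()] object with at least 3 samples.
#' @return Numeric vector of the same length as the trace, in RLU/s.
#' @examples
#' tr <- new_trace(3 * seq(0, 10, by = 0.5), rate_hz = 2)
#' range(differentiate_trace(tr))
#' @export
differentiate_trace <- function(trace) {
  stopifnot(is_trace(trace))
  x <- trace$values
  n <- length(x)
  if (n < 3L) stop("differentiation needs at least 3 samples")
  dt <- 1 / trace$rate_hz
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}
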