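#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with unit rate: a positive lobe
#' peaking at `peak` seconds and an undershoot peaking at `undershoot`
#' seconds, scaled by `1/ratio`. The result is normalized to unit peak
#' height so that evoked amplitudes are expressed directly in percent
#' signal change at the response peak.
#'
#' @param t time grid in seconds (values before 0 give 0).
#' @param peak positive-lobe peak time, seconds.
#' @param undershoot undershoot peak time, seconds.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector of amplitudes, max 1 over a dense grid.
#' @export
canonical_hrf <- function(t, peak = 5, undershoot = 15, ratio = 6) {
  if (any(t < 0)) stop("time grid must be non-negative")
  raw <- function(tt) {
    stats::dgamma(tt, shape = peak + 1, rate = 1) -
      stats::dgamma(tt, shape = undershoot + 1, rate = 1) / ratio
  }
  peak_height <- max(raw(seq(0, 32, by = 0.01)))
  raw(t) / peak_height
}

#' Unit-peak response kernel for a sustained (boxcar) event
#'
#' Convolves a boxcar of the given duration with [canonical_hrf()] on a
#' fine time grid and rescales to unit peak, so an event of amplitude
#' `a` (percent of baseline) produces a peak evoked response of `a`
#' regardless of its duration.
#'
#' @param duration_seconds event duration (boxcar width).
#' @param dt convolution grid step, seconds.
#' @param span_seconds HRF support retained after the event ends.
#' @inheritParams canonical_hrf
#' @return object of class `hrf_kernel`: list with `time` and `values`.
#' @export
hrf_kernel <- function(duration_seconds, dt = 0.1, span_seconds = 32,
                       peak = 5, undershoot = 15, ratio = 6) {
  stopifnot(duration_seconds > 0, dt > 0)
  t_h <- seq(0, span_seconds, by = dt)
  h <- canonical_hrf(t_h, peak = peak, undershoot = undershoot, ratio = ratio)
  n_box <- max(1L, round(duration_seconds / dt))
  box <- rep(1, n_box)
  conv <- stats::convolve(c(h, rep(0, n_box)), rev(box), type = "open") * dt
  conv <- conv[seq_len(length(t_h) + n_box - 1L)]
  times <- seq(0, by = dt, length.out = length(conv))
  structure(
    list(time = times, values = conv / max(conv), duration = duration_seconds,
         dt = dt),
    class = "hrf_kernel"
  )
}

# cache: kernels are reused across thousands of simulated runs
.kernel_cache <- new.env(parent = emptyenv())

.cached_kernel <- function(duration_seconds, dt = 0.1) {
  key <- paste(duration_seconds, dt, sep = "|")
  if (is.null(.kernel_cache[[key]])) {
    .kernel_cache[[key]] <- hrf_kernel(duration_seconds, dt = dt)
  }
  .kernel_cache[[key]]
}

#' Evaluate an event-response kernel at arbitrary lags
#'
#' Linear interpolation of the kernel; 0 outside its support (in
#' particular for negative lags, i.e. before the event onset).
#'
#' @param kernel an `hrf_kernel`.
#' @param lag_seconds numeric vector of times since event onset.
#' @export
kernel_value <- function(kernel, lag_seconds) {
  out <- numeric(length(lag_seconds))
  inside <- lag_seconds >= 0 & lag_seconds <= max(kernel$time)
  if (any(inside)) {
    lags <- lag_seconds[inside]
    steps <- lags / kernel$dt
    if (all(abs(steps - round(steps)) < 1e-9)) {
      # lags on the kernel grid (the usual case: integer-second onsets)
      out[inside] <- kernel$values[round(steps) + 1]
    } else {
      out[inside] <- stats::approx(kernel$time, kernel$values, xout = lags)$y
    }
  }
  out
}
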