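#' Canonical mu-rhythm band definitions
#'
#' Alpha 8--14 Hz and beta 15--30 Hz, the sensorimotor mu-rhythm components
#' used throughout the pipeline.
#'
#' @return named list of `c(low, high)` band edges in Hz
#' @export
mu_bands <- function() list(alpha = c(8, 14), beta = c(15, 30))

#' Zero-phase Butterworth band-pass filter
#'
#' Designs an IIR Butterworth band-pass filter of the given order (poles in
#' the single-pass filter; a band-pass design with `order/2` per edge) and
#' applies it forward and backward so that the net phase response is zero.
#' Edge transients are suppressed by odd-reflection padding of ten cycles
#' of the low band edge at each end (enough for the narrow-band transient
#' to decay below round-off scale); the padding is discarded so the output
#' has the length of the input.
#'
#' @param x numeric time series
#' @param fs sampling rate in Hz
#' @param low,high band edges in Hz, `0 < low < high < fs/2`
#' @param order order of the single-pass band-pass filter; must be even
#'   (default 6). Forward-backward application doubles the effective
#'   attenuation.
#' @return filtered series, same length as `x`
#' @export
bandpass_zero_phase <- function(x, fs, low, high, order = 6) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band edges: need 0 < low < high < fs/2")
  if (order %% 2 != 0) stop("order must be even for a band-pass design")
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  if (length(x) < 10L * order) stop("signal too short for filter warm-up")
  pad <- min(length(x) - 1L, as.integer(round(10 * fs / low)))
  # odd reflection about the end points keeps the padded signal continuous
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[seq(pad + 1L, pad + length(x))]
}

#' Full-wave rectification
#'
#' @param x numeric time series
#' @return elementwise absolute value
#' @export
rectify <- function(x) abs(x)

#' Centered moving-average smoothing
#'
#' Smooths with a centered moving mean of `round(window_s * fs)` samples
#' (incremented to the next odd length so the window is symmetric). Edges
#' are handled by reflection padding, so the output has the length of the
#' input.
#'
#' @param x numeric time series
#' @param fs sampling rate in Hz
#' @param window_s window length in seconds (default 0.1)
#' @return smoothed series, same length as `x`
#' @export
moving_average <- function(x, fs, window_s = 0.1) {
  L <- as.integer(round(window_s * fs))
  if (L < 1L) stop("window shorter than one sample")
  if (L %% 2L == 0L) L <- L + 1L
  if (L > length(x)) stop("window longer than signal")
  h <- (L - 1L) %/% 2L
  xp <- if (h > 0L)
    c(x[seq(h + 1L, 2L)], x, x[seq(length(x) - 1L, length(x) - h)])
  else x
  cs <- cumsum(c(0, xp))
  (cs[seq(L + 1L, length(xp) + 1L)] - cs[seq_len(length(xp) - L + 1L)]) / L
}

#' Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal, computed through the FFT: the negative
#' frequencies are zeroed, positive frequencies doubled, and the inverse
#' transform's modulus taken.
#'
#' @param x finite numeric time series
#' @return nonnegative envelope, same length as `x`
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (any(!is.finite(x))) stop("signal must be finite")
  # pad to a 2-3-5-smooth length (reflected tail) so the FFT stays O(n log n)
  m <- stats::nextn(n, c(2L, 3L, 5L))
  xp <- if (m > n) c(x, x[seq(n, by = -1L, length.out = m - n)]) else x
  X <- stats::fft(xp)
  h <- numeric(m)
  if (m %% 2L == 0L) {
    h[c(1L, m / 2L + 1L)] <- 1
    h[2:(m / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((m + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / m)[seq_len(n)]
}

#' Band-limited amplitude envelope of one channel
#'
#' The two extraction methods share the zero-phase band-pass front end and
#' differ in the demodulation step:
#' \describe{
#'   \item{`rectify_smooth`}{full-wave rectification followed by a 0.1 s
#'     centered moving average (the default). Note the rectified-and-
#'     smoothed envelope of a tone of amplitude A converges to `2A/pi`.}
#'   \item{`hilbert_am`}{magnitude of the analytic signal (amplitude
#'     modulation method); a tone of amplitude A gives envelope A.}
#' }
#'
#' @param rec a [recording()]
#' @param channel channel label (case-insensitive)
#' @param band `"alpha"`, `"beta"`, or a numeric `c(low, high)` in Hz
#' @param method `"rectify_smooth"` or `"hilbert_am"`
#' @param order band-pass filter order (see [bandpass_zero_phase()])
#' @param window_s smoothing window for `rectify_smooth`, seconds
#' @return an `envelope_signal`: list with `values` (nonnegative, microvolts,
#'   same length as the channel), `fs`, `channel`, `band`, `band_edges`,
#'   `method`
#' @export
compute_envelope <- function(rec, channel, band = "alpha",
                             method = c("rectify_smooth", "hilbert_am"),
                             order = 6, window_s = 0.1) {
  method <- match.arg(method)
  x <- get_channel(rec, channel)
  if (is.character(band)) {
    edges <- mu_bands()[[band]]
    if (is.null(edges)) stop("unknown band: ", band)
    band_name <- band
  } else {
    edges <- as.numeric(band)
    if (length(edges) != 2L) stop("numeric band must be c(low, high)")
    band_name <- paste0(edges[1], "-", edges[2], "Hz")
  }
  bp <- bandpass_zero_phase(x, rec$fs, edges[1], edges[2], order = order)
  values <- switch(method,
    rectify_smooth = moving_average(rectify(bp), rec$fs, window_s),
    hilbert_am = hilbert_envelope(bp)
  )
  structure(
    list(values = values, fs = rec$fs, channel = channel, band = band_name,
         band_edges = edges, method = method),
    class = "envelope_signal"
  )
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf(
    "<envelope_signal> %s %s [%g-%g Hz], %s, %d samples @ %g Hz\n",
    x$channel, x$band, x$band_edges[1], x$band_edges[2], x$method,
    length(x$values), x$fs))
  invisible(x)
}
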