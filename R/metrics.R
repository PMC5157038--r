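#' Response extrema in the pre- and post-onset search windows
#'
#' `amp_min` is the minimum of the averaged envelope over the pre-onset
#' window `[-1.5, 0)` and `amp_max` the maximum over the post-onset window
#' `[0, 2)` (both half-open; ties broken by the earliest time point).
#'
#' @param resp an `event_related_response` from [block_average()]
#' @param pre_window,post_window `c(start, end)` seconds relative to onset
#' @return named list with `amp_min`, `amp_max`, `t_min`, `t_max`
#' @export
amp_extrema <- function(resp, pre_window = c(-1.5, 0),
                        post_window = c(0, 2)) {
  t <- resp$time
  pre <- t >= pre_window[1] & t < pre_window[2]
  post <- t >= post_window[1] & t < post_window[2]
  if (!any(pre) || !any(post))
    stop("search windows outside the response time axis")
  v <- resp$values
  i_min <- which(pre)[which.min(v[pre])]
  i_max <- which(post)[which.max(v[post])]
  list(amp_min = v[i_min], amp_max = v[i_max],
       t_min = t[i_min], t_max = t[i_max])
}

#' Amplitude response
#'
#' @param amp_min pre-onset minimum, microvolts
#' @param amp_max post-onset maximum, microvolts
#' @return `amp_max - amp_min`, microvolts
#' @export
amp_resp <- function(amp_min, amp_max) amp_max - amp_min

#' Normalized amplitude response (percent)
#'
#' The amplitude response normalized to the midpoint of the averaged
#' response, `100 * (amp_max - amp_min) / ((amp_max + amp_min) / 2)`. The
#' normalization makes the statistic invariant to overall signal scale; for
#' nonnegative envelopes it lies in `[0, 200]`.
#'
#' @param amp_min,amp_max response extrema, microvolts
#' @return PAmp_resp in percent
#' @export
pamp_resp <- function(amp_min, amp_max) {
  if (amp_max + amp_min <= 0)
    stop("undefined result: amp_max + amp_min must be positive")
  100 * (amp_max - amp_min) / ((amp_max + amp_min) / 2)
}

#' Laterality index
#'
#' Inter-hemispheric asymmetry of the normalized amplitude response:
#' `(contra - ipsi) / (contra + ipsi)`. Positive values mean contralateral
#' dominance; for nonnegative inputs the index lies in `[-1, 1]`.
#'
#' @param pamp_contra,pamp_ipsi PAmp_resp (%) of the hemispheres
#'   contralateral and ipsilateral to the moving hand
#' @return dimensionless laterality index
#' @export
laterality_index <- function(pamp_contra, pamp_ipsi) {
  s <- pamp_contra + pamp_ipsi
  if (any(s == 0)) stop("zero sum: laterality index undefined")
  (pamp_contra - pamp_ipsi) / s
}

#' Contralateral / ipsilateral channel mapping
#'
#' Standard M1 somatotopy: the hemisphere contralateral to the moving hand
#' carries the movement-related response, so right-hand movement maps to
#' C3 (left hemisphere) as contralateral and C4 as ipsilateral, and vice
#' versa.
#'
#' @param hand `"left"` or `"right"`
#' @return named character vector `c(contra = ..., ipsi = ...)`
#' @export
contralateral_map <- function(hand) {
  switch(hand,
    right = c(contra = "C3", ipsi = "C4"),
    left = c(contra = "C4", ipsi = "C3"),
    stop("unknown hand: ", hand)
  )
}

#' Per-block response metrics for one channel/band
#'
#' Runs [amp_extrema()], [amp_resp()] and [pamp_resp()] on each block-
#' averaged response.
#'
#' @param responses list of `event_related_response` from [block_average()]
#' @param pre_window,post_window extremum search windows, seconds
#' @param denominator `"midpoint"` (the canonical
#'   `(amp_max + amp_min) / 2`) or `"time_mean"` (mean of the averaged
#'   response over its full time axis)
#' @return tibble with one row per block: `block`, `channel`, `band`,
#'   `amp_min`, `amp_max`, `amp_resp`, `pamp_resp`
#' @export
response_metrics <- function(responses, pre_window = c(-1.5, 0),
                             post_window = c(0, 2),
                             denominator = c("midpoint", "time_mean")) {
  stopifnot(length(responses) >= 1)
  denominator <- match.arg(denominator)
  rows <- lapply(responses, function(r) {
    ex <- amp_extrema(r, pre_window, post_window)
    ar <- amp_resp(ex$amp_min, ex$amp_max)
    pa <- if (denominator == "midpoint")
      pamp_resp(ex$amp_min, ex$amp_max)
    else 100 * ar / mean(r$values)
    tibble::tibble(
      block = r$block, channel = r$channel, band = r$band,
      amp_min = ex$amp_min, amp_max = ex$amp_max,
      amp_resp = ar, pamp_resp = pa)
  })
  do.call(rbind, rows)
}

#' Mean and standard deviation across blocks
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator; 0 for
#' a single block) of the per-block metrics, per channel and band.
#'
#' @param metrics tibble from [response_metrics()], possibly covering
#'   several channels/bands
#' @return tibble with `channel`, `band`, `n_blocks`, and mean/sd columns
#'   for `amp_resp` and `pamp_resp`
#' @export
aggregate_blocks <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0) stop("empty metrics")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  parts <- split(metrics, interaction(metrics$channel, metrics$band,
                                      drop = TRUE))
  do.call(rbind, lapply(parts, function(m) tibble::tibble(
    channel = m$channel[1], band = m$band[1], n_blocks = nrow(m),
    amp_resp_mean = mean(m$amp_resp), amp_resp_sd = sd0(m$amp_resp),
    pamp_resp_mean = mean(m$pamp_resp), pamp_resp_sd = sd0(m$pamp_resp))))
}
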