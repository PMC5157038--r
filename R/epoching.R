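#' Inter-movement durations
#'
#' Realized onset-to-onset durations: `duration[k] = t_k - t_{k-1}`. The
#' first movement of a run has no predecessor and gets `NA`; the same
#' applies to the first movement after each rest (sub-session break).
#'
#' @param triggers sorted movement-onset times, seconds
#' @param breaks optional sub-session boundary times in seconds; a trigger
#'   whose predecessor lies before a boundary has undefined duration
#' @return numeric vector of durations with `NA` marking undefined entries
#' @export
inter_movement_durations <- function(triggers, breaks = numeric(0)) {
  if (is.unsorted(triggers, strictly = TRUE))
    stop("triggers must be sorted strictly increasing")
  n <- length(triggers)
  if (n == 0L) return(numeric(0))
  imd <- c(NA_real_, diff(triggers))
  if (length(breaks) && n > 1L) {
    for (b in breaks) {
      crossed <- which(triggers[-1] > b & triggers[-n] <= b) + 1L
      imd[crossed] <- NA_real_
    }
  }
  imd
}

#' Segment a band-limited envelope around movement onsets
#'
#' Cuts one epoch per trigger over the half-open window
#' `[start, end)` seconds relative to the onset (default `[-1.5, 2)`, wide
#' enough for both the pre-onset minimum and post-onset maximum searches).
#' Triggers whose full window does not fit inside the recording are flagged
#' `rejected_edge`. The peak absolute EOG amplitude within the same window
#' is stored per epoch for the artifact rule.
#'
#' @param env an `envelope_signal` from [compute_envelope()]
#' @param eog EOG time series (microvolts), same length/fs as the envelope;
#'   `NULL` disables the artifact measure (peaks set to 0)
#' @param triggers movement-onset times in seconds
#' @param window `c(start, end)` seconds relative to onset, `start < 0 < end`
#' @param breaks optional sub-session boundaries (see
#'   [inter_movement_durations()])
#' @return an `epoch_set`: list with `epochs` (triggers x samples matrix,
#'   `NA` rows for edge rejections), `time` (relative axis, seconds), `fs`,
#'   `imd`, `eog_peak`, `flags` (factor: retained / rejected_artifact /
#'   rejected_timing / rejected_first / rejected_edge; all non-edge epochs
#'   start as `retained` until [apply_retention()]), `band`, `channel`,
#'   `method`
#' @export
segment_epochs <- function(env, eog, triggers, window = c(-1.5, 2),
                           breaks = numeric(0)) {
  stopifnot(inherits(env, "envelope_signal"))
  if (!(window[1] < 0 && window[2] > 0))
    stop("window must straddle the onset: start < 0 < end")
  fs <- env$fs
  x <- env$values
  n <- length(x)
  if (!is.null(eog) && length(eog) != n)
    stop("EOG length must match the envelope")
  nsamp <- as.integer(round((window[2] - window[1]) * fs))
  offs <- as.integer(round(window[1] * fs)) + seq_len(nsamp) - 1L
  k <- length(triggers)
  if (k == 0L) stop("no triggers")

  epochs <- matrix(NA_real_, k, nsamp)
  eog_peak <- rep(NA_real_, k)
  flags <- rep("retained", k)
  for (i in seq_len(k)) {
    idx <- as.integer(round(triggers[i] * fs)) + 1L + offs
    if (idx[1] < 1L || idx[nsamp] > n) {
      flags[i] <- "rejected_edge"
      next
    }
    epochs[i, ] <- x[idx]
    eog_peak[i] <- if (is.null(eog)) 0 else max(abs(eog[idx]))
  }
  if (all(flags == "rejected_edge"))
    stop("no triggers inside bounds")

  structure(
    list(epochs = epochs, time = offs / fs, fs = fs, window = window,
         triggers = triggers,
         imd = inter_movement_durations(triggers, breaks),
         eog_peak = eog_peak,
         flags = factor(flags, levels = epoch_flag_levels()),
         band = env$band, channel = env$channel, method = env$method,
         retention = NULL),
    class = "epoch_set"
  )
}

epoch_flag_levels <- function() {
  c("retained", "rejected_artifact", "rejected_timing", "rejected_first",
    "rejected_edge")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s %s: %d epochs x %d samples @ %g Hz\n",
              x$channel, x$band, nrow(x$epochs), ncol(x$epochs), x$fs))
  print(table(x$flags))
  invisible(x)
}

#' Apply the artifact and timing retention rules
#'
#' An epoch is retained only if it is artifact-free (peak absolute EOG below
#' `eog_threshold`, strict) and its realized inter-movement duration is
#' close to the designated interval (absolute deviation below
#' `deviation_threshold`, strict). Epochs with undefined duration (first of
#' a run or sub-session) are flagged `rejected_first`; edge rejections are
#' left untouched. The artifact rule takes precedence over the timing rule
#' when both fail.
#'
#' @param es an `epoch_set` from [segment_epochs()]
#' @param designated_imi designated inter-movement interval, seconds
#' @param deviation_threshold maximum timing deviation, seconds (default
#'   0.5)
#' @param eog_threshold EOG artifact threshold, microvolts (default 300)
#' @param eog_criterion `"peak"` (max absolute amplitude, default) or
#'   `"peak_to_peak"`
#' @return the `epoch_set` with updated `flags` and a `retention` summary
#'   list (counts per flag, thresholds used, retention rate)
#' @export
apply_retention <- function(es, designated_imi, deviation_threshold = 0.5,
                            eog_threshold = 300,
                            eog_criterion = c("peak", "peak_to_peak")) {
  stopifnot(inherits(es, "epoch_set"), designated_imi > 0)
  eog_criterion <- match.arg(eog_criterion)
  flags <- as.character(es$flags)
  eogv <- es$eog_peak
  if (eog_criterion == "peak_to_peak") eogv <- 2 * eogv
  for (i in seq_along(flags)) {
    if (flags[i] == "rejected_edge") next
    if (is.na(es$imd[i])) {
      flags[i] <- "rejected_first"
    } else if (!is.na(eogv[i]) && eogv[i] >= eog_threshold) {
      flags[i] <- "rejected_artifact"
    } else if (abs(es$imd[i] - designated_imi) >= deviation_threshold) {
      flags[i] <- "rejected_timing"
    } else {
      flags[i] <- "retained"
    }
  }
  es$flags <- factor(flags, levels = epoch_flag_levels())
  counts <- table(es$flags)
  es$retention <- list(
    counts = counts,
    designated_imi = designated_imi,
    deviation_threshold = deviation_threshold,
    eog_threshold = eog_threshold,
    eog_criterion = eog_criterion,
    rate = retention_rate_from_counts(counts)
  )
  es
}

retention_rate_from_counts <- function(counts) {
  eligible <- counts[["retained"]] + counts[["rejected_timing"]] +
    counts[["rejected_artifact"]]
  if (eligible == 0) return(NA_real_)
  100 * counts[["retained"]] / eligible
}

#' Epoch retention rate
#'
#' Percentage of eligible epochs surviving the artifact and timing filters:
#' `100 * retained / (retained + rejected_timing + rejected_artifact)`.
#' First-of-run and edge rejections are excluded from the denominator since
#' they say nothing about timing or artifact compliance.
#'
#' @param es an `epoch_set` after [apply_retention()]
#' @return retention rate in percent
#' @export
retention_rate <- function(es) {
  if (is.null(es$retention)) stop("apply_retention() first")
  rate <- es$retention$rate
  if (is.na(rate)) stop("no eligible epochs in the denominator")
  rate
}

#' Average retained epochs in consecutive blocks
#'
#' Retained epochs, in chronological order, are partitioned into
#' non-overlapping blocks of `block_size` (default 60, the canonical block)
#' and averaged pointwise; the remainder short of a full block is discarded
#' with a warning.
#'
#' @param es an `epoch_set` after [apply_retention()]
#' @param block_size epochs per block
#' @param min_blocks minimum number of full blocks required
#' @return list of `event_related_response` objects (fields `time`,
#'   `values`, `block_size`, `block`, `band`, `channel`, `n_discarded`)
#' @export
block_average <- function(es, block_size = 60, min_blocks = 1) {
  stopifnot(inherits(es, "epoch_set"), block_size >= 1)
  keep <- which(es$flags == "retained")
  n_blocks <- length(keep) %/% block_size
  if (n_blocks < min_blocks)
    stop(sprintf("insufficient retained epochs: %d retained, need %d",
                 length(keep), block_size * min_blocks))
  n_left <- length(keep) - n_blocks * block_size
  if (n_left > 0)
    warning(sprintf("%d retained epochs short of a full block discarded",
                    n_left))
  lapply(seq_len(n_blocks), function(b) {
    rows <- keep[seq((b - 1) * block_size + 1, b * block_size)]
    structure(
      list(time = es$time,
           values = colMeans(es$epochs[rows, , drop = FALSE]),
           block_size = block_size, block = b,
           band = es$band, channel = es$channel, n_discarded = n_left),
      class = "event_related_response")
  })
}

#' @export
print.event_related_response <- function(x, ...) {
  cat(sprintf(
    "<event_related_response> %s %s, block %d (n = %d), t in [%.2f, %.2f] s\n",
    x$channel, x$band, x$block, x$block_size, min(x$time), max(x$time)))
  invisible(x)
}
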