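#' Continuous multichannel EEG recording with movement-onset triggers
#'
#' A `recording` bundles the per-channel time series (microvolts), the
#' sampling rate, movement-onset trigger times, and run metadata. Time is
#' measured in seconds with t = 0 at the first sample; all windows used
#' downstream are half-open `[start, end)`.
#'
#' @param data numeric matrix (samples x channels) or a named list of
#'   equal-length numeric vectors, in microvolts.
#' @param fs sampling rate in Hz, a single positive number.
#' @param channels character vector of channel labels (e.g. `"C3"`, `"C4"`,
#'   `"EOG"`); required when `data` is an unnamed matrix.
#' @param triggers numeric vector of movement-onset times in seconds from
#'   recording start, strictly increasing, inside `[0, duration]`.
#' @param meta named list of run metadata. Recognized fields: `subject`,
#'   `hand` (`"left"`/`"right"`), `hand_status`
#'   (`"healthy"`/`"paretic"`/`"non_paretic"`), `imi` (designated
#'   inter-movement interval in seconds), `session`.
#'
#' @return An object of class `recording`: a list with elements `data`
#'   (samples x channels matrix with column names), `fs`, `channels`,
#'   `triggers`, `meta`.
#' @export
#' @examples
#' x <- matrix(rnorm(3000), ncol = 3)
#' rec <- recording(x, fs = 1000, channels = c("C3", "C4", "EOG"),
#'                  triggers = c(0.5, 1.5, 2.5), meta = list(imi = 1))
#' duration(rec)
recording <- function(data, fs, channels = NULL, triggers = numeric(0),
                      meta = list()) {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(channels)) channels <- names(data)
    lens <- lengths(data)
    if (length(unique(lens)) != 1L)
      stop("all channels must share one length")
    data <- do.call(cbind, lapply(data, as.numeric))
  }
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) channels <- colnames(data)
  if (is.null(channels) || length(channels) != ncol(data))
    stop("channel labels must be given, one per data column")
  if (nrow(data) == 0L) stop("empty recording")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  colnames(data) <- channels
  triggers <- as.numeric(triggers)
  if (any(is.na(triggers))) stop("triggers must be finite")
  if (is.unsorted(triggers, strictly = TRUE))
    stop("triggers must be strictly increasing")
  dur <- nrow(data) / fs
  if (length(triggers) && (min(triggers) < 0 || max(triggers) > dur))
    stop("triggers must lie within [0, duration]")
  structure(
    list(data = data, fs = as.numeric(fs), channels = channels,
         triggers = triggers, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels (%s), fs = %g Hz, %.1f s, %d triggers\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              x$fs, duration(x), length(x$triggers)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [recording()]
#' @return duration in seconds (`n_samples / fs`)
#' @export
duration <- function(rec) nrow(rec$data) / rec$fs

#' Extract one channel by label (case-insensitive)
#'
#' Label lookup ignores case but the stored labels keep their original
#' spelling.
#'
#' @param rec a [recording()]
#' @param channel channel label
#' @return numeric vector of samples in microvolts
#' @export
get_channel <- function(rec, channel) {
  idx <- match(tolower(channel), tolower(rec$channels))
  if (is.na(idx)) stop("unknown channel: ", channel)
  rec$data[, idx]
}

#' Bipolar EOG derivation
#'
#' The vertical/oblique electro-oculogram is recorded from one electrode
#' above the left eye (EOG+) and one at the outer right canthus (EOG-);
#' the bipolar trace is their elementwise difference.
#'
#' @param above EOG+ time series in microvolts
#' @param canthus EOG- time series in microvolts
#' @return `above - canthus`
#' @export
bipolar_eog <- function(above, canthus) {
  if (length(above) != length(canthus))
    stop("EOG channel length mismatch")
  above - canthus
}
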