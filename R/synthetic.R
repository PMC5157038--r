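#' Modulation parameters for one channel/band
#'
#' Describes the event-related amplitude modulation of a narrow-band
#' mu-rhythm carrier as a multiplicative gain on its envelope: a Gaussian
#' suppression bump (event-related desynchronization, ERD) around each
#' movement onset and a Gaussian rebound bump (event-related
#' synchronization, ERS) after it. Defaults place the suppression at the
#' onset and the rebound 0.85 s later, consistent with pre-movement
#' desynchronization that builds up over the final ~1.5 s and a rebound
#' 0.7--1 s after movement.
#'
#' @param band `"alpha"` or `"beta"`
#' @param A_base baseline envelope amplitude, microvolts
#' @param d ERD depth, fractional suppression in `[0, 1)`
#' @param r rebound gain, fractional enhancement `>= 0`
#' @param t_erd,sigma_erd center (s, relative to onset) and width of the
#'   suppression bump
#' @param t_ers,sigma_ers center and width of the rebound bump
#' @param lat laterality factor in `[0, 1]` scaling `(d, r)` on the
#'   ipsilateral channel; 1 = symmetric hemispheres
#' @return a `modulation_params` list
#' @export
modulation_params <- function(band = "alpha", A_base = 15, d = 0.4, r = 0.2,
                              t_erd = 0, sigma_erd = 0.3,
                              t_ers = 0.85, sigma_ers = 0.35, lat = 1) {
  stopifnot(band %in% c("alpha", "beta"), A_base > 0,
            d >= 0, d < 1, r >= 0, sigma_erd > 0, sigma_ers > 0,
            lat >= 0, lat <= 1)
  structure(list(band = band, A_base = A_base, d = d, r = r,
                 t_erd = t_erd, sigma_erd = sigma_erd,
                 t_ers = t_ers, sigma_ers = sigma_ers, lat = lat),
            class = "modulation_params")
}

#' Analytic amplitude-response percentage implied by modulation parameters
#'
#' For well-separated suppression and rebound bumps the averaged envelope
#' attains minimum `A_base (1 - d)` and maximum `A_base (1 + r)`, so the
#' normalized amplitude response is
#' `100 * ((1+r) - (1-d)) / (((1+r) + (1-d)) / 2) = 200 (d + r) / (2 + r - d)`,
#' independent of `A_base`.
#'
#' @param d ERD depth
#' @param r rebound gain
#' @return expected PAmp_resp in percent
#' @export
pamp_closed_form <- function(d, r) 200 * (d + r) / (2 + r - d)

#' Simulate movement-onset trigger times
#'
#' Successive inter-movement durations are `imi` plus Gaussian jitter; a
#' fraction `outlier_rate` of them is additionally shifted by
#' `+/- outlier_shift` (random sign) to emulate mistimed movements that the
#' retention filter must reject. Durations are clamped below at 0.2 s.
#'
#' @param imi designated inter-movement interval, seconds (> 0)
#' @param jitter_sd standard deviation of the timing jitter, seconds
#' @param n number of movements (>= 2)
#' @param outlier_rate probability that a duration is an outlier
#' @param outlier_shift absolute shift applied to outlier durations, seconds
#' @param t0 time of the first movement, seconds
#' @param seed optional integer seed (scoped; does not disturb the session
#'   RNG)
#' @return strictly increasing vector of `n` onset times in seconds
#' @export
simulate_triggers <- function(imi, jitter_sd = 0, n = 10, outlier_rate = 0,
                              outlier_shift = 0, t0 = 3, seed = NULL) {
  stopifnot(imi > 0, n >= 2, jitter_sd >= 0, outlier_rate >= 0,
            outlier_rate <= 1)
  gen <- function() {
    diffs <- imi + stats::rnorm(n - 1, 0, jitter_sd)
    if (outlier_rate > 0) {
      is_out <- stats::runif(n - 1) < outlier_rate
      signs <- sample(c(-1, 1), n - 1, replace = TRUE)
      diffs[is_out] <- diffs[is_out] + signs[is_out] * outlier_shift
    }
    pmax(diffs, 0.2)
  }
  diffs <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  t <- t0 + cumsum(c(0, diffs))
  if (is.unsorted(t, strictly = TRUE))
    stop("parameters produce non-increasing trigger times")
  t
}

# pink (1/f amplitude) noise by spectral shaping of white Gaussian noise
pink_noise <- function(n, sd = 1) {
  if (n < 2L) return(stats::rnorm(n, 0, sd))
  m <- stats::nextn(n, c(2L, 3L, 5L))   # keep the FFT O(n log n)
  w <- stats::fft(stats::rnorm(m))
  k <- seq_len(m) - 1L
  f <- pmin(k, m - k)          # symmetric |frequency| index
  amp <- 1 / sqrt(pmax(f, 1))
  amp[1] <- 0                  # no DC
  x <- Re(stats::fft(w * amp, inverse = TRUE) / m)[seq_len(n)]
  x * sd / stats::sd(x)
}

#' Simulate a unit-envelope narrow-band mu-rhythm carrier
#'
#' Constant-envelope frequency-modulated synthesis: the instantaneous
#' frequency performs a slow bounded random walk inside the band
#' (`f_c +/- 0.5 x half-bandwidth`, smoothed over ~0.5 s), and the carrier
#' is the cosine of the accumulated phase. The Hilbert envelope is
#' therefore ~1 everywhere, so all event-related amplitude structure in a
#' simulated recording comes from the modulation gain. `pure_tone = TRUE`
#' gives a plain sinusoid at the band center (10 Hz for alpha) instead.
#'
#' @param band `"alpha"` or `"beta"` (or numeric `c(low, high)` Hz)
#' @param fs sampling rate, must be at least 4x the band's upper edge
#' @param duration_s length in seconds
#' @param pure_tone emit `sin(2 pi f0 t)` at the band center instead of
#'   frequency-modulated noise
#' @param seed optional integer seed (scoped)
#' @return zero-mean numeric vector of `round(duration_s * fs)` samples
#'   with >= 90% of spectral power inside the band and long-run
#'   Hilbert-envelope mean 1
#' @export
simulate_mu_carrier <- function(band = "alpha", fs = 1000, duration_s = 10,
                                pure_tone = FALSE, seed = NULL) {
  edges <- if (is.character(band)) mu_bands()[[band]] else as.numeric(band)
  if (is.null(edges)) stop("unknown band: ", band)
  if (fs < 4 * edges[2])
    stop("fs too low: need fs >= 4x the band upper edge")
  n <- as.integer(round(duration_s * fs))
  if (pure_tone) {
    f0 <- mean(edges)
    if (is.character(band) && identical(band, "alpha")) f0 <- 10
    return(sin(2 * pi * f0 * seq_len(n) / fs))
  }
  f_c <- mean(edges)
  dev <- 0.5 * (edges[2] - edges[1]) / 2
  gen <- function() {
    u <- moving_average(stats::rnorm(n + 1L), fs, 0.5)
    u <- u / max(stats::sd(u), 1e-12)
    f_inst <- f_c + dev * tanh(u)
    phase <- 2 * pi * cumsum(f_inst) / fs + stats::runif(1, 0, 2 * pi)
    x <- cos(phase[seq_len(n)])
    x / mean(hilbert_envelope(x))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Event-related multiplicative envelope gain
#'
#' `g(t) = 1 - d * sum_k exp(-(t - t_k - t_erd)^2 / (2 sigma_erd^2))
#'          + r * sum_k exp(-(t - t_k - t_ers)^2 / (2 sigma_ers^2))`,
#' clipped below at 0.05 so the envelope stays positive. Each Gaussian is
#' evaluated on a +/- 6 sigma support.
#'
#' @param params a [modulation_params()]
#' @param triggers movement-onset times, seconds
#' @param t time axis, seconds
#' @return gain trace, same length as `t`
#' @export
modulation_gain <- function(params, triggers, t) {
  g <- rep(1, length(t))
  dt <- if (length(t) > 1L) t[2] - t[1] else 1
  add_bump <- function(g, center, sigma, coef) {
    i0 <- max(1L, findInterval(center - 6 * sigma, t))
    i1 <- min(length(t), findInterval(center + 6 * sigma, t) + 1L)
    if (i1 < i0) return(g)
    idx <- i0:i1
    g[idx] <- g[idx] + coef * exp(-(t[idx] - center)^2 / (2 * sigma^2))
    g
  }
  for (tk in triggers) {
    if (params$d > 0)
      g <- add_bump(g, tk + params$t_erd, params$sigma_erd, -params$d)
    if (params$r > 0)
      g <- add_bump(g, tk + params$t_ers, params$sigma_ers, params$r)
  }
  pmax(g, 0.05)
}

# ipsilateral variant of modulation params: (d, r) scaled by lat
scale_lat <- function(p) {
  q <- p
  q$d <- p$d * p$lat
  q$r <- p$r * p$lat
  q
}

#' Scenario configuration for [simulate_recording()]
#'
#' Collects every knob of one synthetic run. Defaults emulate a healthy
#' subject moving at a moderate rate: alpha carrier 15 uV and beta 6 uV
#' baseline envelope, pink background noise of 5 uV, blinks at 0.1 / s with
#' 200 uV peak, 1 kHz sampling.
#'
#' @param imi designated inter-movement interval, seconds
#' @param n_triggers number of movements
#' @param fs sampling rate, Hz
#' @param hand `"left"` or `"right"` moving hand (contralateral channel is
#'   C4 resp. C3)
#' @param alpha,beta [modulation_params()] for the contralateral channel;
#'   the ipsilateral channel uses `(d, r)` scaled by their `lat` factor
#' @param jitter_sd timing jitter sd, seconds
#' @param outlier_rate,outlier_shift mistimed-movement contamination passed
#'   to [simulate_triggers()]
#' @param noise_sd pink-noise sd on C3/C4, microvolts
#' @param line_amp amplitude of an optional 60 Hz mains tone, microvolts
#' @param blink_rate Poisson blink rate on the EOG channel, events per
#'   second
#' @param blink_amp blink peak amplitude, microvolts
#' @param hand_status `"healthy"`, `"paretic"` or `"non_paretic"`
#' @param subject subject identifier
#' @return a `scenario` list
#' @export
scenario <- function(imi = 2, n_triggers = 80, fs = 1000, hand = "right",
                     alpha = modulation_params("alpha", A_base = 15),
                     beta = modulation_params("beta", A_base = 6),
                     jitter_sd = 0.05, outlier_rate = 0, outlier_shift = 0,
                     noise_sd = 5, line_amp = 0,
                     blink_rate = 0.1, blink_amp = 200,
                     hand_status = "healthy", subject = "S01") {
  stopifnot(hand %in% c("left", "right"))
  structure(list(imi = imi, n_triggers = n_triggers, fs = fs, hand = hand,
                 alpha = alpha, beta = beta, jitter_sd = jitter_sd,
                 outlier_rate = outlier_rate, outlier_shift = outlier_shift,
                 noise_sd = noise_sd, line_amp = line_amp,
                 blink_rate = blink_rate, blink_amp = blink_amp,
                 hand_status = hand_status, subject = subject),
            class = "scenario")
}

# blink waveform: difference of two centered Gaussians, peak normalized to 1
blink_waveform <- function(fs, width_s = 0.25) {
  tt <- seq(-2 * width_s, 2 * width_s, by = 1 / fs)
  w <- exp(-tt^2 / (2 * (width_s / 3)^2)) -
    0.6 * exp(-tt^2 / (2 * (width_s / 1.5)^2))
  w / max(abs(w))
}

# expected PAmp_resp (%) from the realized gain trace, mirroring the
# pipeline's epoching: mean gain profile over in-bounds triggers, extrema in
# the pre/post search windows
expected_pamp_from_gain <- function(g, fs, triggers, n_total,
                                    window = c(-1.5, 2),
                                    pre = c(-1.5, 0), post = c(0, 2)) {
  nsamp <- as.integer(round((window[2] - window[1]) * fs))
  offs <- as.integer(round(window[1] * fs)) + seq_len(nsamp) - 1L
  rel_t <- offs / fs
  prof <- numeric(nsamp); k <- 0L
  for (tk in triggers) {
    idx <- as.integer(round(tk * fs)) + 1L + offs
    if (idx[1] < 1L || idx[nsamp] > n_total) next
    prof <- prof + g[idx]; k <- k + 1L
  }
  if (k == 0L) return(NA_real_)
  prof <- prof / k
  amin <- min(prof[rel_t >= pre[1] & rel_t < pre[2]])
  amax <- max(prof[rel_t >= post[1] & rel_t < post[2]])
  100 * (amax - amin) / ((amax + amin) / 2)
}

#' Simulate one synthetic EEG recording with ground truth
#'
#' Builds C3/C4 as the sum over bands of `A_base * g(t) * carrier(t)` plus
#' pink noise (and an optional 60 Hz tone), and a bipolar EOG channel
#' carrying Poisson blink deflections. The contralateral channel (relative
#' to the moving hand) uses the scenario's modulation parameters; the
#' ipsilateral channel uses `(d, r)` scaled by the `lat` factor. The
#' returned ground truth holds, per channel and band, the expected
#' PAmp_resp computed numerically from the realized gain trace through the
#' same epoch-averaging geometry as the analysis pipeline (this agrees with
#' [pamp_closed_form()] when the suppression and rebound bumps of
#' neighbouring movements do not overlap), and the implied laterality
#' index.
#'
#' @param sc a [scenario()]
#' @param seed integer seed; identical `(sc, seed)` give bit-identical
#'   output
#' @return list with elements `recording` (a [recording()] with channels
#'   C3, C4, EOG) and `truth` (params, per-channel/band expected PAmp_resp,
#'   expected LI per band)
#' @export
simulate_recording <- function(sc, seed = 1) {
  stopifnot(inherits(sc, "scenario"))
  withr::with_seed(seed, {
    triggers <- simulate_triggers(sc$imi, sc$jitter_sd, sc$n_triggers,
                                  sc$outlier_rate, sc$outlier_shift, t0 = 3)
    dur <- max(triggers) + 3
    n <- as.integer(round(dur * sc$fs))
    t <- (seq_len(n) - 1L) / sc$fs

    map <- contralateral_map(sc$hand)
    chans <- c("C3", "C4", "EOG")
    data <- matrix(0, n, 3, dimnames = list(NULL, chans))
    truth_rows <- list()

    for (band in c("alpha", "beta")) {
      p_contra <- sc[[band]]
      p_ipsi <- scale_lat(p_contra)
      for (role in c("contra", "ipsi")) {
        ch <- if (role == "contra") map[["contra"]] else map[["ipsi"]]
        p <- if (role == "contra") p_contra else p_ipsi
        g <- modulation_gain(p, triggers, t)
        carrier <- simulate_mu_carrier(band, sc$fs, dur)
        j <- match(ch, chans)
        data[, j] <- data[, j] + p$A_base * g * carrier
        truth_rows[[paste(band, ch)]] <- tibble::tibble(
          channel = ch, band = band, role = role,
          d = p$d, r = p$r, A_base = p$A_base,
          pamp_expected = expected_pamp_from_gain(g, sc$fs, triggers, n),
          pamp_closed_form = pamp_closed_form(p$d, p$r))
      }
    }

    for (j in 1:2) {
      if (sc$noise_sd > 0)
        data[, j] <- data[, j] + pink_noise(n, sc$noise_sd)
      if (sc$line_amp > 0)
        data[, j] <- data[, j] + sc$line_amp * sin(2 * pi * 60 * t)
    }

    eog <- if (sc$noise_sd > 0) pink_noise(n, min(sc$noise_sd, 5)) else
      numeric(n)
    n_blinks <- stats::rpois(1, sc$blink_rate * dur)
    if (n_blinks > 0 && sc$blink_amp > 0) {
      w <- blink_waveform(sc$fs) * sc$blink_amp
      centers <- sort(stats::runif(n_blinks, 0, dur))
      half <- (length(w) - 1L) %/% 2L
      for (ct in centers) {
        i0 <- as.integer(round(ct * sc$fs)) + 1L - half
        idx <- seq(i0, i0 + length(w) - 1L)
        ok <- idx >= 1L & idx <= n
        eog[idx[ok]] <- eog[idx[ok]] + w[ok]
      }
    }
    data[, 3] <- eog

    truth_tbl <- do.call(rbind, truth_rows)
    li <- do.call(rbind, lapply(split(truth_tbl, truth_tbl$band), function(b) {
      tibble::tibble(
        band = b$band[1],
        li_expected = (b$pamp_expected[b$role == "contra"] -
                         b$pamp_expected[b$role == "ipsi"]) /
          (b$pamp_expected[b$role == "contra"] +
             b$pamp_expected[b$role == "ipsi"]))
    }))

    rec <- recording(data, fs = sc$fs, channels = chans, triggers = triggers,
                     meta = list(subject = sc$subject, hand = sc$hand,
                                 hand_status = sc$hand_status, imi = sc$imi))
    list(recording = rec,
         truth = list(scenario = sc, expected = truth_tbl,
                      expected_li = li, jitter_sd = sc$jitter_sd))
  })
}
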