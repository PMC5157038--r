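test_that("inter-movement durations are first differences with NA first", {
  expect_equal(inter_movement_durations(c(0, 2.1, 4.7, 6.6)),
               c(NA, 2.1, 2.6, 1.9))
  expect_equal(inter_movement_durations(5), NA_real_)
  expect_error(inter_movement_durations(c(2, 1)), "sorted")
  # jitter-free simulated run
  tr <- simulate_triggers(imi = 2, jitter_sd = 0, n = 6, seed = 1)
  expect_equal(inter_movement_durations(tr)[-1], rep(2, 5))
  # sub-session break: first movement after the break is undefined
  imd <- inter_movement_durations(c(1, 3, 5, 65, 67), breaks = 35)
  expect_equal(imd, c(NA, 2, 2, NA, 2))
})

test_that("segmentation yields fixed-size half-open epochs with edge flags", {
  fs <- 1000
  env <- toy_envelope(abs(rnorm(10 * fs)), fs)
  eog <- rnorm(10 * fs, sd = 20)
  trig <- c(0.5, 2, 3, 5, 8.9)
  es <- segment_epochs(env, eog, trig, window = c(-1.5, 2))
  expect_equal(ncol(es$epochs), 3500)
  expect_equal(as.character(es$flags)[c(1, 5)],
               c("rejected_edge", "rejected_edge"))
  expect_false(anyNA(es$epochs[2:4, ]))
  expect_equal(es$time[1], -1.5)
  expect_equal(es$time[3500], 2 - 1 / fs)
  # epoch content is the envelope slice
  i0 <- round(2 * fs) + 1 - 1500
  expect_equal(es$epochs[2, ], env$values[i0:(i0 + 3499)])
  expect_equal(es$eog_peak[2], max(abs(eog[i0:(i0 + 3499)])))

  expect_error(segment_epochs(env, eog, trig, window = c(0.5, 2)),
               "straddle")
  expect_error(segment_epochs(env, eog, c(0.1, 9.99)), "inside bounds")

  # simulator run: all well-inside triggers segment cleanly
  sc <- scenario(imi = 1, n_triggers = 20, fs = 250)
  sim <- simulate_recording(sc, seed = 2)
  env2 <- compute_envelope(sim$recording, "C3", "alpha")
  es2 <- segment_epochs(env2, get_channel(sim$recording, "EOG"),
                        sim$recording$triggers)
  expect_equal(sum(es2$flags == "rejected_edge"), 0)
  expect_equal(nrow(es2$epochs), 20)
})

test_that("retention rules match the brute-force oracle", {
  fs <- 100
  # toy epoch set assembled directly
  imd <- c(NA, 2.1, 2.6, 1.4, 2.0, 2.45)
  eogp <- c(50, 40, 350, 20, 300, 60)
  env <- toy_envelope(abs(rnorm(30 * fs)), fs)
  trig <- cumsum(c(2, ifelse(is.na(imd[-1]), 2, imd[-1])))
  es <- segment_epochs(env, NULL, trig)
  es$imd <- imd
  es$eog_peak <- eogp
  es <- apply_retention(es, designated_imi = 2)
  expect_equal(as.character(es$flags),
               unname(retention_oracle(imd, eogp, imi = 2)))
  # exact boundary: eog == 300 and |dev| == 0.5 are both rejected
  expect_equal(as.character(es$flags)[5], "rejected_artifact")
  expect_equal(as.character(es$flags)[3], "rejected_artifact")
  expect_equal(as.character(es$flags)[4], "rejected_timing")

  # spec-style enumeration: deviations .1,.6,.1,.6,0 with clean EOG
  es2 <- es
  es2$imd <- 2 + c(0.1, 0.6, 0.1, 0.6, 0, NA)
  es2$eog_peak <- rep(0, 6)
  es2 <- apply_retention(es2, 2)
  expect_equal(sum(es2$flags == "retained"), 3)
  expect_equal(retention_rate(es2), 60)
})

test_that("retention rate excludes first/edge epochs from the denominator", {
  fs <- 100
  env <- toy_envelope(abs(rnorm(60 * fs)), fs)
  trig <- seq(2, 50, by = 2)
  es <- segment_epochs(env, NULL, trig)
  es <- apply_retention(es, 2)
  # all defined-duration epochs retained -> 100%
  expect_equal(retention_rate(es), 100)
  expect_equal(sum(es$flags == "rejected_first"), 1)
})

test_that("retention under outlier contamination matches the binomial rate", {
  trig <- simulate_triggers(imi = 2, jitter_sd = 0.05, n = 10000,
                            outlier_rate = 0.2, outlier_shift = 0.8,
                            seed = 31)
  imd <- inter_movement_durations(trig)
  flags <- retention_oracle(imd, rep(0, length(imd)), imi = 2)
  rate <- 100 * sum(flags == "retained") /
    sum(flags %in% c("retained", "rejected_timing", "rejected_artifact"))
  expect_gt(rate, 78)
  expect_lt(rate, 82)
})

test_that("retention flags are monotone in the thresholds and sum correctly", {
  sc <- scenario(imi = 2, n_triggers = 40, fs = 250, jitter_sd = 0.3,
                 blink_rate = 0.3, blink_amp = 320)
  sim <- simulate_recording(sc, seed = 8)
  env <- compute_envelope(sim$recording, "C3", "alpha")
  es <- segment_epochs(env, get_channel(sim$recording, "EOG"),
                       sim$recording$triggers)
  n_ret <- function(dev, eog) {
    sum(apply_retention(es, 2, dev, eog)$flags == "retained")
  }
  base <- n_ret(0.5, 300)
  expect_gte(n_ret(0.8, 300), base)
  expect_gte(n_ret(0.5, 500), base)
  expect_lte(n_ret(0.2, 300), base)
  es2 <- apply_retention(es, 2)
  expect_equal(sum(table(es2$flags)), length(sim$recording$triggers))
})

test_that("block averaging partitions chronologically and reduces variance", {
  fs <- 100
  env <- toy_envelope(abs(rnorm(300 * fs)) + 1, fs)
  trig <- seq(3, 295, by = 2)  # 147 triggers
  es <- segment_epochs(env, NULL, trig)
  es <- apply_retention(es, 2)
  # 146 retained (first rejected): 2 blocks of 60, 26 discarded
  expect_warning(resp <- block_average(es, block_size = 60), "26")
  expect_length(resp, 2)
  expect_equal(resp[[1]]$values,
               colMeans(es$epochs[which(es$flags == "retained")[1:60], ]))
  # identical epochs -> block mean equals the single trace
  es_const <- es
  es_const$epochs <- matrix(rep(es$epochs[2, ], each = nrow(es$epochs)),
                            nrow = nrow(es$epochs))
  resp_c <- suppressWarnings(block_average(es_const, 60))
  expect_equal(resp_c[[1]]$values, es$epochs[2, ])
  # averaging reduces pointwise variance
  keep <- which(es$flags == "retained")[1:60]
  expect_lt(var(resp[[1]]$values), mean(apply(es$epochs[keep, ], 1, var)))
  expect_error(block_average(es, block_size = 200), "insufficient")
})

test_that("averaged simulated response peaks near the modulation bumps", {
  sc <- scenario(imi = 3, n_triggers = 30, fs = 250, jitter_sd = 0,
                 noise_sd = 0.5, blink_rate = 0,
                 alpha = modulation_params("alpha", A_base = 15,
                                           d = 0.5, r = 0.3))
  sim <- simulate_recording(sc, seed = 13)
  env <- compute_envelope(sim$recording, "C3", "alpha")
  es <- apply_retention(
    segment_epochs(env, NULL, sim$recording$triggers), 3)
  resp <- suppressWarnings(block_average(es, block_size = 25))[[1]]
  ex <- amp_extrema(resp)
  expect_lt(abs(ex$t_min - 0), 0.2)     # ERD dip at onset
  expect_lt(abs(ex$t_max - 0.85), 0.25) # rebound at t_ers
})
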