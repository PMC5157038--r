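test_that("trigger simulation matches its statistical contract", {
  # degenerate noise: exact spacing
  t0 <- simulate_triggers(imi = 2, jitter_sd = 0, n = 5, seed = 1)
  expect_equal(diff(t0), rep(2, 4))

  # jitter sd recovered from a long run
  t1 <- simulate_triggers(imi = 3, jitter_sd = 0.1, n = 1000, seed = 11)
  expect_true(all(diff(t1) > 0))
  expect_gt(sd(diff(t1)), 0.08)
  expect_lt(sd(diff(t1)), 0.12)

  # outlier fraction ~ binomial expectation
  t2 <- simulate_triggers(imi = 2, jitter_sd = 0.05, n = 10000,
                          outlier_rate = 0.2, outlier_shift = 0.8,
                          seed = 12)
  frac <- mean(abs(diff(t2) - 2) >= 0.5)
  expect_gt(frac, 0.18)
  expect_lt(frac, 0.22)

  expect_error(simulate_triggers(imi = -1, n = 5))
  expect_error(simulate_triggers(imi = 2, n = 1))
})

test_that("mu carrier is narrow-band with unit mean envelope", {
  power_frac <- function(x, fs, lo, hi) {
    P <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * fs
    keep <- f <= fs / 2
    sum(P[keep & f >= lo & f <= hi]) / sum(P[keep])
  }
  a <- simulate_mu_carrier("alpha", fs = 1000, duration_s = 60, seed = 5)
  expect_gt(power_frac(a, 1000, 8, 14), 0.9)
  expect_equal(mean(hilbert_envelope(a)), 1, tolerance = 1e-9)
  expect_lt(abs(mean(a)), 0.02)

  tone <- simulate_mu_carrier("alpha", fs = 1000, duration_s = 10,
                              pure_tone = TRUE)
  expect_gt(power_frac(tone, 1000, 9.9, 10.1), 0.999)

  # beta carrier has almost no power in the alpha band
  b <- simulate_mu_carrier("beta", fs = 1000, duration_s = 60, seed = 6)
  expect_lt(power_frac(b, 1000, 8, 14), 0.1)

  expect_error(simulate_mu_carrier("beta", fs = 100), "fs too low")
})

test_that("modulation gain has closed-form extrema", {
  t <- seq(0, 20, by = 0.001)
  p0 <- modulation_params("alpha", d = 0, r = 0)
  expect_equal(modulation_gain(p0, c(5, 10), t), rep(1, length(t)))

  p1 <- modulation_params("alpha", d = 0.4, r = 0, t_erd = 0,
                          sigma_erd = 0.3)
  g1 <- modulation_gain(p1, 10, t)
  expect_equal(min(g1), 0.6, tolerance = 1e-6)
  expect_equal(t[which.min(g1)], 10, tolerance = 1e-3)

  # grid-search oracle on well-separated bumps
  p2 <- modulation_params("alpha", d = 0.4, r = 0.2, t_ers = 3,
                          sigma_ers = 0.3)
  g2 <- modulation_gain(p2, 10, t)
  expect_equal(range(g2), c(0.6, 1.2), tolerance = 1e-4)

  # positivity clip
  p3 <- modulation_params("alpha", d = 0.99, r = 0)
  expect_gte(min(modulation_gain(p3, c(5, 5.1, 5.2), t)), 0.05)
})

test_that("analytic PAmp_resp formula and simulator ground truth agree", {
  expect_equal(pamp_closed_form(0.4, 0.2), 200 * 0.6 / 1.8)
  expect_equal(pamp_closed_form(0, 0), 0)

  # bumps separated well beyond their widths: the numeric ground truth
  # collapses onto the closed form
  sep <- function(band, A) modulation_params(band, A_base = A, d = 0.4,
                                             r = 0.2, sigma_erd = 0.25,
                                             t_ers = 1.2, sigma_ers = 0.25)
  sc <- scenario(imi = 3, n_triggers = 10, fs = 500,
                 alpha = sep("alpha", 15), beta = sep("beta", 6),
                 jitter_sd = 0, noise_sd = 0, blink_rate = 0)
  sim <- simulate_recording(sc, seed = 3)
  expect_equal(sim$truth$expected$pamp_expected,
               sim$truth$expected$pamp_closed_form, tolerance = 0.02)
  # default bump placement overlaps mildly: ground truth a little below
  sc2 <- scenario(imi = 3, n_triggers = 10, fs = 500, jitter_sd = 0,
                  noise_sd = 0, blink_rate = 0,
                  alpha = modulation_params("alpha", d = 0.4, r = 0.2))
  sim2 <- simulate_recording(sc2, seed = 3)
  ex2 <- sim2$truth$expected[sim2$truth$expected$band == "alpha", ]
  expect_lt(max(abs(ex2$pamp_expected - ex2$pamp_closed_form)), 4)
  # symmetric hemispheres -> expected LI = 0
  expect_equal(sim$truth$expected_li$li_expected, c(0, 0))
})

test_that("noise-free unmodulated recording has a flat envelope", {
  sc <- scenario(imi = 2, n_triggers = 8, fs = 500,
                 alpha = modulation_params("alpha", A_base = 15,
                                           d = 0, r = 0),
                 beta = modulation_params("beta", A_base = 0.001,
                                          d = 0, r = 0),
                 jitter_sd = 0, noise_sd = 0, blink_rate = 0)
  sim <- simulate_recording(sc, seed = 9)
  env <- compute_envelope(sim$recording, "C3", "alpha",
                          method = "hilbert_am")
  interior <- seq(2 * 500, length(env$values) - 2 * 500)
  expect_equal(mean(env$values[interior]), 15, tolerance = 0.15 * 15)
  cv <- sd(env$values[interior]) / mean(env$values[interior])
  expect_lt(cv, 0.1)
})

test_that("simulation is bit-identical under a fixed seed", {
  sc <- scenario(imi = 2, n_triggers = 6, fs = 250)
  a <- simulate_recording(sc, seed = 21)
  b <- simulate_recording(sc, seed = 21)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$recording$triggers, b$recording$triggers)
  expect_identical(a$truth$expected, b$truth$expected)
  c_ <- simulate_recording(sc, seed = 22)
  expect_false(identical(a$recording$data, c_$recording$data))
})

test_that("simulated envelope gain stays positive", {
  sc <- scenario(imi = 1, n_triggers = 30, fs = 250,
                 alpha = modulation_params("alpha", d = 0.8, r = 0.6))
  sim <- simulate_recording(sc, seed = 4)
  t <- (seq_len(nrow(sim$recording$data)) - 1) / 250
  g <- modulation_gain(sc$alpha, sim$recording$triggers, t)
  expect_true(all(g > 0))
})
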