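test_that("recording constructor enforces its invariants", {
  x <- matrix(0, 10, 2)
  expect_error(recording(x, fs = 1000), "channel labels")
  expect_error(recording(x, fs = 0, channels = c("C3", "C4")), "positive")
  expect_error(recording(x, fs = 1000, channels = c("C3", "C4"),
                         triggers = c(0.5, 0.2)), "increasing")
  expect_error(recording(x, fs = 1000, channels = c("C3", "C4"),
                         triggers = 5), "within")
  expect_error(recording(matrix(0, 0, 2), fs = 1000,
                         channels = c("C3", "C4")), "empty")
  rec <- recording(x, fs = 1000, channels = c("C3", "C4"))
  expect_equal(duration(rec), 0.01)
})

test_that("channel lookup is case-insensitive but label-preserving", {
  rec <- make_test_recording()
  expect_identical(get_channel(rec, "c3"), get_channel(rec, "C3"))
  expect_identical(rec$channels, c("C3", "C4", "EOG"))
  expect_error(get_channel(rec, "Cz"), "unknown channel")
})

test_that("bipolar EOG is the elementwise difference", {
  expect_equal(bipolar_eog(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(bipolar_eog(rep(200, 5), rep(50, 5)), rep(150, 5))
  expect_error(bipolar_eog(1:3, 1:4), "mismatch")
  # simulator blink on EOG+ passes through unchanged when EOG- is flat
  blink <- 350 * muresp:::blink_waveform(1000)
  expect_equal(max(bipolar_eog(blink, numeric(length(blink)))), 350)
})

test_that("BrainVision round-trip preserves the recording", {
  rec <- make_test_recording()
  dir <- withr::local_tempdir()
  save_recording(rec, file.path(dir, "run1.vhdr"), "brainvision")
  back <- load_recording(file.path(dir, "run1.vhdr"))
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channels, rec$channels)
  expect_equal(back$triggers, rec$triggers, tolerance = 1 / rec$fs)
  # float32 storage: relative precision ~1e-7
  expect_equal(back$data, rec$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$meta$imi, rec$meta$imi)
  expect_equal(back$meta$hand, rec$meta$hand)
})

test_that("EDF round-trip preserves values to format quantization", {
  rec <- make_test_recording()
  dir <- withr::local_tempdir()
  save_recording(rec, file.path(dir, "run1.edf"), "edf")
  back <- load_recording(file.path(dir, "run1.edf"))
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channels, rec$channels)
  expect_equal(back$triggers, rec$triggers, tolerance = 1e-6)
  # 16-bit quantization: step = phys_range / 65534
  for (ch in rec$channels) {
    step <- 2 * max(abs(get_channel(rec, ch))) / 65534
    expect_lt(max(abs(get_channel(back, ch) - get_channel(rec, ch))),
              1.01 * step)
  }
  expect_equal(back$meta$hand, "right")
})

test_that("EDF of a non-whole-second recording round-trips", {
  rec <- make_test_recording(fs = 500, dur = 2.5, triggers = c(0.4, 1.1))
  dir <- withr::local_tempdir()
  save_recording(rec, file.path(dir, "odd.edf"), "edf")
  back <- load_recording(file.path(dir, "odd.edf"))
  expect_identical(nrow(back$data), nrow(rec$data))
  expect_lt(max(abs(back$data - rec$data)), 0.01)
})

test_that("large-amplitude EDF save warns about coarse quantization", {
  x <- matrix(5e5 * sin(2 * pi * 3 * (1:1000) / 1000), ncol = 1)
  rec <- recording(x, fs = 1000, channels = "C3", triggers = 0.5,
                   meta = list(hand = "right", imi = 1))
  dir <- withr::local_tempdir()
  expect_warning(save_recording(rec, file.path(dir, "big.edf"), "edf"),
                 "quantization")
  back <- load_recording(file.path(dir, "big.edf"))
  expect_equal(back$data[, 1], x[, 1], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("trigger sources: sidecar, missing sources, merging", {
  rec <- make_test_recording()
  dir <- withr::local_tempdir()

  # EDF with no sidecar -> no triggers error
  norec <- rec; norec$triggers <- numeric(0)
  files <- save_recording(norec, file.path(dir, "bare.edf"), "edf")
  file.remove(grep("events", files, value = TRUE))
  expect_error(load_recording(file.path(dir, "bare.edf")), "no triggers")

  # explicit sidecar merges with embedded markers
  save_recording(rec, file.path(dir, "m.vhdr"), "brainvision")
  extra <- file.path(dir, "extra.txt")
  writeLines(c("2.0", "0.5"), extra)
  back <- load_recording(file.path(dir, "m.vhdr"), events = extra)
  expect_equal(back$triggers, c(0.5, 1.0, 1.5, 2.0), tolerance = 1e-3)

  expect_error(load_recording(file.path(dir, "nope.vhdr")), "missing file")
  writeLines("x", file.path(dir, "weird.xyz"))
  expect_error(load_recording(file.path(dir, "weird.xyz")),
               "unknown extension")
})

test_that("empty recording cannot be saved", {
  rec <- make_test_recording()
  rec$data <- rec$data[0, , drop = FALSE]
  expect_error(save_recording(rec, tempfile(fileext = ".edf"), "edf"),
               "empty recording")
})

test_that("python mne reads our BrainVision and EDF files identically", {
  py <- Sys.which("python")
  expect_true(nzchar(py))  # part of the pinned toolchain
  rec <- make_test_recording()
  dir <- withr::local_tempdir()
  save_recording(rec, file.path(dir, "x.vhdr"), "brainvision")
  save_recording(rec, file.path(dir, "x.edf"), "edf")
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import mne, numpy as np, sys",
    sprintf("d = %s", shQuote(dir)),
    "bv = mne.io.read_raw_brainvision(d + '/x.vhdr', preload=True, verbose='error')",
    "ed = mne.io.read_raw_edf(d + '/x.edf', preload=True, verbose='error')",
    "ev, _ = mne.events_from_annotations(bv, verbose='error')",
    "print(bv.info['sfreq'], ed.info['sfreq'])",
    "print(','.join(bv.ch_names), ','.join(ed.ch_names))",
    "print(','.join('%d' % s for s in ev[:, 0]))",
    "print(','.join('%.4f' % v for v in bv.get_data(picks=['C3'])[0][:5] * 1e6))",
    "print(','.join('%.4f' % v for v in ed.get_data(picks=['C3'])[0][:5] * 1e6))"
  ), script)
  out <- suppressWarnings(system2(py, script, stdout = TRUE, stderr = FALSE))
  expect_equal(strsplit(out[1], " ")[[1]], c("1000.0", "1000.0"))
  expect_equal(out[2], "C3,C4,EOG C3,C4,EOG")
  expect_equal(as.integer(strsplit(out[3], ",")[[1]]),
               as.integer(round(rec$triggers * rec$fs)))
  ref <- rec$data[1:5, "C3"]
  expect_equal(as.numeric(strsplit(out[4], ",")[[1]]), ref, tolerance = 1e-3)
  expect_equal(as.numeric(strsplit(out[5], ",")[[1]]), ref, tolerance = 1e-2)
})
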