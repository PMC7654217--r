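# A minimal hand-built session: one channel, known windows, optional pulses.
toy_session <- function(x, fs = 2000, stim_events = NULL,
                        attempt = c(2, 3), bg = c(0.5, 1.5)) {
  structure(list(signals = matrix(x, 1, dimnames = list("M1")),
                 fs = fs, channel_names = "M1",
                 stim_events = stim_events,
                 attempt_windows = data.frame(start = attempt[1],
                                              end = attempt[2],
                                              task = "attempt",
                                              bg_start = bg[1],
                                              bg_end = bg[2])),
            class = "emg_session")
}

test_that("band-pass rejects DC and the stopband, passes the band", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  mid <- 1001:3001
  dc <- suppressWarnings(bandpass_filter(rep(1, length(t)), fs))
  expect_lt(max(abs(dc[mid])), 1e-3)
  s100 <- suppressWarnings(bandpass_filter(sin(2 * pi * 100 * t), fs))
  expect_lt(abs(max(abs(s100[mid])) - 1), 0.05)
  s5 <- suppressWarnings(bandpass_filter(sin(2 * pi * 5 * t), fs))
  expect_lt(max(abs(s5[mid])), 0.1)
})

test_that("band-pass clips an upper edge at Nyquist with a warning", {
  expect_warning(bandpass_filter(rnorm(2000), 2000, high = 1000), "Nyquist")
  expect_silent(invisible(bandpass_filter(rnorm(2000), 4000, high = 1000)))
  expect_error(bandpass_filter(c(1, NA, 3), 2000), "non-finite")
})

test_that("RMS amplitude follows its closed forms", {
  expect_equal(rms_amplitude(rep(-3, 100)), 3)
  expect_equal(rms_amplitude(c(3, 4)), sqrt(12.5))
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)  # exactly 10 periods of 10 Hz
  expect_equal(rms_amplitude(2 * sin(2 * pi * 10 * t)), 2 / sqrt(2),
               tolerance = 1e-10)
  expect_error(rms_amplitude(numeric(0)), "empty")
})

test_that("attempt delta-RMS subtracts background and may be negative", {
  fs <- 2000
  n <- 3 * fs
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  x[t >= 0.5 & t < 1.5] <- 0.1 * sqrt(2) * sin(2 * pi * 100 * t[t >= 0.5 & t < 1.5])
  x[t >= 2] <- 0.3 * sqrt(2) * sin(2 * pi * 100 * t[t >= 2])
  s <- toy_session(x)
  expect_equal(attempt_delta_rms(s, "M1"), 0.2, tolerance = 1e-3)
  # suppression: quieter during the attempt than at rest
  x3 <- numeric(n)
  x3[t >= 0.5 & t < 1.5] <- 0.3 * sqrt(2) * sin(2 * pi * 100 * t[t >= 0.5 & t < 1.5])
  x3[t >= 2] <- 0.1 * sqrt(2) * sin(2 * pi * 100 * t[t >= 2])
  expect_equal(attempt_delta_rms(toy_session(x3), "M1"), -0.2,
               tolerance = 1e-3)
  # identical stationary noise in both windows: increment near zero
  set.seed(1)
  xn <- rnorm(n, sd = 0.05)
  expect_lt(abs(attempt_delta_rms(toy_session(xn), "M1")), 0.005)
  # overlapping windows are rejected
  expect_error(attempt_delta_rms(toy_session(x, bg = c(1.5, 2.5)), "M1"),
               "precede")
})

test_that("evoked peak-to-peak is max minus min in the response window", {
  fs <- 2000
  x <- numeric(2 * fs)
  ev <- data.frame(time = 0.5, intensity = 1)
  # biphasic +0.6 / -0.4 at 10 ms latency
  i0 <- round((0.5 + 0.01) * fs)
  x[i0 + 1:4] <- c(0.6, 0.6, -0.4, -0.4)
  s <- toy_session(x, stim_events = ev)
  expect_equal(evoked_peak_peak(s, "M1", 0.5), 1.0)
  expect_equal(evoked_peak_peak(toy_session(numeric(2 * fs),
                                            stim_events = ev), "M1", 0.5), 0)
  # sloped baseline: brute-force max - min over the window samples
  xs <- seq_len(2 * fs) / fs
  s2 <- toy_session(xs * 0.2 + x, stim_events = ev)
  idx <- (floor((0.5 + 0.005) * fs) + 1):ceiling((0.5 + 0.095) * fs)
  seg <- (xs * 0.2 + x)[idx]
  expect_equal(evoked_peak_peak(s2, "M1", 0.5), max(seg) - min(seg))
  # window longer than the inter-stimulus interval is rejected
  ev2 <- data.frame(time = c(0.5, 1.0), intensity = c(1, 1))
  expect_error(evoked_peak_peak(toy_session(x, stim_events = ev2), "M1", 0.5,
                                response_window = c(0.005, 0.6)),
               "inter-stimulus")
})

test_that("recruitment curve groups by intensity and is order-invariant", {
  gen <- make_emg_session(emg_spec(background_sd = 0, seed = 4))
  rc <- recruitment_curve(gen$session, "TA")
  expect_equal(rc$curve$n_stimuli, rep(5L, 8))
  expect_equal(rc$max_p2p, max(rc$curve$mean_p2p))
  # noiseless recovery of the sigmoid within 1% relative
  expect_lt(max(abs(rc$curve$mean_p2p - gen$truth$evoked_p2p[, "TA"]) /
                  gen$truth$evoked_p2p[, "TA"]), 0.01)
  # shuffling the stimulus order leaves the curve unchanged
  s2 <- gen$session
  perm <- sample(nrow(s2$stim_events))
  s2$stim_events <- s2$stim_events[perm, ]
  rc2 <- recruitment_curve(s2, "TA")
  expect_equal(rc2$curve, rc$curve)
  # no stimulation events is an error; missing stimuli warn
  s3 <- gen$session; s3$stim_events <- s3$stim_events[0, ]
  expect_error(recruitment_curve(s3, "TA"), "no stimulation events")
  s4 <- gen$session; s4$stim_events <- s4$stim_events[-1, ]
  expect_warning(recruitment_curve(s4, "TA"), "5 stimuli")
})

test_that("normalization divides delta-RMS by the maximal evoked response", {
  rc <- structure(list(curve = data.frame(intensity = 1, mean_p2p = 1,
                                          n_stimuli = 5L),
                       max_p2p = 1.0, channel = "M1"),
                  class = "recruitment_curve")
  expect_equal(normalize_activation(0.2, rc), 0.2)
  expect_equal(normalize_activation(0, rc), 0)
  rc$max_p2p <- 0
  expect_error(normalize_activation(0.2, rc), "floor")
})

test_that("the full chain recovers generator ground truth on noiseless data", {
  # Delta-RMS 0.15 with plateau 0.5 gives normalized activation 0.30
  es <- emg_spec(background_sd = 0,
                 burst_amplitude = c(TA = 0.15 * sqrt(2), SOL = 0.05),
                 seed = 6)
  gen <- make_emg_session(es)
  act <- session_activation(gen$session)
  expect_equal(act$normalized[1], 0.30, tolerance = 0.01)
  rel <- abs(act$normalized - gen$truth$normalized) / gen$truth$normalized
  expect_lt(max(rel), 0.01)
})

test_that("normalized activation is invariant to channel gain", {
  gen <- make_emg_session(emg_spec(seed = 8))
  act <- session_activation(gen$session)
  s2 <- gen$session
  s2$signals <- s2$signals * 3.7
  act2 <- session_activation(s2)
  expect_equal(act2$normalized, act$normalized, tolerance = 1e-7)
  expect_equal(act2$delta_rms, act$delta_rms * 3.7, tolerance = 1e-7)
})

test_that("channels below the evoked-response floor are excluded, not zeroed", {
  es <- emg_spec(background_sd = 0, burst_amplitude = c(TA = 0.2, SOL = 0.1),
                 recruitment = list(threshold = 2, slope = 3,
                                    plateau = c(0.5, 0)),
                 seed = 10)
  gen <- make_emg_session(es)
  expect_message(act <- session_activation(gen$session), "excluded")
  expect_false(act$excluded[act$channel == "TA"])
  expect_true(act$excluded[act$channel == "SOL"])
  expect_true(is.na(act$normalized[act$channel == "SOL"]))
})

test_that("EMG sessions survive the CSV round trip", {
  gen <- make_emg_session(emg_spec(seed = 13))
  dir <- withr::local_tempdir()
  write_emg_session(gen$session, dir)
  s2 <- read_emg_session(dir)
  expect_equal(s2$signals, gen$session$signals, tolerance = 1e-12)
  expect_equal(s2$fs, gen$session$fs)
  expect_equal(s2$stim_events, gen$session$stim_events)
  expect_equal(as.numeric(s2$attempt_windows[1, c("start", "end")]),
               as.numeric(gen$session$attempt_windows[1, c("start", "end")]))
})
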