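#' Zero-phase band-pass filter for EMG
#'
#' 4th-order Butterworth band-pass (default 30-1000 Hz) applied
#' forward-backward ([signal::filtfilt()]) for zero phase distortion. An
#' upper edge at or above Nyquist is clipped to 0.999 x Nyquist with a
#' warning: a digital realization cannot place the edge at Nyquist itself,
#' which matters at the standard 2 kHz sampling rate where the nominal
#' 1000 Hz edge coincides with it.
#'
#' @param x numeric signal (mV).
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz.
#' @param order Butterworth order (default 4).
#' @return filtered signal, same length.
#' @export
bandpass_filter <- function(x, fs, low = 30, high = 1000, order = 4) {
  assert_that(all(is.finite(x)), "signal contains non-finite samples")
  assert_that(low > 0 && high > low, "need 0 < low < high")
  nyq <- fs / 2
  if (high >= nyq) {
    warning(sprintf("band-pass upper edge %g Hz >= Nyquist (%g Hz); clipped to %g Hz",
                    high, nyq, 0.999 * nyq), call. = FALSE)
    high <- 0.999 * nyq
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

window_to_idx <- function(window, fs, n) {
  i0 <- floor(window[1] * fs) + 1L
  i1 <- min(n, ceiling(window[2] * fs))
  assert_that(i0 >= 1 && i1 >= i0, "window is empty or outside the record")
  i0:i1
}

#' Root-mean-square amplitude
#'
#' @param x numeric signal.
#' @param window optional numeric(2) start/end in seconds (requires `fs`);
#'   default is the whole signal.
#' @param fs sampling rate in Hz, required when `window` is given.
#' @return RMS amplitude (same units as `x`).
#' @export
rms_amplitude <- function(x, window = NULL, fs = NULL) {
  if (!is.null(window)) {
    assert_that(!is.null(fs), "fs required when windowing by time")
    x <- x[window_to_idx(window, fs, length(x))]
  }
  assert_that(length(x) > 0, "empty window")
  sqrt(mean(x^2))
}

get_channel <- function(session, channel) {
  if (is.character(channel)) {
    assert_that(channel %in% session$channel_names,
                paste0("unknown channel: ", channel))
  }
  session$signals[channel, ]
}

#' Attempt-minus-background RMS increment
#'
#' RMS amplitude over the volitional attempt window minus the RMS over the
#' resting background window preceding it. Negative values are meaningful
#' (volitional suppression of ongoing activity) and are not clamped.
#'
#' @param session an `emg_session`.
#' @param channel channel name or index.
#' @param attempt attempt index into `session$attempt_windows` (default 1).
#' @param x optional pre-filtered signal to use instead of the raw channel.
#' @return RMS increment in mV.
#' @export
attempt_delta_rms <- function(session, channel, attempt = 1L, x = NULL) {
  aw <- session$attempt_windows[attempt, ]
  assert_that(aw$bg_end <= aw$start,
              "background window must precede (not overlap) the attempt window")
  if (is.null(x)) x <- get_channel(session, channel)
  rms_amplitude(x, c(aw$start, aw$end), session$fs) -
    rms_amplitude(x, c(aw$bg_start, aw$bg_end), session$fs)
}

#' Evoked-potential peak-to-peak amplitude
#'
#' Max minus min of the signal within a response window after one stimulus.
#'
#' @param session an `emg_session`.
#' @param channel channel name or index.
#' @param stim_time stimulus time in seconds.
#' @param response_window numeric(2), window relative to the stimulus in
#'   seconds (default 5-95 ms, inside the 500 ms inter-stimulus interval at
#'   the standard 2 Hz stimulation rate).
#' @param x optional pre-filtered signal.
#' @return peak-to-peak amplitude in mV.
#' @export
evoked_peak_peak <- function(session, channel, stim_time,
                             response_window = c(0.005, 0.095), x = NULL) {
  gaps <- diff(sort(unique(session$stim_events$time)))
  min_isi <- if (length(gaps)) min(gaps) else Inf
  assert_that(diff(response_window) > 0 && response_window[2] <= min_isi,
              "response window must fit inside the inter-stimulus interval")
  if (is.null(x)) x <- get_channel(session, channel)
  seg <- x[window_to_idx(stim_time + response_window, session$fs, length(x))]
  max(seg) - min(seg)
}

#' Evoked-potential recruitment curve
#'
#' Groups stimuli by intensity, averages the evoked peak-to-peak amplitude
#' within each group (the assessment protocol delivers five stimuli per
#' intensity), and records the maximum mean amplitude across intensities --
#' the normalization denominator for volitional activation.
#'
#' @inheritParams evoked_peak_peak
#' @param filter band-pass filter the channel first (default TRUE).
#' @return object of class `recruitment_curve`: list with `curve`
#'   (data.frame: intensity, mean_p2p, n_stimuli), `max_p2p`, `channel`.
#' @export
recruitment_curve <- function(session, channel,
                              response_window = c(0.005, 0.095),
                              filter = TRUE) {
  ev <- session$stim_events
  assert_that(!is.null(ev) && nrow(ev) > 0, "session has no stimulation events")
  x <- get_channel(session, channel)
  if (filter) x <- bandpass_filter_quiet(x, session$fs)
  p2p <- vapply(seq_len(nrow(ev)), function(i)
    evoked_peak_peak(session, channel, ev$time[i], response_window, x = x),
    0)
  agg <- stats::aggregate(p2p, by = list(intensity = ev$intensity),
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  curve <- data.frame(intensity = agg$intensity,
                      mean_p2p = agg$x[, "mean"],
                      n_stimuli = as.integer(agg$x[, "n"]))
  curve <- curve[order(curve$intensity), ]
  rownames(curve) <- NULL
  if (any(curve$n_stimuli != 5L)) {
    warning("some intensities do not have the protocol's 5 stimuli",
            call. = FALSE)
  }
  structure(list(curve = curve, max_p2p = max(curve$mean_p2p),
                 channel = channel),
            class = "recruitment_curve")
}

# internal: band-pass with the Nyquist clip warning silenced (the standard
# 2 kHz / 1000 Hz configuration would otherwise warn on every call)
bandpass_filter_quiet <- function(x, fs, low = 30, high = 1000, order = 4) {
  withCallingHandlers(
    bandpass_filter(x, fs, low, high, order),
    warning = function(w) {
      if (grepl("Nyquist", conditionMessage(w))) invokeRestart("muffleWarning")
    })
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat("<recruitment_curve> channel ", x$channel, ", max p2p ",
      signif(x$max_p2p, 4), " mV\n", sep = "")
  print(x$curve)
  invisible(x)
}

#' Normalize a volitional RMS increment by the maximal evoked response
#'
#' @param delta_rms RMS increment in mV (may be negative).
#' @param curve a [recruitment_curve()].
#' @param floor minimum usable `max_p2p` in mV (default 1e-6); channels
#'   below it cannot be normalized and raise an error so callers can flag
#'   them explicitly.
#' @return dimensionless normalized activation.
#' @export
normalize_activation <- function(delta_rms, curve, floor = 1e-6) {
  mp <- if (inherits(curve, "recruitment_curve")) curve$max_p2p else curve
  assert_that(is.finite(mp) && mp >= floor,
              "maximal evoked response below floor: normalization undefined")
  delta_rms / mp
}

#' Normalized volitional activation for every channel of a session
#'
#' The full processing chain: band-pass filter, attempt-minus-background RMS,
#' evoked recruitment curve, and normalization by the maximal evoked
#' peak-to-peak response. Channels whose maximal evoked response falls below
#' `floor` are retained in the output with `excluded = TRUE` and `NA`
#' normalized activation.
#'
#' @param session an `emg_session`.
#' @param attempt attempt index (default 1).
#' @param response_window evoked response window, seconds post-stimulus.
#' @param filter apply the band-pass first (default TRUE).
#' @param floor minimal usable max p2p, mV.
#' @return data.frame: channel, delta_rms, max_p2p, normalized, excluded.
#' @export
session_activation <- function(session, attempt = 1L,
                               response_window = c(0.005, 0.095),
                               filter = TRUE, floor = 1e-6) {
  rows <- lapply(session$channel_names, function(ch) {
    x <- get_channel(session, ch)
    if (filter) x <- bandpass_filter_quiet(x, session$fs)
    dr <- attempt_delta_rms(session, ch, attempt, x = x)
    # recruitment curve computed on the same (already filtered) trace
    rc <- recruitment_curve_from_signal(session, ch, x, response_window)
    mp <- rc$max_p2p
    excl <- !(is.finite(mp) && mp >= floor)
    data.frame(channel = ch, delta_rms = dr, max_p2p = mp,
               normalized = if (excl) NA_real_ else dr / mp,
               excluded = excl)
  })
  out <- do.call(rbind, rows)
  if (any(out$excluded)) {
    message("channel(s) excluded (max evoked response below floor): ",
            paste(out$channel[out$excluded], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

recruitment_curve_from_signal <- function(session, channel, x,
                                          response_window = c(0.005, 0.095)) {
  recruitment_curve(structure(
    list(signals = matrix(x, 1, dimnames = list(channel)),
         fs = session$fs, channel_names = channel,
         stim_events = session$stim_events,
         attempt_windows = session$attempt_windows),
    class = "emg_session"), channel, response_window, filter = FALSE)
}
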