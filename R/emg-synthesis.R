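#' Specification for a synthetic EMG session
#'
#' Describes a multichannel surface-EMG recording containing one volitional
#' movement attempt (a band-limited burst with rectangular envelope riding on
#' Gaussian background noise) followed by an evoked-potential
#' recruitment-curve assessment: trains of biphasic pulses delivered at a
#' fixed rate, several stimuli per intensity, with pulse amplitude following
#' a sigmoid of stimulation intensity.
#'
#' All amplitudes are in mV. The biphasic pulse is a positive half-sine lobe
#' at 0.6 of the pulse amplitude followed by a negative lobe at 0.4, so its
#' peak-to-peak amplitude equals the sigmoid amplitude exactly.
#'
#' @param channel_names character vector of muscle labels.
#' @param fs sampling rate in Hz (default 2000). Must exceed 2 kHz to
#'   represent the 30-1000 Hz analysis band.
#' @param background_sd Gaussian background noise SD in mV (scalar or per
#'   channel).
#' @param burst_amplitude volitional burst sine-carrier amplitude in mV,
#'   per channel (named vector recycled if scalar).
#' @param burst_freq burst carrier frequency in Hz (default 150, inside the
#'   30-1000 Hz band).
#' @param attempt_window numeric(2), attempt start/end in seconds.
#' @param background_window numeric(2), resting window preceding the attempt.
#' @param stim_intensities stimulation amplitudes (device units, e.g. mA).
#' @param stimuli_per_intensity stimuli delivered at each intensity
#'   (default 5).
#' @param stim_rate stimulation rate in Hz (default 2).
#' @param stim_start time of the first stimulus in seconds; defaults to 1 s
#'   after the attempt window ends. The stimulation epoch must not overlap
#'   the attempt or background windows.
#' @param recruitment list with `threshold`, `slope` and `plateau` (mV;
#'   plateau may be a per-channel vector): evoked pulse amplitude at
#'   intensity I is `plateau / (1 + exp(-slope * (I - threshold)))`.
#' @param pulse_lobe_ms half-sine lobe width in ms (default 2).
#' @param pulse_latency_s evoked-response onset latency after the stimulus
#'   in seconds (default 0.01, emulating conduction delay; keeps the
#'   response inside the standard 5-95 ms analysis window).
#' @param seed integer seed.
#' @return An `emg_spec` list.
#' @export
emg_spec <- function(channel_names = c("TA", "SOL"), fs = 2000,
                     background_sd = 0.01,
                     burst_amplitude = c(TA = 0.2, SOL = 0.05),
                     burst_freq = 150,
                     attempt_window = c(2, 5), background_window = c(0.5, 1.5),
                     stim_intensities = seq(0.5, 4, by = 0.5),
                     stimuli_per_intensity = 5L, stim_rate = 2,
                     stim_start = NULL,
                     recruitment = list(threshold = 2, slope = 3,
                                        plateau = 0.5),
                     pulse_lobe_ms = 2, pulse_latency_s = 0.01, seed = 1L) {
  assert_that(fs >= 2000, "fs must be at least 2000 Hz so the analysis band is representable")
  assert_that(stimuli_per_intensity >= 1, "need at least one stimulus per intensity")
  assert_that(all(recruitment$plateau >= 0), "recruitment plateau must be nonnegative")
  assert_that(all(stim_intensities >= 0), "stim intensities must be nonnegative")
  assert_that(background_window[2] <= attempt_window[1],
              "background window must precede the attempt window")
  nch <- length(channel_names)
  bsd <- rep_len(background_sd, nch)
  amp <- rep_len(burst_amplitude, nch)
  plat <- rep_len(recruitment$plateau, nch)
  names(bsd) <- names(amp) <- names(plat) <- channel_names
  if (is.null(stim_start)) stim_start <- attempt_window[2] + 1
  n_stim <- length(stim_intensities) * stimuli_per_intensity
  stim_end <- stim_start + (n_stim - 1) / stim_rate
  ovl <- function(a, b) a[1] < b[2] && b[1] < a[2]
  stim_epoch <- c(stim_start - 0.05, stim_end + 0.45)
  assert_that(!ovl(stim_epoch, attempt_window) &&
                !ovl(stim_epoch, background_window),
              "stimulation epoch overlaps the attempt/background windows")
  structure(list(channel_names = channel_names, fs = fs, background_sd = bsd,
                 burst_amplitude = amp, burst_freq = burst_freq,
                 attempt_window = attempt_window,
                 background_window = background_window,
                 stim_intensities = stim_intensities,
                 stimuli_per_intensity = as.integer(stimuli_per_intensity),
                 stim_rate = stim_rate, stim_start = stim_start,
                 recruitment = list(threshold = recruitment$threshold,
                                    slope = recruitment$slope, plateau = plat),
                 pulse_lobe_ms = pulse_lobe_ms,
                 pulse_latency_s = pulse_latency_s,
                 seed = as.integer(seed)),
            class = "emg_spec")
}

recruitment_sigmoid <- function(intensity, threshold, slope, plateau) {
  plateau / (1 + exp(-slope * (intensity - threshold)))
}

biphasic_pulse <- function(amplitude, fs, lobe_ms) {
  pw <- max(2L, round(lobe_ms / 1000 * fs))
  lobe <- sin(pi * seq_len(pw) / pw)
  amplitude * c(0.6 * lobe, -0.4 * lobe)
}

#' Generate a synthetic EMG session with known ground truth
#'
#' Builds the session described by an [emg_spec()] and returns analytic
#' ground truths alongside: the expected attempt-minus-background RMS
#' increment per channel, the evoked peak-to-peak amplitude at every
#' stimulation intensity (the recruitment sigmoid), the maximum evoked
#' peak-to-peak, and the resulting normalized activation.
#'
#' The expected RMS of noise plus an independent sine burst of amplitude A is
#' `sqrt(sd^2 + A^2/2)`, so the ground-truth RMS increment is
#' `sqrt(sd^2 + A^2/2) - sd` (exact in the noiseless case).
#'
#' @param spec an [emg_spec()].
#' @return list with `session` (an `emg_session`: `signals` channels-by-
#'   samples matrix, `fs`, `channel_names`, `stim_events` data.frame
#'   (time, intensity), `attempt_windows` data.frame) and `truth` (list:
#'   `delta_rms`, `evoked_p2p` intensity-by-channel matrix, `max_p2p`,
#'   `normalized`).
#' @export
make_emg_session <- function(spec) {
  stopifnot(inherits(spec, "emg_spec"))
  fs <- spec$fs
  n_stim_total <- length(spec$stim_intensities) * spec$stimuli_per_intensity
  stim_times <- spec$stim_start + (seq_len(n_stim_total) - 1) / spec$stim_rate
  stim_int <- rep(spec$stim_intensities, each = spec$stimuli_per_intensity)
  duration <- max(stim_times) + 0.5
  n <- ceiling(duration * fs)
  t <- (seq_len(n) - 1) / fs
  nch <- length(spec$channel_names)

  att <- t >= spec$attempt_window[1] & t < spec$attempt_window[2]
  signals <- matrix(0, nrow = nch, ncol = n,
                    dimnames = list(spec$channel_names, NULL))
  for (ci in seq_len(nch)) {
    set.seed(substream_seed(spec$seed, ci))
    x <- rnorm(n, sd = spec$background_sd[ci])
    x[att] <- x[att] +
      spec$burst_amplitude[ci] *
      sin(2 * pi * spec$burst_freq * (t[att] - spec$attempt_window[1]))
    for (si in seq_along(stim_times)) {
      amp <- recruitment_sigmoid(stim_int[si], spec$recruitment$threshold,
                                 spec$recruitment$slope,
                                 spec$recruitment$plateau[ci])
      pulse <- biphasic_pulse(amp, fs, spec$pulse_lobe_ms)
      i0 <- round((stim_times[si] + spec$pulse_latency_s) * fs) + 1L
      idx <- i0 + seq_along(pulse) - 1L
      idx <- idx[idx <= n]
      x[idx] <- x[idx] + pulse[seq_along(idx)]
    }
    signals[ci, ] <- x
  }

  evoked <- sapply(seq_len(nch), function(ci)
    recruitment_sigmoid(spec$stim_intensities, spec$recruitment$threshold,
                        spec$recruitment$slope, spec$recruitment$plateau[ci]))
  evoked <- matrix(evoked, nrow = length(spec$stim_intensities),
                   dimnames = list(NULL, spec$channel_names))
  max_p2p <- apply(evoked, 2, max)
  delta_rms <- sqrt(spec$background_sd^2 + spec$burst_amplitude^2 / 2) -
    spec$background_sd
  normalized <- ifelse(max_p2p > 0, delta_rms / max_p2p, NA_real_)

  session <- structure(
    list(signals = signals, fs = fs, channel_names = spec$channel_names,
         stim_events = data.frame(time = stim_times, intensity = stim_int),
         attempt_windows = data.frame(start = spec$attempt_window[1],
                                      end = spec$attempt_window[2],
                                      task = "attempt",
                                      bg_start = spec$background_window[1],
                                      bg_end = spec$background_window[2]),
         spec = spec),
    class = "emg_session")
  list(session = session,
       truth = list(delta_rms = delta_rms, evoked_p2p = evoked,
                    max_p2p = max_p2p, normalized = normalized,
                    intensities = spec$stim_intensities))
}

#' @export
print.emg_session <- function(x, ...) {
  cat("<emg_session> ", nrow(x$signals), " channel(s) x ",
      ncol(x$signals), " samples @ ", x$fs, " Hz; ",
      nrow(x$stim_events), " stimuli over ",
      length(unique(x$stim_events$intensity)), " intensities\n", sep = "")
  invisible(x)
}
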