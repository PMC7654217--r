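#' Write an EMG session as long-format CSV plus JSON sidecar
#'
#' The signals go to `signals.csv` (columns: time, channel, value) and the
#' sampling rate, stimulation events and attempt windows to `session.json`.
#' This plain-text container is the package's interchange format for EMG.
#'
#' @param session an `emg_session`.
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_emg_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- ncol(session$signals)
  t <- (seq_len(n) - 1) / session$fs
  long <- data.table::data.table(
    time = rep(t, times = nrow(session$signals)),
    channel = rep(session$channel_names, each = n),
    value = as.vector(t(session$signals)))
  sig_path <- file.path(dir, "signals.csv")
  data.table::fwrite(long, sig_path)
  meta_path <- file.path(dir, "session.json")
  jsonlite::write_json(
    list(fs = session$fs, channel_names = session$channel_names,
         stim_events = session$stim_events,
         attempt_windows = session$attempt_windows),
    meta_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(signals = sig_path, meta = meta_path))
}

#' Read an EMG session written by [write_emg_session()]
#'
#' @param dir directory holding `signals.csv` and `session.json`.
#' @return an `emg_session`.
#' @export
read_emg_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  long <- data.table::fread(file.path(dir, "signals.csv"))
  chans <- meta$channel_names
  sig <- do.call(rbind, lapply(chans, function(ch)
    long[long$channel == ch, ][["value"]]))
  dimnames(sig) <- list(chans, NULL)
  structure(list(signals = sig, fs = meta$fs, channel_names = chans,
                 stim_events = as.data.frame(meta$stim_events),
                 attempt_windows = as.data.frame(meta$attempt_windows)),
            class = "emg_session")
}

#' Write per-attempt normalized activations to CSV
#'
#' @param df data.frame as returned by [session_activation()], optionally
#'   with extra key columns (subject, task, side).
#' @param path output CSV path.
#' @return invisibly, `df`.
#' @export
write_activation_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
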