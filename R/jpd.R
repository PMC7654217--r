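#' Moving-RMS activation envelope
#'
#' Amplitude envelope of a (filtered) EMG trace: the square root of a
#' centred moving average of the squared signal, window `window_ms`
#' milliseconds. At the edges the window shrinks to the available samples,
#' so the output has the same length and sampling grid as the input and is
#' nonnegative everywhere.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window_ms window length in milliseconds (default 50).
#' @return nonnegative envelope, same length as `x`.
#' @export
activation_envelope <- function(x, fs, window_ms = 50) {
  assert_that(window_ms > 0, "window_ms must be positive")
  w <- max(1L, round(window_ms / 1000 * fs))
  n <- length(x)
  assert_that(w <= n, "envelope window longer than the signal")
  # centred window, shrunk at the edges to the available samples
  half <- (w - 1L) %/% 2L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + (w - 1L) - half)
  cs <- cumsum(c(0, x^2))
  sqrt(pmax((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L), 0))
}

#' Time-aligned envelope pair for two muscles
#'
#' @param a,b nonnegative amplitude series on a common sampling grid.
#' @param muscles character(2) muscle names.
#' @param attempt optional attempt label.
#' @return object of class `envelope_pair`.
#' @export
envelope_pair <- function(a, b, muscles = c("A", "B"), attempt = NULL) {
  assert_that(length(a) == length(b) && length(a) > 0,
              "envelopes must be nonempty and of equal length")
  assert_that(all(a >= 0) && all(b >= 0), "envelope amplitudes must be nonnegative")
  structure(list(a = a, b = b, muscles = muscles, attempt = attempt),
            class = "envelope_pair")
}

#' JPD four-quadrant co-contraction statistic
#'
#' Classifies every time point of a two-muscle amplitude plot into four
#' regions -- isolated activation of either muscle, co-contraction at high
#' level, co-contraction at low level -- using as activity threshold ten
#' percent of the largest amplitude detected during the attempt, and reports
#' the percentage of points in each region. With `per_muscle = TRUE`
#' (default) each muscle gets 10% of its own maximum, giving the
#' axis-aligned rectangular regions of the standard JPD plot; with
#' `per_muscle = FALSE` a single threshold from the joint maximum is used.
#'
#' Samples exactly at threshold count as inactive. If no activation is
#' detected for either muscle (both attempt maxima below `floor`), the
#' attempt is by definition 100% co-contraction at low level of activation.
#'
#' @param pair an [envelope_pair()] (or the first envelope, with `b` the
#'   second).
#' @param b second envelope when `pair` is a plain vector.
#' @param threshold_frac activity threshold as a fraction of the attempt
#'   maximum (default 0.10).
#' @param per_muscle one threshold per muscle (default) or a single joint
#'   threshold.
#' @param floor activity floor for the no-activation degenerate rule
#'   (default 1e-9 normalized units).
#' @return object of class `jpd_summary`: list with `pct_isolated_a`,
#'   `pct_isolated_b`, `pct_coco_high`, `pct_coco_low`, `thresholds`,
#'   `n`, `muscles`.
#' @export
jpd_quadrants <- function(pair, b = NULL, threshold_frac = 0.10,
                          per_muscle = TRUE, floor = 1e-9) {
  if (!inherits(pair, "envelope_pair")) {
    pair <- envelope_pair(pair, b)
  }
  a <- pair$a; bb <- pair$b
  n <- length(a)
  max_a <- max(a); max_b <- max(bb)
  if (max_a < floor && max_b < floor) {
    return(structure(list(pct_isolated_a = 0, pct_isolated_b = 0,
                          pct_coco_high = 0, pct_coco_low = 100,
                          thresholds = c(a = NA_real_, b = NA_real_),
                          n = n, muscles = pair$muscles, degenerate = TRUE),
                     class = "jpd_summary"))
  }
  if (per_muscle) {
    th_a <- threshold_frac * max_a
    th_b <- threshold_frac * max_b
  } else {
    th_a <- th_b <- threshold_frac * max(max_a, max_b)
  }
  act_a <- a > th_a
  act_b <- bb > th_b
  structure(list(
    pct_isolated_a = 100 * sum(act_a & !act_b) / n,
    pct_isolated_b = 100 * sum(!act_a & act_b) / n,
    pct_coco_high = 100 * sum(act_a & act_b) / n,
    pct_coco_low = 100 * sum(!act_a & !act_b) / n,
    thresholds = c(a = th_a, b = th_b),
    n = n, muscles = pair$muscles, degenerate = FALSE),
    class = "jpd_summary")
}

#' @export
print.jpd_summary <- function(x, ...) {
  cat("<jpd_summary> ", x$muscles[1], " vs ", x$muscles[2], " (n = ", x$n,
      ")\n", sep = "")
  cat(sprintf("  isolated %s: %.1f%%  isolated %s: %.1f%%  co-co high: %.1f%%  co-co low: %.1f%%\n",
              x$muscles[1], x$pct_isolated_a, x$muscles[2], x$pct_isolated_b,
              x$pct_coco_high, x$pct_coco_low))
  invisible(x)
}

#' @export
as.data.frame.jpd_summary <- function(x, ...) {
  data.frame(pct_isolated_a = x$pct_isolated_a,
             pct_isolated_b = x$pct_isolated_b,
             pct_coco_high = x$pct_coco_high,
             pct_coco_low = x$pct_coco_low)
}

#' Render a JPD panel figure
#'
#' 2-D binned density of the two envelopes with the activity thresholds as
#' lines and the four quadrant percentages annotated; written to file.
#'
#' @param pair an [envelope_pair()].
#' @param summary a [jpd_quadrants()] result; computed from `pair` if NULL.
#' @param file output file (png/pdf/svg by extension).
#' @param width,height figure size in inches.
#' @return invisibly, the `jpd_summary` used.
#' @importFrom ggplot2 .data
#' @export
jpd_panel <- function(pair, summary = NULL, file, width = 4.5, height = 4.5) {
  if (is.null(summary)) summary <- jpd_quadrants(pair)
  df <- data.frame(a = pair$a, b = pair$b)
  th <- summary$thresholds
  lim_a <- max(pair$a, th["a"], na.rm = TRUE) * 1.05 + 1e-12
  lim_b <- max(pair$b, th["b"], na.rm = TRUE) * 1.05 + 1e-12
  lab <- c(sprintf("isolated %s: %.1f%%", summary$muscles[1],
                   summary$pct_isolated_a),
           sprintf("isolated %s: %.1f%%", summary$muscles[2],
                   summary$pct_isolated_b),
           sprintf("co-co high: %.1f%%", summary$pct_coco_high),
           sprintf("co-co low: %.1f%%", summary$pct_coco_low))
  ann <- data.frame(
    a = c(lim_a * 0.75, lim_a * 0.12, lim_a * 0.75, lim_a * 0.12),
    b = c(lim_b * 0.05, lim_b * 0.95, lim_b * 0.95, lim_b * 0.05),
    lab = lab)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_bin2d(bins = 40) +
    ggplot2::scale_fill_viridis_c(name = "points") +
    ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$lab),
                       size = 2.8, colour = "grey20") +
    ggplot2::coord_cartesian(xlim = c(0, lim_a), ylim = c(0, lim_b)) +
    ggplot2::labs(x = paste(summary$muscles[1], "amplitude"),
                  y = paste(summary$muscles[2], "amplitude"),
                  title = "Joint probability density of muscle activation") +
    ggplot2::theme_minimal(base_size = 9)
  if (!summary$degenerate) {
    p <- p +
      ggplot2::geom_vline(xintercept = th["a"], linetype = 2,
                          colour = "red") +
      ggplot2::geom_hline(yintercept = th["b"], linetype = 2,
                          colour = "red")
  }
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  invisible(summary)
}
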