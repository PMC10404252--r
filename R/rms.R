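# centered rolling mean with shrinking windows at the edges (no NA padding)
roll_mean_partial <- function(x, width) {
  n <- length(x)
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width - 1L - half_lo
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Delta-RMS firing-activity proxy from raw multiunit voltage
#'
#' Converts a raw extracellular voltage trace (nominally 15 kHz) into a
#' baseline-subtracted moving root-mean-square envelope at 20 Hz, a
#' firing-activity proxy for recordings that cannot be spike-sorted. The
#' chain: 4th-order zero-phase Butterworth band-pass (300-6000 Hz), clipping
#' of samples beyond `clip_sd` baseline standard deviations, moving RMS with
#' a 20 ms window, downsampling by 150, a 10-point moving average,
#' downsampling by 5 (15000 / 150 / 5 = 20 samples/s), and subtraction of
#' the mean over the 1 s pre-stimulus baseline.
#'
#' @param x Numeric voltage trace.
#' @param fs Sampling rate in Hz (default 15000).
#' @param onset_s Stimulus onset in seconds from the start of the trace;
#'   defines the baseline for clipping and the final subtraction.
#' @param band Band-pass edges in Hz (default `c(300, 6000)`).
#' @param clip_sd Clip threshold in baseline s.d. (default 5); `Inf`
#'   disables clipping (the chain is then amplitude-equivariant).
#' @param rms_window_s Moving-RMS window in seconds (default 0.02).
#' @param down1,down2 Downsampling factors (defaults 150 and 5).
#' @param ma_points Moving-average length between downsampling steps
#'   (default 10).
#' @param baseline_s Baseline span for the final mean subtraction
#'   (default 1 s).
#' @param baseline_subtract Subtract the pre-stimulus mean? Default `TRUE`.
#' @return A tibble `time_s` (seconds from trace start, one sample per
#'   `down1 * down2 / fs` seconds) and `drms`.
#' @export
rms_preprocess <- function(x, fs = 15000, onset_s,
                           band = c(300, 6000),
                           clip_sd = 5,
                           rms_window_s = 0.02,
                           down1 = 150, down2 = 5, ma_points = 10,
                           baseline_s = 1,
                           baseline_subtract = TRUE) {
  stopifnot(is.numeric(x))
  w <- as.integer(round(rms_window_s * fs))
  if (length(x) < 10L * w) {
    abort("Trace shorter than the filter warm-up (need >= 10 RMS windows).")
  }
  if (missing(onset_s)) abort("`onset_s` (stimulus onset) is required.")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bf, x)

  idx_base_raw <- seq_along(x) / fs < onset_s
  if (is.finite(clip_sd)) {
    if (!any(idx_base_raw)) abort("No pre-stimulus samples for clipping baseline.")
    bmu <- mean(filtered[idx_base_raw])
    bsd <- sd(filtered[idx_base_raw])
    if (is.na(bsd)) bsd <- 0
    filtered <- pmin(pmax(filtered, bmu - clip_sd * bsd), bmu + clip_sd * bsd)
  }

  env <- sqrt(roll_mean_partial(filtered^2, w))
  s1 <- env[seq(1L, length(env), by = down1)]
  s1 <- roll_mean_partial(s1, ma_points)
  s2 <- s1[seq(1L, length(s1), by = down2)]
  step <- down1 * down2 / fs
  time_s <- (seq_along(s2) - 1L) * step

  if (baseline_subtract) {
    in_base <- time_s < onset_s & time_s >= onset_s - baseline_s
    if (!any(in_base)) abort("No samples in the pre-stimulus baseline window.")
    s2 <- s2 - mean(s2[in_base])
  }
  tibble::tibble(time_s = time_s, drms = s2)
}
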