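#' Detect a palp-opening response in a separation trace
#'
#' A locust counts as responsive to an odor if its palp separation exceeds
#' the pre-stimulus baseline mean by `sd_mult` baseline standard deviations
#' for at least `min_frames` frames (1 s at 30 fps) within the response
#' window, with an absolute separation above `min_separation` arb.u. (the
#' tracking noise floor). The baseline spans the `baseline_s` seconds before
#' stimulus onset; a flat baseline is handled with a small s.d. floor. The
#' response window runs from onset through `post_offset_s` seconds after
#' offset, since PORs can persist into the OFF period. Frames need not be
#' contiguous by default; `contiguous = TRUE` requires a single run.
#'
#' @param trace A data frame with columns `time_s` and `separation` for one
#'   (locust, odor) trace, e.g. one group of [simulate_por_traces()].
#' @param onset_s,offset_s Stimulus onset/offset in seconds (defaults 0, 4,
#'   or the trace attributes if present).
#' @param baseline_s Baseline span before onset (default 2 s).
#' @param sd_mult Threshold in baseline s.d. units (default 6.5).
#' @param min_frames Minimum supra-threshold frames (default 30).
#' @param min_separation Absolute separation gate in arb.u. (default 1.5).
#' @param post_offset_s Response window extension past offset (default 4 s).
#' @param contiguous Require the frames to be consecutive? Default `FALSE`.
#' @param sd_floor Lower bound on the baseline s.d. (default 1e-6).
#' @return Logical scalar.
#' @export
detect_por_response <- function(trace,
                                onset_s = attr(trace, "onset_s") %||% 0,
                                offset_s = attr(trace, "offset_s") %||% 4,
                                baseline_s = 2,
                                sd_mult = 6.5,
                                min_frames = 30,
                                min_separation = 1.5,
                                post_offset_s = 4,
                                contiguous = FALSE,
                                sd_floor = 1e-6) {
  stopifnot(is.data.frame(trace), all(c("time_s", "separation") %in% names(trace)))
  t <- trace$time_s
  sep <- trace$separation
  base <- sep[t >= onset_s - baseline_s & t < onset_s]
  if (length(base) < 2) abort("Trace must cover the pre-stimulus baseline.")
  thr <- mean(base) + sd_mult * max(sd(base), sd_floor)
  in_window <- t >= onset_s & t < offset_s + post_offset_s
  hit <- in_window & sep > thr & sep > min_separation
  if (!contiguous) {
    sum(hit) >= min_frames
  } else {
    runs <- rle(hit[in_window])
    any(runs$lengths[runs$values] >= min_frames)
  }
}

#' Normalize a locust's POR traces to the unit interval
#'
#' Affinely rescales each locust's palp-separation traces so that 0 maps to
#' the minimum and 1 to the maximum separation that locust showed across all
#' of its test-odor traces (a per-locust, not per-trace, rescaling, so
#' relative response sizes between odors are preserved). A locust that is
#' flat across all odors gets all-zero output and is flagged.
#'
#' @param traces A data frame with columns `locust_id` and `separation`
#'   (long format, as from [simulate_por_traces()]).
#' @return The input with `separation` replaced by its normalized value and
#'   a logical `flat` column marking zero-range locusts.
#' @export
normalize_traces <- function(traces) {
  stopifnot(is.data.frame(traces),
            all(c("locust_id", "separation") %in% names(traces)))
  out <- traces |>
    dplyr::group_by(.data$locust_id) |>
    dplyr::mutate(
      .range = max(.data$separation) - min(.data$separation),
      flat = .data$.range == 0,
      separation = dplyr::if_else(
        .data$flat, 0,
        (.data$separation - min(.data$separation)) / .data$.range
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".range")
  if (any(out$flat)) {
    warn(sprintf("%d locust(s) had zero separation range; normalized to 0.",
                 dplyr::n_distinct(out$locust_id[out$flat])))
  }
  out
}
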