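#' Configuration for the synthetic locust olfaction dataset
#'
#' Bundles every knob of the synthetic-data generator: population and panel
#' sizes, stimulus timing, Poisson firing rates, and the valence structure of
#' the projection-neuron (PN) ensembles. Defaults reproduce the study
#' conditions of the emulated experiments: 89 PNs, 26 locusts, a 22-odor
#' panel, 10 trials per odor, a 4 s odor pulse followed by a 4 s OFF window.
#'
#' Ensemble structure: PNs are partitioned into four pools --
#' appetitive-ON, appetitive-OFF, non-appetitive-ON and non-appetitive-OFF --
#' and each PN carries a fixed sensitivity rank. An odor of a pool's valence
#' class recruits the pool PNs whose rank falls below
#' `ensemble_overlap * (0.2 + 0.8 * por_prob)`, so same-class ensembles
#' are nested around a shared core and higher-valence odors recruit more
#' PNs; response gains (`on_gain` / `off_gain`) are scaled by
#' `0.7 + 0.5 * por_prob`, so higher-valence odors also drive PNs somewhat
#' harder while recruited PNs of any class respond robustly (non-appetitive
#' odors strongly engage their own ensemble). The
#' `cross_activation` fraction of the appetitive-ON pool with the highest
#' sensitivity (the most broadly tuned appetitive PNs) is additionally
#' weakly driven at `cross_gain` Hz by unappetitive odors -- the response
#' overlap that makes cross-learning possible in the Hebbian model.
#' Unappetitive odors suppress non-responding appetitive-pool PNs to
#' `inhibition_factor * baseline_rate` with probability `inhibition_prob`.
#'
#' @param n_pns Number of projection neurons (default 89).
#' @param n_locusts Number of locusts in the behavioral assay (default 26).
#' @param odor_panel Tibble with columns `odor_id`, `valence`, `por_prob`;
#'   see [default_odor_panel()].
#' @param n_trials Electrophysiology trials per odor (default 10).
#' @param timing Named numeric vector of window durations in seconds:
#'   `baseline` (pre-stimulus span simulated; 4 s so that both the 4 s
#'   consistency-filter baseline and the 2 s classification baseline exist),
#'   `on` (odor pulse, 4 s), `off` (post-stimulus window, 4 s).
#' @param baseline_rate Spontaneous PN firing rate in Hz (default 3).
#' @param on_gain,off_gain Peak rate increments (Hz) for ON/OFF responders
#'   before valence scaling (defaults 15 and 10).
#' @param cross_gain Rate increment (Hz) for cross-activated appetitive-pool
#'   PNs during non-appetitive odors (default 9).
#' @param ensemble_overlap Fraction of a valence pool recruited by an odor of
#'   that class, before valence scaling (default 0.8).
#' @param cross_activation Fraction of the appetitive-ON pool weakly driven
#'   by unappetitive odors (default 0.15).
#' @param inhibition_prob Probability that a low-valence odor suppresses a
#'   non-responding appetitive-pool PN (default 0.3).
#' @param inhibition_factor Multiplier on `baseline_rate` during suppression
#'   (default 0.2).
#' @param seed Integer seed; identical configs with identical seeds produce
#'   bit-identical datasets.
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_pns = 10, n_trials = 2, seed = 42)
#' cfg$timing
synth_config <- function(n_pns = 89,
                         n_locusts = 26,
                         odor_panel = default_odor_panel(),
                         n_trials = 10,
                         timing = c(baseline = 4, on = 4, off = 4),
                         baseline_rate = 3,
                         on_gain = 15,
                         off_gain = 10,
                         cross_gain = 9,
                         ensemble_overlap = 0.8,
                         cross_activation = 0.15,
                         inhibition_prob = 0.3,
                         inhibition_factor = 0.2,
                         seed = 1L) {
  n_pns <- assert_count(n_pns)
  n_locusts <- assert_count(n_locusts)
  n_trials <- assert_count(n_trials)
  stopifnot(is.data.frame(odor_panel))
  required <- c("odor_id", "valence", "por_prob")
  if (!all(required %in% names(odor_panel))) {
    abort("`odor_panel` needs columns odor_id, valence, por_prob.")
  }
  if (anyDuplicated(odor_panel$odor_id)) abort("Duplicate odor ids in panel.")
  bad <- setdiff(unique(odor_panel$valence),
                 c("appetitive", "neutral", "unappetitive"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown valence class: %s", paste(bad, collapse = ", ")))
  }
  assert_probability(odor_panel$por_prob, "odor_panel$por_prob")
  if (!all(c("baseline", "on", "off") %in% names(timing))) {
    abort("`timing` needs named entries baseline, on, off.")
  }
  assert_positive(unname(timing), "timing")
  assert_positive(c(baseline_rate, on_gain, off_gain, cross_gain),
                  "rates", strict = FALSE)
  assert_probability(ensemble_overlap)
  assert_probability(cross_activation)
  assert_probability(inhibition_prob)
  assert_probability(inhibition_factor)
  seed <- assert_count(seed, min = 0)

  structure(
    list(
      n_pns = n_pns, n_locusts = n_locusts,
      odor_panel = tibble::as_tibble(odor_panel),
      n_trials = n_trials, timing = timing,
      baseline_rate = baseline_rate, on_gain = on_gain, off_gain = off_gain,
      cross_gain = cross_gain, ensemble_overlap = ensemble_overlap,
      cross_activation = cross_activation,
      inhibition_prob = inhibition_prob,
      inhibition_factor = inhibition_factor,
      seed = seed
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d PNs x %d odors x %d trials; %d locusts; seed %d\n",
              x$n_pns, nrow(x$odor_panel), x$n_trials, x$n_locusts, x$seed))
  cat(sprintf("  windows (s): baseline %g | ON %g | OFF %g\n",
              x$timing[["baseline"]], x$timing[["on"]], x$timing[["off"]]))
  cat(sprintf("  rates (Hz): baseline %g, ON gain %g, OFF gain %g\n",
              x$baseline_rate, x$on_gain, x$off_gain))
  invisible(x)
}

# stimulus windows in seconds relative to odor onset (onset = 0)
config_windows <- function(config) {
  list(
    baseline = c(-config$timing[["baseline"]], 0),
    on = c(0, config$timing[["on"]]),
    off = c(config$timing[["on"]],
            config$timing[["on"]] + config$timing[["off"]])
  )
}
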