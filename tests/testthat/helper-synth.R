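# shared fixtures: small configurations and hand-built datasets

mini_panel <- function() {
  tibble::tribble(
    ~odor_id, ~valence,       ~por_prob,
    "hex",    "appetitive",   0.8,
    "iaa",    "appetitive",   0.7,
    "neu1",   "neutral",      0.45,
    "neu2",   "neutral",      0.35,
    "bza",    "unappetitive", 0.15,
    "cit",    "unappetitive", 0.10
  )
}

small_config <- function(seed = 1L, n_pns = 24, n_locusts = 12,
                         n_trials = 6, ...) {
  synth_config(n_pns = n_pns, n_locusts = n_locusts,
               odor_panel = mini_panel(), n_trials = n_trials,
               seed = seed, ...)
}

# a dataset built spike-by-spike, for exact binning/classification checks
manual_dataset <- function(spikes, odor_ids = unique(spikes$odor_id),
                           n_trials = max(spikes$trial),
                           pn_ids = sort(unique(spikes$pn_id))) {
  spike_dataset(
    spikes = spikes,
    panel = tibble::tibble(odor_id = odor_ids),
    windows = list(baseline = c(-4, 0), on = c(0, 4), off = c(4, 8)),
    n_trials = n_trials, pn_ids = pn_ids
  )
}

# regular (non-random) spike train covering [from, to) at a given rate
regular_train <- function(rate, from, to) {
  if (rate <= 0) return(numeric(0))
  seq(from, to - 1e-9, by = 1 / rate)
}

# one POR trace at 30 fps over [-2, 8) s with a given response envelope
flat_trace <- function(level = 1, fps = 30) {
  t <- seq(-2 + 1 / (2 * fps), 8, by = 1 / fps)
  tibble::tibble(time_s = t, separation = rep(level, length(t)))
}

# baseline with small deterministic jitter (sd ~ 0.01) plus an excursion to
# an absolute separation value for a given duration; with level = 1 the
# baseline 6.5-sd threshold sits near 1.07 units
excursion_trace <- function(sep_value, duration_s, level = 1,
                            excursion_at = 0.5, fps = 30) {
  tr <- flat_trace(level, fps)
  tr$separation <- tr$separation + rep(c(-0.01, 0.01), length.out = nrow(tr))
  hit <- tr$time_s >= excursion_at & tr$time_s < excursion_at + duration_s
  tr$separation[hit] <- sep_value
  tr
}
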