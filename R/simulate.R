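#' Simulate a binary locusts-by-odors palp-opening-response matrix
#'
#' Each cell is an independent Bernoulli draw with the odor's innate POR
#' probability from the panel, emulating a single pseudorandomized
#' presentation of every odor to every locust.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with a `locust_id` column followed by one 0/1 column per
#'   odor (class `por_matrix`).
#' @export
#' @examples
#' por <- simulate_por_matrix(synth_config(n_locusts = 6, seed = 1))
#' dim(por)
simulate_por_matrix <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  panel <- config$odor_panel
  assert_probability(panel$por_prob, "por_prob")
  n <- config$n_locusts
  draws <- withr::with_seed(seed, {
    vapply(panel$por_prob, function(p) rbinom(n, 1L, p), integer(n))
  })
  draws <- matrix(draws, nrow = n, dimnames = list(NULL, panel$odor_id))
  out <- tibble::as_tibble(as.data.frame(draws, check.names = FALSE))
  out <- dplyr::bind_cols(
    tibble::tibble(locust_id = sprintf("locust_%02d", seq_len(n))), out
  )
  class(out) <- c("por_matrix", class(out))
  out
}

#' Simulate a valence-structured projection-neuron population
#'
#' Generates piecewise-constant-rate Poisson spike trains for every
#' (PN, odor, trial) triple over a baseline / 4 s ON / 4 s OFF protocol.
#' The population carries the ensemble structure described in
#' [synth_config()]: appetitive odors recruit overlapping subsets of the
#' appetitive ON and OFF pools, non-appetitive odors recruit the
#' complementary pools plus a small cross-activated corner of the appetitive
#' pool, and low-valence odors suppress some appetitive-pool PNs below
#' baseline during the ON window. Recruitment probability and response gain
#' both scale with the odor's innate POR probability, so higher-valence odors
#' drive stronger responses across more PNs.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `spike_dataset`: a list with
#'   \describe{
#'     \item{spikes}{tibble `pn_id`, `odor_id`, `trial`, `spike_time_s`
#'       (seconds relative to odor onset at 0)}
#'     \item{panel}{the odor panel used}
#'     \item{windows}{list of half-open windows `baseline`, `on`, `off`}
#'     \item{n_trials, n_pns}{design sizes}
#'     \item{truth}{per (PN, odor) generative ground truth: ON/OFF
#'       responder flags, inhibition flag, cross-activation flag and the
#'       realized ON/OFF rates -- used by construction checks}
#'     \item{pools}{tibble `pn_id`, `pool` with the four-way pool partition}
#'   }
#' @export
#' @examples
#' ds <- simulate_pn_spikes(synth_config(n_pns = 8, n_trials = 2, seed = 3))
#' ds
simulate_pn_spikes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_pns < 1 || config$n_trials < 1) {
    abort("Need at least one PN and one trial.")
  }
  panel <- config$odor_panel
  n_pns <- config$n_pns
  n_odors <- nrow(panel)
  windows <- config_windows(config)

  withr::with_seed(seed, {
    # four-way pool partition of the population
    pool_labels <- c("appetitive_on", "appetitive_off",
                     "nonappetitive_on", "nonappetitive_off")
    pool <- sample(rep(pool_labels, length.out = n_pns))
    # fixed per-PN sensitivity: an odor recruits the pool PNs whose
    # sensitivity rank falls below its valence-graded cutoff, so ensembles
    # of same-class odors are nested (shared core + graded recruitment)
    sens <- runif(n_pns)
    app_on_ids <- which(pool == "appetitive_on")
    n_cross <- round(config$cross_activation * length(app_on_ids))
    cross_ids <- if (n_cross > 0) {
      app_on_ids[order(sens[app_on_ids])][seq_len(n_cross)]
    } else integer(0)

    # per (pn, odor) membership and rates
    grid <- tidyr::expand_grid(pn_id = seq_len(n_pns), odor = seq_len(n_odors))
    p_odor <- panel$por_prob[grid$odor]
    valence <- panel$valence[grid$odor]
    pn_pool <- pool[grid$pn_id]
    appetitive_odor <- valence == "appetitive"
    cutoff <- config$ensemble_overlap * (0.2 + 0.8 * p_odor)
    gain_scale <- 0.7 + 0.5 * p_odor

    match_on <- (appetitive_odor & pn_pool == "appetitive_on") |
      (!appetitive_odor & pn_pool == "nonappetitive_on")
    match_off <- (appetitive_odor & pn_pool == "appetitive_off") |
      (!appetitive_odor & pn_pool == "nonappetitive_off")
    drives_on <- match_on & sens[grid$pn_id] < cutoff
    drives_off <- match_off & sens[grid$pn_id] < cutoff

    # the most sensitive (most broadly tuned) appetitive-ON PNs are weakly
    # driven by unappetitive odors -- the ensemble overlap that supports
    # cross-learning in the conditioning model
    cross <- valence == "unappetitive" & grid$pn_id %in% cross_ids
    inhibited <- valence == "unappetitive" &
      pn_pool %in% c("appetitive_on", "appetitive_off") &
      !cross & runif(nrow(grid)) < config$inhibition_prob

    rate_on <- config$baseline_rate +
      drives_on * config$on_gain * gain_scale +
      cross * config$cross_gain
    rate_on[inhibited] <- config$baseline_rate * config$inhibition_factor
    rate_off <- config$baseline_rate + drives_off * config$off_gain * gain_scale

    truth <- tibble::tibble(
      pn_id = grid$pn_id,
      odor_id = panel$odor_id[grid$odor],
      drives_on = drives_on, drives_off = drives_off,
      cross_activated = cross, inhibited = inhibited,
      rate_on = rate_on, rate_off = rate_off
    )

    # Poisson spike times, segment by segment, all trials at once
    seg <- tibble::tibble(
      segment = c("baseline", "on", "off"),
      start = c(windows$baseline[1], windows$on[1], windows$off[1]),
      dur = c(diff(windows$baseline), diff(windows$on), diff(windows$off))
    )
    rate_mat <- cbind(baseline = rep(config$baseline_rate, nrow(grid)),
                      on = rate_on, off = rate_off)
    pieces <- vector("list", nrow(seg) * config$n_trials)
    k <- 0L
    for (trial in seq_len(config$n_trials)) {
      for (s in seq_len(nrow(seg))) {
        lambda <- rate_mat[, seg$segment[s]] * seg$dur[s]
        counts <- rpois(length(lambda), lambda)
        total <- sum(counts)
        k <- k + 1L
        if (total == 0) next
        idx <- rep.int(seq_along(counts), counts)
        pieces[[k]] <- tibble::tibble(
          pn_id = grid$pn_id[idx],
          odor_id = panel$odor_id[grid$odor[idx]],
          trial = trial,
          spike_time_s = seg$start[s] + runif(total) * seg$dur[s]
        )
      }
    }
    spikes <- dplyr::bind_rows(pieces)
    spikes <- dplyr::arrange(spikes, .data$pn_id, .data$odor_id,
                             .data$trial, .data$spike_time_s)

    new_spike_dataset(
      spikes = spikes, panel = panel, windows = windows,
      n_trials = config$n_trials, n_pns = n_pns,
      truth = truth,
      pools = tibble::tibble(pn_id = seq_len(n_pns), pool = pool)
    )
  })
}

#' Assemble a spike dataset from a spike-time table
#'
#' Constructor for the container used by every electrophysiology stage.
#' Spike times are seconds relative to stimulus onset (onset = 0); windows
#' are half-open `[start, end)` intervals.
#'
#' @param spikes Tibble/data frame with columns `pn_id` (integer),
#'   `odor_id` (character), `trial` (integer in `1..n_trials`),
#'   `spike_time_s` (finite numeric).
#' @param panel Data frame with at least an `odor_id` column (one row per
#'   odor; `valence` and `por_prob` columns are carried through if present).
#' @param windows List with numeric length-2 entries `baseline`, `on`,
#'   `off` (non-overlapping, in seconds).
#' @param n_trials Trials per (PN, odor).
#' @param pn_ids Integer vector of PN identifiers; defaults to the sorted
#'   unique ids in `spikes`.
#' @return A `spike_dataset`.
#' @export
spike_dataset <- function(spikes, panel, windows, n_trials,
                          pn_ids = sort(unique(spikes$pn_id))) {
  spikes <- tibble::as_tibble(spikes)
  required <- c("pn_id", "odor_id", "trial", "spike_time_s")
  if (!all(required %in% names(spikes))) {
    abort("`spikes` needs columns pn_id, odor_id, trial, spike_time_s.")
  }
  if (!all(is.finite(spikes$spike_time_s))) abort("Spike times must be finite.")
  n_trials <- assert_count(n_trials)
  if (nrow(spikes) > 0 &&
      (any(spikes$trial < 1) || any(spikes$trial > n_trials))) {
    abort("Trial indices must lie in 1..n_trials.")
  }
  if (!all(c("baseline", "on", "off") %in% names(windows))) {
    abort("`windows` needs entries baseline, on, off.")
  }
  if (windows$baseline[2] > windows$on[1] || windows$on[2] > windows$off[1]) {
    abort("Windows must be non-overlapping and ordered.")
  }
  panel <- tibble::as_tibble(panel)
  if (!"odor_id" %in% names(panel)) abort("`panel` needs an odor_id column.")
  extra <- setdiff(unique(spikes$odor_id), panel$odor_id)
  if (length(extra) > 0) {
    abort(sprintf("Spike table has odors absent from the panel: %s",
                  paste(extra, collapse = ", ")))
  }
  ds <- new_spike_dataset(spikes = spikes, panel = panel,
                          windows = lapply(windows, as.numeric),
                          n_trials = n_trials, n_pns = length(pn_ids))
  ds$pn_ids <- as.integer(pn_ids)
  ds
}

new_spike_dataset <- function(spikes, panel, windows, n_trials, n_pns,
                              truth = NULL, pools = NULL) {
  structure(
    list(spikes = spikes, panel = panel, windows = windows,
         n_trials = n_trials, n_pns = n_pns, truth = truth, pools = pools),
    class = "spike_dataset"
  )
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset>\n")
  cat(sprintf("  %d PNs x %d odors x %d trials; %s spikes\n",
              x$n_pns, nrow(x$panel), x$n_trials,
              format(nrow(x$spikes), big.mark = ",")))
  cat(sprintf("  windows (s): baseline [%g, %g) | ON [%g, %g) | OFF [%g, %g)\n",
              x$windows$baseline[1], x$windows$baseline[2],
              x$windows$on[1], x$windows$on[2],
              x$windows$off[1], x$windows$off[2]))
  invisible(x)
}

#' Simulate palp-separation traces for the conditioning test phase
#'
#' Emulates 30 fps palp-tracking output for locusts tested (unrewarded) on
#' the four conditioning odorants after ON- or OFF-paradigm training.
#' Trained-appetitive odors evoke a smooth palp-opening excursion whose peak
#' falls inside the 4 s stimulus window (ON paradigm) or after stimulus
#' offset (OFF paradigm); non-appetitive odors stay at baseline. Gaussian
#' frame noise (s.d. `noise_sd`) is added and separation is clipped at zero.
#'
#' @param config A [synth_config()].
#' @param paradigm `"ON"` or `"OFF"` training paradigm.
#' @param odors Odor ids to test; defaults to [conditioning_odors()].
#' @param n_locusts Number of tested locusts (defaults to `config$n_locusts`).
#' @param fps Frames per second (default 30).
#' @param baseline_level Baseline palp separation in arbitrary units.
#' @param amplitude Mean response amplitude for appetitive odors (arb.u.).
#' @param noise_sd Frame-noise standard deviation (arb.u.).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble `locust_id`, `odor_id`, `frame`, `time_s`, `separation`
#'   with attributes `onset_s = 0`, `offset_s = 4`, `fps` (class
#'   `por_traces`). Time spans 2 s of pre-stimulus baseline through 4 s
#'   after odor offset.
#' @export
simulate_por_traces <- function(config,
                                paradigm = c("ON", "OFF"),
                                odors = conditioning_odors(),
                                n_locusts = config$n_locusts,
                                fps = 30,
                                baseline_level = 1,
                                amplitude = 12,
                                noise_sd = 1,
                                seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  paradigm <- match.arg(paradigm)
  panel <- config$odor_panel
  missing_odors <- setdiff(odors, panel$odor_id)
  if (length(missing_odors) > 0) {
    abort(sprintf("Odors not in panel: %s", paste(missing_odors, collapse = ", ")))
  }
  on_dur <- config$timing[["on"]]
  t <- seq(-2 + 1 / (2 * fps), on_dur + 4, by = 1 / fps)
  n_frames <- length(t)

  envelope <- function(valence) {
    if (valence != "appetitive") return(numeric(n_frames))
    if (paradigm == "ON") {
      # opens shortly after onset, peaks mid-stimulus, closes after offset
      sigmoid((t - 0.5) / 0.3) * sigmoid((on_dur + 0.5 - t) / 0.8)
    } else {
      # delayed opening; peak after stimulus offset
      sigmoid((t - (on_dur - 0.5)) / 0.5) * sigmoid((on_dur + 3.5 - t) / 0.8)
    }
  }

  withr::with_seed(seed, {
    rows <- tidyr::expand_grid(
      locust_id = sprintf("locust_%02d", seq_len(n_locusts)),
      odor_id = odors
    )
    traces <- purrr::pmap(rows, function(locust_id, odor_id) {
      valence <- panel$valence[panel$odor_id == odor_id]
      amp <- amplitude * runif(1, 0.8, 1.2)
      sep <- baseline_level + amp * envelope(valence) +
        rnorm(n_frames, sd = noise_sd)
      tibble::tibble(
        locust_id = locust_id, odor_id = odor_id,
        frame = seq_len(n_frames), time_s = t,
        separation = pmax(sep, 0)
      )
    })
    out <- dplyr::bind_rows(traces)
    structure(out, onset_s = 0, offset_s = on_dur, fps = fps,
              class = c("por_traces", class(out)))
  })
}
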