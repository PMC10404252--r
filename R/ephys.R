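#' Bin spike times into non-overlapping count bins
#'
#' Counts spikes per (PN, odor, trial) in half-open bins `[t, t + width)`
#' spanning the full baseline/ON/OFF protocol. Binning conserves spikes:
#' the bin counts of a trial sum to its number of in-window spikes.
#'
#' @param dataset A `spike_dataset` (see [simulate_pn_spikes()]).
#' @param bin_width Bin width in seconds (default 0.05, i.e. 50 ms).
#' @return A `binned_spikes` object: list with `counts` (4-d array
#'   PN x odor x trial x bin), `bin_starts`, `bin_width`, `windows`,
#'   `pn_ids`, `odor_ids`, `panel`, `n_trials`.
#' @export
bin_spikes <- function(dataset, bin_width = 0.05) {
  stopifnot(inherits(dataset, "spike_dataset"))
  assert_positive(bin_width)
  w <- dataset$windows
  t0 <- w$baseline[1]
  t1 <- w$off[2]
  n_bins_real <- (t1 - t0) / bin_width
  if (abs(n_bins_real - round(n_bins_real)) > 1e-9) {
    abort("`bin_width` must divide the total window span.")
  }
  n_bins <- as.integer(round(n_bins_real))
  pn_ids <- dataset$pn_ids %||% seq_len(dataset$n_pns)
  odor_ids <- dataset$panel$odor_id
  n_pns <- length(pn_ids)
  n_odors <- length(odor_ids)
  n_trials <- dataset$n_trials

  sp <- dataset$spikes
  keep <- sp$spike_time_s >= t0 & sp$spike_time_s < t1
  sp <- sp[keep, , drop = FALSE]
  pn_idx <- match(sp$pn_id, pn_ids)
  odor_idx <- match(sp$odor_id, odor_ids)
  if (anyNA(pn_idx) || anyNA(odor_idx)) {
    abort("Spike table contains PN or odor ids absent from the dataset index.")
  }
  if (any(sp$trial < 1 | sp$trial > n_trials)) {
    abort("Trial index outside 1..n_trials.")
  }
  # small tolerance keeps boundary spikes in the correct half-open bin
  bin_idx <- floor((sp$spike_time_s - t0) / bin_width + 1e-7) + 1L
  lin <- pn_idx +
    n_pns * ((odor_idx - 1L) +
               n_odors * ((sp$trial - 1L) + n_trials * (bin_idx - 1L)))
  counts <- array(
    tabulate(lin, nbins = n_pns * n_odors * n_trials * n_bins),
    dim = c(n_pns, n_odors, n_trials, n_bins)
  )
  structure(
    list(counts = counts,
         bin_starts = t0 + (seq_len(n_bins) - 1L) * bin_width,
         bin_width = bin_width, windows = w,
         pn_ids = pn_ids, odor_ids = odor_ids,
         panel = dataset$panel, n_trials = n_trials),
    class = "binned_spikes"
  )
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("<binned_spikes> %d PNs x %d odors x %d trials x %d bins (%g ms)\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              dim(x$counts)[4], 1000 * x$bin_width))
  invisible(x)
}

# trial-averaged counts: PN x odor x bin
trial_average <- function(binned) {
  stopifnot(inherits(binned, "binned_spikes"))
  d <- dim(binned$counts)
  out <- colMeans(aperm(binned$counts, c(3, 1, 2, 4)))
  array(out, dim = d[c(1, 2, 4)])
}

# bin selector for a named window ("baseline", "on", "off", "on_off", "all")
window_bins <- function(binned, window) {
  s <- binned$bin_starts
  w <- binned$windows
  switch(window,
    baseline = which(s >= w$baseline[1] & s < w$baseline[2]),
    on = which(s >= w$on[1] & s < w$on[2]),
    off = which(s >= w$off[1] & s < w$off[2]),
    on_off = which(s >= w$on[1] & s < w$off[2]),
    all = seq_along(s),
    abort(sprintf("Unknown window '%s'.", window))
  )
}

#' Trial-averaged PN-by-time response matrix
#'
#' Concatenates the trial-averaged binned responses of every odor into a
#' single PN x (bins per odor * odors) matrix -- the common currency of the
#' PCA, regression, and network-model stages. Columns are grouped by odor in
#' panel order.
#'
#' @param binned A [bin_spikes()] result.
#' @param window Which bins per odor: `"on"` (default), `"off"`, `"on_off"`,
#'   `"baseline"`, or `"all"`.
#' @return A numeric matrix with attributes `odor` (odor id per column),
#'   `time` (bin start per column), and `bins_per_odor`.
#' @export
as_response_matrix <- function(binned, window = "on") {
  bins <- window_bins(binned, window)
  avg <- trial_average(binned)[, , bins, drop = FALSE]
  d <- dim(avg)
  # columns odor-major: odor 1 bins, odor 2 bins, ...
  m <- matrix(aperm(avg, c(1, 3, 2)), nrow = d[1])
  rownames(m) <- as.character(binned$pn_ids)
  structure(m,
            odor = rep(binned$odor_ids, each = d[3]),
            time = rep(binned$bin_starts[bins], times = d[2]),
            bins_per_odor = d[3])
}

#' Classify PN responses as ON, OFF, inhibited, or none
#'
#' Implements the threshold classification of odor-evoked PN activity.
#' Per trial, a PN is ON-positive for an odor if any 50 ms ON-window bin
#' count exceeds the trial's baseline-bin mean by `sd_mult` baseline
#' standard deviations (baseline = the `baseline_s` seconds preceding the
#' stimulus); OFF-positive analogously on the OFF window; and
#' inhibited-positive if no ON bin exceeds baseline mean + `inhib_sd_mult`
#' s.d. and the mean ON rate is below the mean baseline rate. A label is
#' assigned when at least `min_trials` trials agree (five of ten by
#' default), with precedence ON > OFF > inhibited > none.
#'
#' By default the baseline mean and s.d. are pooled across all trials of a
#' (PN, odor) pair: at spontaneous rates of a few Hz, a single trial's 2 s
#' baseline contains too few spikes to estimate the null spread, and the
#' resulting degenerate thresholds push the rule's false-positive rate on
#' signal-free data above 1%; pooling keeps it far below that level.
#' `pooled_baseline = FALSE` restores strictly per-trial statistics.
#'
#' @param dataset A `spike_dataset`, or a prepared [bin_spikes()] object.
#' @param bin_width Classification bin width in seconds (default 0.05).
#' @param baseline_s Baseline span before onset used for the statistics
#'   (default 2 s).
#' @param sd_mult Excitation threshold in baseline s.d. (default 6.5).
#' @param inhib_sd_mult Ceiling for the inhibition criterion (default 2).
#' @param min_trials Trials required to assign a label; default
#'   `ceiling(n_trials / 2)`.
#' @param pooled_baseline If `TRUE` (default), baseline mean/s.d. are pooled
#'   across trials; if `FALSE` they are computed per trial.
#' @param sd_floor Baseline s.d. floor in count units (default 1e-6).
#' @return A tibble `pn_id`, `odor_id`, `label`, `n_on_trials`,
#'   `n_off_trials`, `n_inhibited_trials`.
#' @export
classify_pn_responses <- function(dataset,
                                  bin_width = 0.05,
                                  baseline_s = 2,
                                  sd_mult = 6.5,
                                  inhib_sd_mult = 2,
                                  min_trials = NULL,
                                  pooled_baseline = TRUE,
                                  sd_floor = 1e-6) {
  binned <- if (inherits(dataset, "binned_spikes")) dataset else {
    bin_spikes(dataset, bin_width)
  }
  counts <- binned$counts
  d <- dim(counts)
  n_trials <- d[3]
  min_trials <- min_trials %||% ceiling(n_trials / 2)

  base_bins <- which(binned$bin_starts >= -baseline_s & binned$bin_starts < 0)
  if (length(base_bins) < 2) abort("Need at least two baseline bins.")
  on_bins <- window_bins(binned, "on")
  off_bins <- window_bins(binned, "off")

  # rows = (pn, odor, trial), columns = bins
  m <- matrix(counts, nrow = d[1] * d[2] * d[3], ncol = d[4])
  bmat <- m[, base_bins, drop = FALSE]
  bmean <- rowMeans(bmat)
  bsd <- pmax(sqrt(pmax(rowMeans(bmat^2) - bmean^2, 0)) *
                sqrt(ncol(bmat) / (ncol(bmat) - 1)), sd_floor)
  if (pooled_baseline) {
    # pool the per-trial baseline bins of each (pn, odor) pair
    grp <- rep(seq_len(d[1] * d[2]), times = d[3])
    pooled_vals <- matrix(bmat, nrow = length(grp))
    gm <- rowsum(rowSums(pooled_vals), grp) / (d[3] * ncol(bmat))
    gs <- rowsum(rowSums(pooled_vals^2), grp) / (d[3] * ncol(bmat))
    nn <- d[3] * ncol(bmat)
    gsd <- pmax(sqrt(pmax(gs - gm^2, 0) * nn / (nn - 1)), sd_floor)
    bmean <- rep(gm[, 1], times = d[3])
    bsd <- rep(gsd[, 1], times = d[3])
  }

  on_max <- apply(m[, on_bins, drop = FALSE], 1, max)
  off_max <- apply(m[, off_bins, drop = FALSE], 1, max)
  on_mean <- rowMeans(m[, on_bins, drop = FALSE])

  trial_on <- on_max > bmean + sd_mult * bsd
  trial_off <- off_max > bmean + sd_mult * bsd
  trial_inh <- (on_max <= bmean + inhib_sd_mult * bsd) & (on_mean < bmean)

  grp <- rep(seq_len(d[1] * d[2]), times = d[3])
  n_on <- rowsum(as.integer(trial_on), grp)[, 1]
  n_off <- rowsum(as.integer(trial_off), grp)[, 1]
  n_inh <- rowsum(as.integer(trial_inh), grp)[, 1]

  label <- dplyr::case_when(
    n_on >= min_trials ~ "ON",
    n_off >= min_trials ~ "OFF",
    n_inh >= min_trials ~ "inhibited",
    TRUE ~ "none"
  )
  tibble::tibble(
    pn_id = rep(binned$pn_ids, times = d[2]),
    odor_id = rep(binned$odor_ids, each = d[1]),
    label = label,
    n_on_trials = n_on, n_off_trials = n_off, n_inhibited_trials = n_inh
  )
}

#' Drop PNs with inconsistent baseline firing
#'
#' Retains a PN only if its baseline firing rate (over the `window_s`
#' seconds before odor onset) in every trial of every odor is at least
#' `min_fraction` of that PN's maximum baseline rate -- a guard against
#' baseline drift and unit loss over a long recording. Trials with no
#' recorded spikes count as zero-rate trials, so a PN with missing trials is
#' excluded. The filter is idempotent.
#'
#' @param dataset A `spike_dataset`.
#' @param window_s Baseline span in seconds (default 4).
#' @param min_fraction Minimum trial-to-maximum baseline-rate ratio
#'   (default 0.15).
#' @return The dataset restricted to retained PNs, with a `consistency`
#'   attribute: tibble `pn_id`, `min_rate`, `max_rate`, `retained`.
#' @export
filter_consistent_pns <- function(dataset, window_s = 4, min_fraction = 0.15) {
  stopifnot(inherits(dataset, "spike_dataset"))
  pn_ids <- dataset$pn_ids %||% seq_len(dataset$n_pns)
  avail <- -dataset$windows$baseline[1]
  if (window_s > avail + 1e-9) {
    warn(sprintf(
      "Only %g s of pre-stimulus data available; using that instead of %g s.",
      avail, window_s))
    window_s <- avail
  }
  sp <- dataset$spikes
  in_base <- sp$spike_time_s >= -window_s & sp$spike_time_s < 0
  sp <- sp[in_base, , drop = FALSE]
  n_odors <- nrow(dataset$panel)
  n_trials <- dataset$n_trials
  pn_idx <- match(sp$pn_id, pn_ids)
  odor_idx <- match(sp$odor_id, dataset$panel$odor_id)
  lin <- pn_idx + length(pn_ids) *
    ((odor_idx - 1L) + n_odors * (sp$trial - 1L))
  counts <- array(
    tabulate(lin, nbins = length(pn_ids) * n_odors * n_trials),
    dim = c(length(pn_ids), n_odors * n_trials)
  )
  rates <- counts / window_s
  min_rate <- apply(rates, 1, min)
  max_rate <- apply(rates, 1, max)
  retained <- max_rate > 0 & min_rate >= min_fraction * max_rate
  summary <- tibble::tibble(
    pn_id = pn_ids, min_rate = min_rate, max_rate = max_rate,
    retained = retained
  )
  keep_ids <- pn_ids[retained]
  out <- dataset
  out$spikes <- dataset$spikes[dataset$spikes$pn_id %in% keep_ids, , drop = FALSE]
  out$pn_ids <- keep_ids
  out$n_pns <- length(keep_ids)
  if (!is.null(out$truth)) {
    out$truth <- out$truth[out$truth$pn_id %in% keep_ids, , drop = FALSE]
  }
  if (!is.null(out$pools)) {
    out$pools <- out$pools[out$pools$pn_id %in% keep_ids, , drop = FALSE]
  }
  attr(out, "consistency") <- summary
  out
}

#' Mean epoch activity per PN per odor
#'
#' Mean spike count over the full 4 s ON (or OFF) epoch for each PN and
#' odor, averaged across trials -- the feature matrix of the valence
#' regressor and the per-PN tuning/valence correlations.
#'
#' @param dataset A `spike_dataset` or `binned_spikes`.
#' @param epoch `"on"` or `"off"`.
#' @param bin_width Bin width used for the underlying binning (default 0.05).
#' @return A numeric matrix odors x PNs (rownames odor ids, colnames PN ids).
#' @export
valence_features <- function(dataset, epoch = c("on", "off"), bin_width = 0.05) {
  epoch <- match.arg(epoch)
  binned <- if (inherits(dataset, "binned_spikes")) dataset else {
    bin_spikes(dataset, bin_width)
  }
  bins <- window_bins(binned, epoch)
  avg <- trial_average(binned)[, , bins, drop = FALSE]
  totals <- apply(avg, c(1, 2), sum)  # PN x odor mean spike count in epoch
  m <- t(totals)
  dimnames(m) <- list(binned$odor_ids, as.character(binned$pn_ids))
  m
}

#' Per-PN tuning breadth and valence correlation
#'
#' For each PN: the number of odors it is classified ON- and OFF-responsive
#' to (tuning breadth), and the Pearson correlation between its mean
#' epoch-activity vector across the panel and the panel's behavioral
#' preference indices, separately for ON and OFF epochs. A PN with a
#' constant response vector has no defined correlation and is reported NA.
#'
#' @param classification Output of [classify_pn_responses()].
#' @param features_on,features_off Odors x PNs matrices from
#'   [valence_features()].
#' @param preference Numeric vector of preference indices named by odor id
#'   (or ordered as the feature rows).
#' @return A tibble `pn_id`, `n_on`, `n_off`, `r_on`, `r_off`.
#' @export
pn_tuning_stats <- function(classification, features_on, features_off,
                            preference) {
  stopifnot(nrow(features_on) == length(preference),
            nrow(features_off) == length(preference))
  if (!is.null(names(preference)) && !is.null(rownames(features_on))) {
    preference <- preference[rownames(features_on)]
  }
  counts <- classification |>
    dplyr::group_by(.data$pn_id) |>
    dplyr::summarise(
      n_on = sum(.data$label == "ON"),
      n_off = sum(.data$label == "OFF"),
      .groups = "drop"
    )
  pn_order <- as.character(counts$pn_id)
  r_on <- vapply(pn_order, function(p) safe_cor(features_on[, p], preference),
                 numeric(1))
  r_off <- vapply(pn_order, function(p) safe_cor(features_off[, p], preference),
                  numeric(1))
  dplyr::mutate(counts, r_on = unname(r_on), r_off = unname(r_off))
}
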