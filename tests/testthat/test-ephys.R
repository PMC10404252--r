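# naive loop reimplementation of the classification rule, used as an
# independent oracle against the vectorized classify_pn_responses()
classify_oracle <- function(binned, sd_mult = 6.5, inhib_sd_mult = 2,
                            baseline_s = 2, pooled = TRUE) {
  d <- dim(binned$counts)
  base_bins <- which(binned$bin_starts >= -baseline_s & binned$bin_starts < 0)
  on_bins <- which(binned$bin_starts >= 0 & binned$bin_starts < 4)
  off_bins <- which(binned$bin_starts >= 4 & binned$bin_starts < 8)
  min_trials <- ceiling(d[3] / 2)
  out <- list()
  for (p in seq_len(d[1])) {
    for (o in seq_len(d[2])) {
      n_on <- n_off <- n_inh <- 0
      pooled_b <- as.vector(binned$counts[p, o, , base_bins])
      for (tr in seq_len(d[3])) {
        b <- if (pooled) pooled_b else binned$counts[p, o, tr, base_bins]
        mu <- mean(b); s <- max(sd(b), 1e-6)
        on <- binned$counts[p, o, tr, on_bins]
        off <- binned$counts[p, o, tr, off_bins]
        if (any(on > mu + sd_mult * s)) n_on <- n_on + 1
        if (any(off > mu + sd_mult * s)) n_off <- n_off + 1
        if (all(on <= mu + inhib_sd_mult * s) && mean(on) < mu) n_inh <- n_inh + 1
      }
      label <- if (n_on >= min_trials) "ON" else if (n_off >= min_trials) {
        "OFF"
      } else if (n_inh >= min_trials) "inhibited" else "none"
      out[[length(out) + 1]] <- tibble::tibble(
        pn_id = binned$pn_ids[p], odor_id = binned$odor_ids[o], label = label)
    }
  }
  dplyr::bind_rows(out)
}

test_that("binning uses half-open bins and conserves spikes", {
  sp <- tibble::tibble(
    pn_id = 1L, odor_id = "hex", trial = 1L,
    spike_time_s = c(0.049, 0.050)
  )
  ds <- manual_dataset(sp)
  b <- bin_spikes(ds, 0.05)
  on_bins <- which(b$bin_starts >= 0)
  expect_equal(b$counts[1, 1, 1, on_bins[1]], 1)  # 0.049 in bin [0, 0.05)
  expect_equal(b$counts[1, 1, 1, on_bins[2]], 1)  # 0.050 in bin [0.05, 0.1)

  # 4 s ON window at 50 ms -> 80 bins; ON+OFF -> 160
  expect_length(which(b$bin_starts >= 0 & b$bin_starts < 4), 80)
  expect_length(which(b$bin_starts >= 0 & b$bin_starts < 8), 160)

  cfg <- small_config(seed = 21)
  ds2 <- simulate_pn_spikes(cfg)
  b2 <- bin_spikes(ds2, 0.05)
  in_window <- ds2$spikes$spike_time_s >= -4 & ds2$spikes$spike_time_s < 8
  expect_equal(sum(b2$counts), sum(in_window))
  expect_error(bin_spikes(ds2, -0.1), "positive")
  expect_error(bin_spikes(ds2, 0.07), "divide")
})

test_that("Poisson spike counts match their analytic rate", {
  cfg <- small_config(seed = 31, baseline_rate = 10, on_gain = 0,
                      off_gain = 0, cross_gain = 0, inhibition_prob = 0)
  ds <- simulate_pn_spikes(cfg)
  b <- bin_spikes(ds, 0.05)
  on_bins <- which(b$bin_starts >= 0 & b$bin_starts < 4)
  totals <- apply(b$counts[, , , on_bins], c(1, 2, 3), sum)
  # mean total over n independent Pois(40) trains within 3 s.e.
  n <- length(totals)
  expect_lt(abs(mean(totals) - 40), 3 * sqrt(40 / n))
})

test_that("response classification matches a naive loop oracle", {
  cfg <- small_config(seed = 41)
  b <- bin_spikes(simulate_pn_spikes(cfg), 0.05)
  for (pooled in c(TRUE, FALSE)) {
    fast <- classify_pn_responses(b, pooled_baseline = pooled)
    slow <- classify_oracle(b, pooled = pooled)
    joined <- dplyr::inner_join(fast, slow, by = c("pn_id", "odor_id"))
    expect_equal(nrow(joined), nrow(fast))
    expect_identical(joined$label.x, joined$label.y)
  }
})

test_that("hand-built firing patterns get the expected labels", {
  # empty spike trains: none
  empty <- manual_dataset(
    tibble::tibble(pn_id = integer(0), odor_id = character(0),
                   trial = integer(0), spike_time_s = numeric(0)),
    odor_ids = "hex", n_trials = 4, pn_ids = 1L)
  expect_true(all(classify_pn_responses(empty)$label == "none"))

  # baseline ~3 Hz, ON-window ~30 Hz in 6 of 10 trials: ON
  set.seed(1)
  mk_trial <- function(trial, on_rate) {
    base <- sort(runif(rpois(1, 3 * 4), -4, 0))
    on <- sort(runif(rpois(1, on_rate * 4), 0, 4))
    off <- sort(runif(rpois(1, 3 * 4), 4, 8))
    tibble::tibble(pn_id = 1L, odor_id = "hex", trial = trial,
                   spike_time_s = c(base, on, off))
  }
  sp <- dplyr::bind_rows(
    purrr::map(1:6, mk_trial, on_rate = 30),
    purrr::map(7:10, mk_trial, on_rate = 3)
  )
  cl <- classify_pn_responses(manual_dataset(sp, n_trials = 10))
  expect_identical(cl$label, "ON")
  expect_gte(cl$n_on_trials, 6)

  # baseline 10 Hz, complete ON suppression: inhibited
  sp2 <- dplyr::bind_rows(purrr::map(1:10, function(tr) {
    tibble::tibble(pn_id = 1L, odor_id = "hex", trial = tr,
                   spike_time_s = c(sort(runif(rpois(1, 40), -4, 0)),
                                    sort(runif(rpois(1, 40), 4, 8))))
  }))
  cl2 <- classify_pn_responses(manual_dataset(sp2, n_trials = 10))
  expect_identical(cl2$label, "inhibited")
})

test_that("the consistency filter applies the 15% rule and is idempotent", {
  # two PNs, steady 5 Hz baselines; PN 2 has one near-silent baseline trial
  mk <- function(pn, trial, rate) {
    tibble::tibble(pn_id = pn, odor_id = "hex", trial = trial,
                   spike_time_s = regular_train(rate, -4, 0))
  }
  sp <- dplyr::bind_rows(
    purrr::map(1:6, ~ mk(1L, .x, 5)),
    purrr::map(1:5, ~ mk(2L, .x, 5)),
    mk(2L, 6L, 0.25)  # 5% of its own max
  )
  ds <- manual_dataset(sp, n_trials = 6)
  kept <- filter_consistent_pns(ds)
  expect_equal(kept$pn_ids, 1L)
  summary <- attr(kept, "consistency")
  expect_false(summary$retained[summary$pn_id == 2])

  again <- filter_consistent_pns(kept)
  expect_equal(again$pn_ids, kept$pn_ids)
  expect_identical(again$spikes, kept$spikes)
})

test_that("tuning stats report breadth and valence correlation", {
  cl <- tibble::tibble(
    pn_id = rep(1:2, each = 3),
    odor_id = rep(c("a", "b", "c"), 2),
    label = c("ON", "ON", "none", "OFF", "none", "none")
  )
  pref <- c(a = 0.3, b = 0, c = -0.3)
  f_on <- cbind(`1` = c(3, 2, 1), `2` = c(1, 1, 1))
  rownames(f_on) <- c("a", "b", "c")
  f_off <- cbind(`1` = c(1, 2, 3), `2` = c(5, 3, 1))
  rownames(f_off) <- c("a", "b", "c")
  st <- pn_tuning_stats(cl, f_on, f_off, pref)
  expect_equal(st$n_on, c(2, 0))
  expect_equal(st$n_off, c(0, 1))
  expect_equal(st$r_on, c(1, NA))   # proportional; constant vector is NA
  expect_equal(st$r_off[1], -1)     # anti-proportional
})

test_that("the RMS chain has the stated rate, gain, and equivariance", {
  fs <- 15000
  n <- fs * 10
  zero <- rms_preprocess(rep(0, n), fs = fs, onset_s = 5)
  expect_equal(nrow(zero), 200)            # exactly 20 samples/s
  expect_true(all(zero$drms == 0))

  t <- seq_len(n) / fs
  sine <- 2 * sin(2 * pi * 1000 * t)
  out <- rms_preprocess(sine, fs = fs, onset_s = 5, baseline_subtract = FALSE)
  plateau <- median(out$drms[out$time_s > 1 & out$time_s < 9])
  expect_lt(abs(plateau - 2 / sqrt(2)) / (2 / sqrt(2)), 0.05)

  # amplitude equivariance holds once clipping is disabled
  set.seed(3)
  noise <- rnorm(n)
  a <- rms_preprocess(noise, fs = fs, onset_s = 5, clip_sd = Inf)
  b <- rms_preprocess(3 * noise, fs = fs, onset_s = 5, clip_sd = Inf)
  expect_equal(b$drms, 3 * a$drms, tolerance = 1e-8)

  expect_error(rms_preprocess(rep(0, 100), fs = fs, onset_s = 0.001),
               "warm-up")
})
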