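#' Partition PNs into two encoding ensembles
#'
#' Splits the population into Encoding Ensemble 1 (PNs responding more to
#' the appetitive reference odor, hexanol) and Encoding Ensemble 2 (PNs
#' responding more to the non-appetitive reference, benzaldehyde), based on
#' mean ON-window responses. Ties are assigned to whichever group is
#' currently smaller, and with `balance = TRUE` (default) PNs with the
#' smallest response differences -- those with no clear preference -- are
#' reassigned from the larger group until the two groups differ in size by
#' at most one, keeping the partition of nearly equal sizes. A fully
#' one-sided population is permitted but warned about.
#'
#' @param hex_response,bza_response Numeric vectors of mean ON responses per
#'   PN to the two reference odors.
#' @param balance Equalize group sizes by reassigning the least-committed
#'   PNs? Default `TRUE`.
#' @return Logical vector: `TRUE` for Ensemble 1 membership.
#' @export
partition_ensembles <- function(hex_response, bza_response, balance = TRUE) {
  stopifnot(length(hex_response) == length(bza_response))
  diff <- hex_response - bza_response
  e1 <- diff > 0
  ties <- which(diff == 0)
  if (length(ties) > 0) {
    # each tie joins whichever group is smaller at that point
    s1 <- sum(e1[-ties])
    s2 <- length(e1) - length(ties) - s1
    for (i in ties) {
      e1[i] <- s1 < s2
      if (e1[i]) s1 <- s1 + 1 else s2 <- s2 + 1
    }
  }
  if (balance) {
    excess <- sum(e1) - sum(!e1)
    if (abs(excess) > 1) {
      n_move <- abs(excess) %/% 2
      pool <- which(e1 == (excess > 0))
      move <- pool[order(abs(diff[pool]))[seq_len(n_move)]]
      e1[move] <- !e1[move]
    }
  }
  if (all(e1) || all(!e1)) {
    warn("Degenerate ensemble partition: every PN fell in one group.")
  }
  e1
}

#' Initialize the neuron/anti-neuron decoding network
#'
#' Builds the two-decoder feed-forward network from trial-averaged 50 ms
#' binned ensemble activity over the four conditioning odorants. Decoder
#' weights are least-squares solutions `W = (X X')^{-1} X Y'` for binary
#' targets marking the stimulus bins of the appetitive pair (hexanol,
#' isoamyl acetate; Decoding Neuron 1) and the non-appetitive pair
#' (benzaldehyde, citral; Decoding Neuron 2). The DN1 threshold is set
#' `epsilon` above the maximum pre-learning drive so DN1 is silent for every
#' odorant before conditioning; the DN2 threshold is half the maximum DN2
#' drive so the non-appetitive odors engage the suppressive pathway. Only
#' the Ensemble-1-to-DN1 connections are plastic (see [hebbian_update()]).
#'
#' @param dataset A `spike_dataset` covering the four odors.
#' @param odors The four conditioning odor ids (appetitive pair first).
#' @param appetitive The two appetitive odor ids among `odors`.
#' @param reference_pair Odors defining the ensemble partition and the
#'   plasticity masks, default `c(odors[1], odors[3])` (hexanol,
#'   benzaldehyde).
#' @param delta Hebbian learning rate (default 0.25).
#' @param epsilon Fractional margin of the DN1 threshold over the maximum
#'   pre-learning drive (default 0.01).
#' @param bin_width Bin width in seconds (default 0.05).
#' @param baseline_s Pre-stimulus span included per odor (default 2 s).
#' @param theta2_rule `"global"` (half of the overall maximum DN2 drive,
#'   default) or `"per_odor"` (half of the smallest per-odor maximum, a
#'   stricter variant).
#' @param classification Optional precomputed [classify_pn_responses()]
#'   table; computed from the dataset if absent.
#' @return A `hebbian_network`: list with the activity matrix `x`
#'   (PN x bins), per-bin `odor` and `time`, weights `w1`, `w2`, thresholds
#'   `theta1`, `theta2`, `ensemble1` mask, `responders` (PN x odor logical),
#'   `delta`, `epsilon`, `appetitive`, `pn_ids`, `updates` (log of applied
#'   conditioning steps).
#' @export
init_hebbian_network <- function(dataset,
                                 odors = conditioning_odors(),
                                 appetitive = odors[1:2],
                                 reference_pair = odors[c(1, 3)],
                                 delta = 0.25,
                                 epsilon = 0.01,
                                 bin_width = 0.05,
                                 baseline_s = 2,
                                 theta2_rule = c("global", "per_odor"),
                                 classification = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  theta2_rule <- match.arg(theta2_rule)
  assert_positive(delta, strict = FALSE)
  if (!all(odors %in% dataset$panel$odor_id)) abort("Odors missing from dataset.")

  binned <- bin_spikes(dataset, bin_width)
  keep <- which(binned$bin_starts >= -baseline_s)
  avg <- trial_average(binned)[, match(odors, binned$odor_ids), keep,
                               drop = FALSE]
  d <- dim(avg)
  x <- matrix(aperm(avg, c(1, 3, 2)), nrow = d[1])
  odor_col <- rep(odors, each = d[3])
  time_col <- rep(binned$bin_starts[keep], times = length(odors))
  on_col <- time_col >= dataset$windows$on[1] & time_col < dataset$windows$on[2]

  nonappetitive <- setdiff(odors, appetitive)
  y1 <- as.numeric(odor_col %in% appetitive & on_col)
  y2 <- as.numeric(odor_col %in% nonappetitive & on_col)

  g <- tcrossprod(x)
  if (rcond(g) < 1e-12) {
    lam <- 1e-8 * sum(diag(g)) / nrow(g)
    warn(sprintf("Singular X X'; ridge-stabilizing with lambda = %.3g.", lam))
    g <- g + diag(lam, nrow(g))
  }
  w1 <- solve(g, x %*% y1)[, 1]
  w2 <- solve(g, x %*% y2)[, 1]

  drive1 <- drop(crossprod(x, w1))
  drive2 <- drop(crossprod(x, w2))
  theta1 <- (1 + epsilon) * max(drive1)
  theta2 <- if (theta2_rule == "global") {
    0.5 * max(drive2)
  } else {
    0.5 * min(tapply(drive2, odor_col, max))
  }

  classification <- classification %||% classify_pn_responses(binned)
  responders <- vapply(odors, function(o) {
    lab <- classification$label[classification$odor_id == o]
    lab[match(binned$pn_ids, classification$pn_id[classification$odor_id == o])] == "ON"
  }, logical(d[1]))

  feats <- valence_features(binned, epoch = "on")
  ensemble1 <- partition_ensembles(feats[reference_pair[1], ],
                                   feats[reference_pair[2], ])

  structure(
    list(x = x, odor = odor_col, time = time_col,
         w1 = w1, w2 = w2, theta1 = theta1, theta2 = theta2,
         ensemble1 = ensemble1, responders = responders,
         delta = delta, epsilon = epsilon,
         appetitive = appetitive, odors = odors,
         pn_ids = binned$pn_ids, updates = character(0)),
    class = "hebbian_network"
  )
}

#' @export
print.hebbian_network <- function(x, ...) {
  cat(sprintf(
    "<hebbian_network> %d PNs (%d in Ensemble 1); theta1 %.3g, theta2 %.3g; delta %g\n",
    length(x$w1), sum(x$ensemble1), x$theta1, x$theta2, x$delta))
  if (length(x$updates)) {
    cat("  conditioned with:", paste(x$updates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hebbian conditioning update of the DN1 weights
#'
#' Applies the reward-gated Hebbian rule for one conditioning session:
#' `W1 <- W1 + delta * (mean reward-bin activity) * N_odor`, where the
#' reward signal is 1 only during the conditioned odor's stimulus bins and
#' `N_odor` masks PNs that are both in Encoding Ensemble 1 and
#' ON-responsive to the conditioned odor. All other connections (`W2`,
#' thresholds, Ensemble-2 weights) are untouched, so masked weights with
#' positive reward-bin activity never decrease and unmasked weights never
#' change.
#'
#' @param net A [init_hebbian_network()] result.
#' @param conditioned_odor One of the network's odors.
#' @param n_updates Number of update steps to apply (default 1; the
#'   six-trial session collapsed into one batch step). Larger values apply
#'   the same step repeatedly (per-trial mode).
#' @return The updated network.
#' @export
hebbian_update <- function(net, conditioned_odor, n_updates = 1) {
  stopifnot(inherits(net, "hebbian_network"))
  if (!conditioned_odor %in% net$odors) {
    abort(sprintf("Unknown conditioned odor '%s'.", conditioned_odor))
  }
  n_updates <- assert_count(n_updates)
  reward <- net$odor == conditioned_odor & net$time >= 0 & net$time < 4
  if (!any(reward)) return(net)  # reward gate never opens: no plasticity
  xbar <- rowMeans(net$x[, reward, drop = FALSE])
  mask <- net$ensemble1 & net$responders[, conditioned_odor]
  net$w1 <- net$w1 + n_updates * net$delta * xbar * as.numeric(mask)
  net$updates <- c(net$updates, rep(conditioned_odor, n_updates))
  net
}

#' Decoder and POR readout of the network
#'
#' Runs the network on its stored (or new) ensemble activity: each decoding
#' neuron outputs its thresholded linear drive,
#' `DN_i(t) = max(x(t)'W_i - theta_i, 0)`, and the motor readout is the
#' rectified neuron-minus-anti-neuron difference,
#' `POR(t) = max(DN1(t) - DN2(t), 0)`.
#'
#' @param net A `hebbian_network`.
#' @param odors Odors to simulate (default all four).
#' @return A tibble `odor_id`, `time`, `drive1`, `drive2`, `dn1`, `dn2`,
#'   `por`.
#' @export
simulate_por_readout <- function(net, odors = net$odors) {
  stopifnot(inherits(net, "hebbian_network"))
  cols <- net$odor %in% odors
  drive1 <- drop(crossprod(net$x[, cols, drop = FALSE], net$w1))
  drive2 <- drop(crossprod(net$x[, cols, drop = FALSE], net$w2))
  dn1 <- pmax(drive1 - net$theta1, 0)
  dn2 <- pmax(drive2 - net$theta2, 0)
  tibble::tibble(
    odor_id = net$odor[cols], time = net$time[cols],
    drive1 = drive1, drive2 = drive2,
    dn1 = dn1, dn2 = dn2, por = pmax(dn1 - dn2, 0)
  )
}
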