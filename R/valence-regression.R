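#' Fit the sigmoid-squashed linear valence regressor
#'
#' Learns a weight per PN plus a bias mapping mean odor-evoked ensemble
#' activity onto the probability of a palp-opening response:
#' `predicted POR = squash(sum_i w_i n_i + bias)`, with the logistic
#' sigmoid as the single-output squashing function so predictions always lie
#' in (0, 1). The mean-squared-error cost is minimized by full-batch
#' gradient descent from a zero initialization; the step size starts at
#' `learning_rate` and is adapted by backtracking (halved whenever a step
#' would increase the loss, mildly re-grown after accepted steps), so the
#' recorded loss trace is non-increasing. Training stops when the loss
#' improvement falls below `tol` or after `max_iter` iterations.
#'
#' @param features Numeric matrix, odors x PNs: mean spike counts over the
#'   chosen 4 s epoch (see [valence_features()]). No standardization is
#'   applied.
#' @param targets Numeric vector in `[0, 1]`, one normalized POR score per
#'   odor.
#' @param learning_rate Initial gradient-descent step (default 0.05).
#' @param max_iter Maximum iterations (default 10000).
#' @param tol Stop when the loss decrease is below this (default 1e-10).
#' @param epoch Label stored with the model (`"on"`, `"off"`, or other).
#' @return A `valence_regressor`: list with `weights`, `bias`, `epoch`,
#'   `loss_trace`, `iterations`, `converged`, `final_loss`.
#' @export
fit_valence_regressor <- function(features, targets,
                                  learning_rate = 0.05,
                                  max_iter = 10000,
                                  tol = 1e-10,
                                  epoch = "on") {
  x <- as.matrix(features)
  y <- as.numeric(targets)
  if (!all(is.finite(x))) abort("Non-finite feature values.")
  if (anyNA(y) || any(y < 0) || any(y > 1)) abort("Targets must lie in [0, 1].")
  if (nrow(x) != length(y)) abort("One target per odor (feature row) required.")
  if (nrow(x) < 2) abort("Need at least two training odors.")
  assert_positive(learning_rate)
  max_iter <- assert_count(max_iter)

  n <- nrow(x)
  w <- numeric(ncol(x))
  b <- 0
  lr <- learning_rate
  pred <- sigmoid(drop(x %*% w) + b)
  loss <- mean((pred - y)^2)
  trace <- numeric(max_iter + 1)
  trace[1] <- loss
  iter <- 0L
  converged <- FALSE

  while (iter < max_iter) {
    iter <- iter + 1L
    g <- 2 * (pred - y) * pred * (1 - pred) / n
    gw <- drop(crossprod(x, g))
    gb <- sum(g)
    # backtracking: shrink the step until the loss does not increase
    repeat {
      w_new <- w - lr * gw
      b_new <- b - lr * gb
      pred_new <- sigmoid(drop(x %*% w_new) + b_new)
      loss_new <- mean((pred_new - y)^2)
      if (loss_new <= loss || lr < 1e-16) break
      lr <- lr / 2
    }
    improvement <- loss - loss_new
    w <- w_new; b <- b_new; pred <- pred_new; loss <- loss_new
    trace[iter + 1] <- loss
    lr <- min(lr * 1.1, 1e6)
    if (improvement >= 0 && improvement < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(weights = setNames(w, colnames(x)), bias = b, epoch = epoch,
         loss_trace = trace[seq_len(iter + 1)], iterations = iter,
         converged = converged, final_loss = loss,
         learning_rate = learning_rate),
    class = "valence_regressor"
  )
}

#' @export
print.valence_regressor <- function(x, ...) {
  cat(sprintf(
    "<valence_regressor> %d PNs, epoch %s; loss %.3g after %d iterations%s\n",
    length(x$weights), x$epoch, x$final_loss, x$iterations,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
predict.valence_regressor <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  sigmoid(drop(x %*% object$weights) + object$bias)
}

#' Leave-one-odor-out cross-validated valence prediction
#'
#' Trains one regressor per odor on the remaining odors and predicts the
#' held-out odor's POR probability, yielding out-of-sample predictions for
#' the whole panel. The headline R-squared is the squared Pearson
#' correlation between predictions and targets; 1 - RSS/TSS is also
#' reported.
#'
#' @inheritParams fit_valence_regressor
#' @param ... Passed to [fit_valence_regressor()].
#' @return A `valence_loocv` object: list with `predictions` (tibble
#'   `odor_id`, `observed`, `predicted`), `r2` (correlation-squared),
#'   `r2_rss`, `mse`, `weights` (odors x PNs matrix of leave-out weight
#'   vectors), `epoch`.
#' @export
loocv_valence <- function(features, targets, epoch = "on", ...) {
  x <- as.matrix(features)
  y <- as.numeric(targets)
  if (nrow(x) < 3) abort("Leave-one-out needs at least three odors.")
  odor_ids <- rownames(x) %||% as.character(seq_len(nrow(x)))

  fits <- purrr::map(seq_len(nrow(x)), function(i) {
    fit <- fit_valence_regressor(x[-i, , drop = FALSE], y[-i],
                                 epoch = epoch, ...)
    list(pred = predict(fit, x[i, , drop = FALSE]), w = fit$weights)
  })
  pred <- vapply(fits, `[[`, numeric(1), "pred")
  weights <- do.call(rbind, purrr::map(fits, "w"))
  rownames(weights) <- odor_ids
  r <- safe_cor(pred, y)
  structure(
    list(
      predictions = tibble::tibble(odor_id = odor_ids, observed = y,
                                   predicted = pred),
      r2 = r^2,
      r2_rss = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
      mse = mean((y - pred)^2),
      weights = weights, epoch = epoch
    ),
    class = "valence_loocv"
  )
}

#' @export
print.valence_loocv <- function(x, ...) {
  cat(sprintf("<valence_loocv> %d odors, epoch %s; R2 = %.3f (MSE %.4f)\n",
              nrow(x$predictions), x$epoch, x$r2, x$mse))
  invisible(x)
}

#' Shuffled-target control for the valence regressor
#'
#' Permutes the behavioral targets across odors before training and runs
#' the same leave-one-out procedure. With the neural-to-behavior
#' correspondence destroyed, predictions concentrate near the mean target.
#'
#' @inheritParams loocv_valence
#' @param seed Integer seed for the permutation.
#' @return A `valence_loocv` object fit to the shuffled targets, with the
#'   permutation stored in `$permutation` and the unshuffled targets in
#'   `$original_targets`.
#' @export
shuffled_valence_control <- function(features, targets, seed = 1L,
                                     epoch = "on", ...) {
  y <- as.numeric(targets)
  perm <- withr::with_seed(seed, sample.int(length(y)))
  out <- loocv_valence(features, y[perm], epoch = epoch, ...)
  out$permutation <- perm
  out$original_targets <- y
  out
}

#' Consistency of regression weights within and across epochs
#'
#' Pairwise Pearson correlations among leave-one-out weight vectors,
#' within the ON set, within the OFF set, and between the two (the
#' cross-epoch block). Constant weight vectors are excluded with a notice.
#'
#' @param weights_on,weights_off Odors x PNs weight matrices (e.g.
#'   `$weights` of [loocv_valence()]); `weights_off` may be `NULL` for a
#'   single-epoch analysis.
#' @return A list with `cor_matrix` (full correlation matrix over all
#'   weight vectors), and a tibble `summary` of mean correlation per block
#'   (`within_on`, `within_off`, `cross`).
#' @export
weight_analysis <- function(weights_on, weights_off = NULL) {
  check <- function(w, label) {
    w <- as.matrix(w)
    keep <- apply(w, 1, sd) > 0
    if (!all(keep)) {
      inform(sprintf("Excluding %d constant weight vector(s) from %s.",
                     sum(!keep), label))
    }
    w[keep, , drop = FALSE]
  }
  won <- check(weights_on, "ON")
  all_w <- won
  block <- rep("on", nrow(won))
  if (!is.null(weights_off)) {
    woff <- check(weights_off, "OFF")
    if (ncol(woff) != ncol(won)) abort("Weight vectors must share PN order.")
    all_w <- rbind(won, woff)
    block <- c(block, rep("off", nrow(woff)))
  }
  cm <- cor(t(all_w))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  pair_block <- ifelse(
    block[pairs[, 1]] == "on" & block[pairs[, 2]] == "on", "within_on",
    ifelse(block[pairs[, 1]] == "off" & block[pairs[, 2]] == "off",
           "within_off", "cross"))
  summary <- tibble::tibble(block = pair_block, r = cm[pairs]) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(mean_r = mean(.data$r), n_pairs = dplyr::n(),
                     .groups = "drop")
  list(cor_matrix = cm, blocks = block, summary = summary)
}

#' Decoder performance as a function of PN count
#'
#' Monte Carlo subsampling of the PN population: for each draw, a random
#' subset of `n` PNs is taken and the leave-one-out procedure is rerun on
#' the reduced feature matrix; the mean squared prediction error is
#' averaged over draws. With `n` equal to the full population the single
#' possible subset reproduces the full-model LOOCV MSE exactly.
#'
#' @inheritParams loocv_valence
#' @param n_pns Integer vector of subset sizes.
#' @param n_sims Draws per size (default 100).
#' @param seed Integer seed.
#' @return A tibble `n_pns`, `mean_mse`, `sem_mse`, `n_draws`.
#' @export
mc_pn_subsample <- function(features, targets, n_pns, n_sims = 100,
                            seed = 1L, ...) {
  x <- as.matrix(features)
  total <- ncol(x)
  if (any(n_pns < 1) || any(n_pns > total)) {
    abort("Subset sizes must be between 1 and the number of PNs.")
  }
  withr::with_seed(seed, {
    purrr::map_dfr(n_pns, function(n) {
      draws <- if (n == total) 1L else n_sims
      mses <- vapply(seq_len(draws), function(i) {
        cols <- if (n == total) seq_len(total) else sample.int(total, n)
        loocv_valence(x[, cols, drop = FALSE], targets, ...)$mse
      }, numeric(1))
      tibble::tibble(
        n_pns = n, mean_mse = mean(mses),
        sem_mse = if (length(mses) > 1) sd(mses) / sqrt(length(mses)) else 0,
        n_draws = draws
      )
    })
  })
}
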