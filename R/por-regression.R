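#' Build the ensemble-activity-to-POR-dynamics design
#'
#' Assembles the regression problem mapping time-varying ensemble PN
#' activity onto mean palp-opening dynamics for the four conditioning
#' odorants: spiking is trial-averaged and binned at 10 Hz over 2 s
#' baseline + 4 s ON + 4 s OFF per odor (100 time points each), POR traces
#' are averaged across locusts and resampled from 30 fps to 10 Hz, and both
#' are concatenated across odors (89 x 400 inputs, 400 x 1 output for the
#' default panel sizes). Stimulus onset lands at column 21 of each
#' 100-column odor segment.
#'
#' @param dataset A `spike_dataset`.
#' @param traces A `por_traces` table covering the same odors (long format
#'   with `odor_id`, `time_s`, `separation`).
#' @param odors Odor ids, default [conditioning_odors()].
#' @param rate_hz Common sampling rate (default 10).
#' @param baseline_s Baseline span retained before onset (default 2).
#' @return A `por_design`: list with `x` (PNs x time matrix), `y` (response
#'   vector), `odors`, `bins_per_odor`, `time` (within-segment bin starts),
#'   `pn_ids`.
#' @export
build_por_design <- function(dataset, traces, odors = conditioning_odors(),
                             rate_hz = 10, baseline_s = 2) {
  stopifnot(inherits(dataset, "spike_dataset"))
  missing_spk <- setdiff(odors, dataset$panel$odor_id)
  missing_trc <- setdiff(odors, unique(traces$odor_id))
  if (length(missing_spk) || length(missing_trc)) {
    abort(sprintf("Odor sets do not match the design: missing %s",
                  paste(unique(c(missing_spk, missing_trc)), collapse = ", ")))
  }
  bw <- 1 / rate_hz
  binned <- bin_spikes(dataset, bw)
  seg_end <- dataset$windows$off[2]
  keep_bins <- which(binned$bin_starts >= -baseline_s &
                       binned$bin_starts < seg_end)
  avg <- trial_average(binned)[, match(odors, binned$odor_ids), keep_bins,
                               drop = FALSE]
  d <- dim(avg)
  x <- matrix(aperm(avg, c(1, 3, 2)), nrow = d[1])
  rownames(x) <- as.character(binned$pn_ids)

  fps <- attr(traces, "fps") %||% 30
  time_grid <- binned$bin_starts[keep_bins]
  y <- purrr::map(odors, function(o) {
    tr <- traces[traces$odor_id == o & traces$time_s >= -baseline_s &
                   traces$time_s < seg_end, , drop = FALSE]
    mean_trace <- tr |>
      dplyr::group_by(.data$time_s) |>
      dplyr::summarise(separation = mean(.data$separation), .groups = "drop")
    # 30 fps -> 10 Hz by averaging frames within each 100 ms bin
    idx <- findInterval(mean_trace$time_s, c(time_grid, seg_end),
                        rightmost.closed = FALSE)
    out <- rowsum(mean_trace$separation, idx)[, 1] /
      tabulate(idx, nbins = length(time_grid))
    if (length(out) != length(time_grid) || anyNA(out)) {
      abort(sprintf("Trace for odor '%s' does not cover the full window.", o))
    }
    out
  })
  structure(
    list(x = x, y = unlist(y, use.names = FALSE), odors = odors,
         bins_per_odor = length(time_grid), time = time_grid,
         pn_ids = binned$pn_ids),
    class = "por_design"
  )
}

#' @export
print.por_design <- function(x, ...) {
  cat(sprintf("<por_design> %d PNs x %d time points (%d odors x %d)\n",
              nrow(x$x), ncol(x$x), length(x$odors), x$bins_per_odor))
  invisible(x)
}

#' L1-regularized (lasso) fit of POR dynamics from ensemble activity
#'
#' Minimizes `(1/(2T)) * ||y - X'w - b||^2 + alpha * ||w||_1` over a weight
#' per PN and an unpenalized intercept (T = number of time points), the
#' scaling under which `alpha = 0.01` reproduces a sparse split of the
#' population into positively, negatively, and zero-weighted PNs. The
#' solution's subgradient (KKT) conditions are checked and the maximal
#' residual stored.
#'
#' @param design A [build_por_design()] result.
#' @param alpha L1 penalty strength (default 0.01).
#' @param paradigm Optional label for the training paradigm this model
#'   represents (e.g. `"hexanol_ON"`).
#' @return A `por_regressor`: list with `weights` (named per PN),
#'   `intercept`, `alpha`, `paradigm`, `kkt_residual`.
#' @export
fit_por_lasso <- function(design, alpha = 0.01, paradigm = NA_character_) {
  stopifnot(inherits(design, "por_design"))
  assert_positive(alpha)
  x <- t(design$x)
  y <- design$y
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("Non-finite design.")
  if (ncol(x) == 1) {
    # closed-form soft-thresholded solution for a single feature
    xc <- x[, 1] - mean(x[, 1])
    yc <- y - mean(y)
    t_len <- length(y)
    rho <- sum(xc * yc) / t_len
    denom <- sum(xc^2) / t_len
    w <- if (denom == 0) 0 else sign(rho) * max(abs(rho) - alpha, 0) / denom
    names(w) <- rownames(design$x)
    b <- mean(y) - w * mean(x[, 1])
  } else {
    fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                          lambda = alpha, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-14, maxit = 1e7)
    w <- as.numeric(fit$beta[, 1])
    names(w) <- rownames(design$x)
    b <- as.numeric(fit$a0[1])
  }
  structure(
    list(weights = w, intercept = b, alpha = alpha, paradigm = paradigm,
         kkt_residual = lasso_kkt_residual(design$x, y, w, b, alpha)),
    class = "por_regressor"
  )
}

# maximal violation of the lasso stationarity conditions:
# for w_j != 0, grad_j must equal alpha * sign(w_j); for w_j = 0,
# |grad_j| <= alpha; the intercept gradient (mean residual) must be 0.
lasso_kkt_residual <- function(x_pn_by_t, y, w, b, alpha) {
  t_len <- length(y)
  r <- y - drop(crossprod(x_pn_by_t, w)) - b
  g <- drop(x_pn_by_t %*% r) / t_len
  nz <- w != 0
  viol <- numeric(length(w))
  viol[nz] <- abs(g[nz] - alpha * sign(w[nz]))
  viol[!nz] <- pmax(0, abs(g[!nz]) - alpha)
  max(c(viol, abs(mean(r))))
}

#' @export
print.por_regressor <- function(x, ...) {
  cat(sprintf(
    "<por_regressor> alpha %.3g; %d+ / %d- / %d zero weights; KKT %.2g%s\n",
    x$alpha, sum(x$weights > 0), sum(x$weights < 0), sum(x$weights == 0),
    x$kkt_residual,
    if (is.na(x$paradigm)) "" else paste0("; ", x$paradigm)))
  invisible(x)
}

#' Predict POR dynamics and score them against the observed traces
#'
#' Applies a fitted lasso model to a design, returning the predicted
#' concatenated POR trace plus, per odor segment and for the whole trace,
#' the Pearson correlation with the observed response and its two-sided
#' t-test P-value on segment-length-minus-2 degrees of freedom.
#'
#' @param model A [fit_por_lasso()] result.
#' @param design A [build_por_design()] result (may differ from the
#'   training design, e.g. for cross-paradigm prediction).
#' @return A `por_prediction`: list with `trace` (tibble `odor_id`, `time`,
#'   `observed`, `predicted`), `by_odor` (tibble `odor_id`, `r`, `df`,
#'   `p_value`), `overall_r`.
#' @export
predict_por <- function(model, design) {
  stopifnot(inherits(model, "por_regressor"), inherits(design, "por_design"))
  if (nrow(design$x) != length(model$weights)) {
    abort("Model and design are dimensionally incompatible.")
  }
  yhat <- drop(crossprod(design$x, model$weights)) + model$intercept
  seg <- rep(design$odors, each = design$bins_per_odor)
  trace <- tibble::tibble(
    odor_id = seg,
    time = rep(design$time, times = length(design$odors)),
    observed = design$y, predicted = yhat
  )
  by_odor <- trace |>
    dplyr::group_by(.data$odor_id) |>
    dplyr::summarise(
      r = safe_cor(.data$observed, .data$predicted),
      df = dplyr::n() - 2L,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_value = 2 * pt(abs(.data$r) * sqrt(.data$df / (1 - .data$r^2)),
                       df = .data$df, lower.tail = FALSE)
    ) |>
    dplyr::arrange(match(.data$odor_id, design$odors))
  structure(
    list(trace = trace, by_odor = by_odor,
         overall_r = safe_cor(design$y, yhat)),
    class = "por_prediction"
  )
}

#' Dissect a family of POR-dynamics models by weight sign
#'
#' Averages the per-PN lasso weights across a set of trained models (one
#' per conditioning paradigm), assigns each PN to a positive, negative, or
#' zero group, and summarizes: pairwise correlations between the models'
#' weight vectors, the mean population firing time course of each sign
#' group, and the per-odor correlation between a PN's mean ON-window rate
#' and its average weight within each sign group.
#'
#' @param models List of [fit_por_lasso()] results sharing PN order.
#' @param design A [build_por_design()] result supplying the rate time
#'   courses.
#' @param zero_tol Magnitude below which a mean weight counts as zero
#'   (default 1e-10).
#' @return A list with `pn_groups` (tibble `pn_id`, `mean_weight`,
#'   `group`), `pairwise` (tibble `model_a`, `model_b`, `r`), `group_psth`
#'   (tibble `group`, `odor_id`, `time`, `mean_rate`), and
#'   `rate_weight_cor` (tibble `group`, `odor_id`, `r`).
#' @export
weight_dissection <- function(models, design, zero_tol = 1e-10) {
  stopifnot(length(models) >= 2, inherits(design, "por_design"))
  wmat <- do.call(rbind, purrr::map(models, "weights"))
  ids <- purrr::map(models, ~ names(.x$weights))
  if (!all(purrr::map_lgl(ids, identical, ids[[1]]))) {
    abort("Models do not share PN order.")
  }
  labels <- purrr::imap_chr(models, function(m, i) {
    if (is.na(m$paradigm)) paste0("model_", i) else m$paradigm
  })
  rownames(wmat) <- labels

  mean_w <- colMeans(wmat)
  group <- dplyr::case_when(
    abs(mean_w) <= zero_tol ~ "zero",
    mean_w > 0 ~ "positive",
    TRUE ~ "negative"
  )
  pn_groups <- tibble::tibble(pn_id = names(mean_w),
                              mean_weight = unname(mean_w), group = group)

  cm <- cor(t(wmat))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  pairwise <- tibble::tibble(
    model_a = labels[pairs[, 1]], model_b = labels[pairs[, 2]],
    r = cm[pairs]
  )

  seg <- rep(design$odors, each = design$bins_per_odor)
  time <- rep(design$time, times = length(design$odors))
  group_psth <- purrr::map_dfr(c("positive", "negative"), function(gr) {
    rows <- which(group == gr)
    if (length(rows) == 0) return(tibble::tibble())
    rate <- colMeans(design$x[rows, , drop = FALSE])
    tibble::tibble(group = gr, odor_id = seg, time = time, mean_rate = rate)
  })

  on_cols <- time >= 0 & time < 4
  rate_weight_cor <- purrr::map_dfr(c("positive", "negative"), function(gr) {
    rows <- which(group == gr)
    if (length(rows) < 3) return(tibble::tibble())
    purrr::map_dfr(design$odors, function(o) {
      cols <- seg == o & on_cols
      mean_rate <- rowMeans(design$x[rows, cols, drop = FALSE])
      tibble::tibble(group = gr, odor_id = o,
                     r = safe_cor(mean_rate, mean_w[rows]))
    })
  })

  list(pn_groups = pn_groups, pairwise = pairwise,
       group_psth = group_psth, rate_weight_cor = rate_weight_cor,
       weight_matrix = wmat)
}
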