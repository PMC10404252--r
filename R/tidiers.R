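# broom-style tidiers for the fitted objects

#' @export
tidy.valence_regressor <- function(x, ...) {
  tibble::tibble(
    term = names(x$weights) %||% as.character(seq_along(x$weights)),
    estimate = unname(x$weights)
  )
}

#' @export
glance.valence_regressor <- function(x, ...) {
  tibble::tibble(
    final_loss = x$final_loss, iterations = x$iterations,
    converged = x$converged, bias = x$bias, epoch = x$epoch
  )
}

#' @export
tidy.valence_loocv <- function(x, ...) x$predictions

#' @export
glance.valence_loocv <- function(x, ...) {
  tibble::tibble(r2 = x$r2, r2_rss = x$r2_rss, mse = x$mse, epoch = x$epoch,
                 n_odors = nrow(x$predictions))
}

#' @export
tidy.por_regressor <- function(x, ...) {
  tibble::tibble(
    term = names(x$weights) %||% as.character(seq_along(x$weights)),
    estimate = unname(x$weights)
  )
}

#' @export
glance.por_regressor <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, intercept = x$intercept,
    n_positive = sum(x$weights > 0), n_negative = sum(x$weights < 0),
    n_zero = sum(x$weights == 0), kkt_residual = x$kkt_residual,
    paradigm = x$paradigm
  )
}

#' @export
tidy.pn_trajectories <- function(x, ...) x$scores

#' @export
glance.pn_trajectories <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    variance_captured = sum(x$variance_explained)
  )
}

#' @export
tidy.hebbian_network <- function(x, ...) {
  tibble::tibble(
    pn_id = x$pn_ids, w1 = unname(x$w1), w2 = unname(x$w2),
    ensemble1 = x$ensemble1
  )
}

#' @export
glance.hebbian_network <- function(x, ...) {
  tibble::tibble(
    theta1 = x$theta1, theta2 = x$theta2, delta = x$delta,
    n_ensemble1 = sum(x$ensemble1), n_pns = length(x$w1),
    n_updates = length(x$updates)
  )
}
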