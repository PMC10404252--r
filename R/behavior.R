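# coerce a POR table (tibble with locust_id column, data frame, or matrix)
# to a binary locusts x odors matrix
por_as_matrix <- function(por) {
  if (is.data.frame(por)) {
    df <- as.data.frame(por)
    if ("locust_id" %in% names(df)) {
      rownames(df) <- df$locust_id
      df$locust_id <- NULL
    }
    por <- as.matrix(df)
  }
  if (!is.numeric(por)) abort("POR matrix must be numeric 0/1.")
  if (nrow(por) < 1 || ncol(por) < 1) abort("POR matrix is empty.")
  if (anyNA(por)) abort("POR matrix has missing cells.")
  if (!all(por %in% c(0, 1))) abort("POR matrix entries must be 0 or 1.")
  if (is.null(colnames(por))) colnames(por) <- sprintf("odor_%02d", seq_len(ncol(por)))
  por
}

#' Per-odor POR scores and preference indices
#'
#' Summarizes a binary locusts-by-odors palp-opening-response matrix into the
#' per-odor total score (column sum), normalized score (fraction of locusts
#' responding, i.e. the POR probability), and the preference index obtained
#' by subtracting the across-odor median of the normalized scores. By
#' construction the median odor has a preference index of zero and indices
#' straddle zero.
#'
#' @param por A POR table: tibble with a `locust_id` column plus one 0/1
#'   column per odor (as returned by [simulate_por_matrix()]), or a plain
#'   binary matrix/data frame.
#' @return A tibble `odor_id`, `total`, `norm_score`, `preference_index`, in
#'   panel column order.
#' @export
#' @examples
#' m <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 0, 1))
#' colnames(m) <- c("a", "b", "c")
#' por_scores(m)
por_scores <- function(por) {
  m <- por_as_matrix(por)
  total <- colSums(m)
  norm_score <- total / nrow(m)
  tibble::tibble(
    odor_id = colnames(m),
    total = unname(total),
    norm_score = unname(norm_score),
    preference_index = unname(norm_score - median(norm_score))
  )
}

#' Classify odors as appetitive, neutral or unappetitive
#'
#' One-sided exact binomial tests of each odor's total POR score against a
#' null response probability (by default the across-odor median normalized
#' score, i.e. a test for significant deviation from the median response).
#' An odor is appetitive if its upper-tail P-value is below `alpha`,
#' unappetitive if its lower-tail P-value is below `alpha`, and neutral
#' otherwise.
#'
#' @inheritParams por_scores
#' @param alpha One-sided significance level (default 0.1).
#' @param null_prob Null POR probability: `"median"` (default) uses the
#'   median normalized score across odors; `"half"` uses 0.5; or supply a
#'   number in (0, 1).
#' @return A tibble `odor_id`, `total`, `norm_score`, `p_upper`, `p_lower`,
#'   `valence_class`.
#' @export
classify_valence <- function(por, alpha = 0.1, null_prob = "median") {
  m <- por_as_matrix(por)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  scores <- por_scores(m)
  p0 <- if (identical(null_prob, "median")) {
    median(scores$norm_score)
  } else if (identical(null_prob, "half")) {
    0.5
  } else {
    assert_probability(null_prob)
    null_prob
  }
  n <- nrow(m)
  # exact binomial tails: P(X >= total) and P(X <= total) under Binom(n, p0)
  p_upper <- pbinom(scores$total - 1, n, p0, lower.tail = FALSE)
  p_lower <- pbinom(scores$total, n, p0)
  cls <- dplyr::case_when(
    p_upper < alpha ~ "appetitive",
    p_lower < alpha ~ "unappetitive",
    TRUE ~ "neutral"
  )
  dplyr::mutate(scores, p_upper = p_upper, p_lower = p_lower,
                valence_class = cls, .keep = "all")
}

#' Stability of preference indices under locust subsampling
#'
#' Monte Carlo check that population-level preference indices are not driven
#' by a handful of individuals: for each subset size, draw `n_sims` random
#' locust subsets (without replacement), recompute preference indices, and
#' correlate them (Pearson) with the full-sample indices. Reports the mean
#' and s.e.m. of the squared correlation per subset size. A draw whose
#' subset indices are constant across odors has no defined correlation and
#' is dropped (counted in `n_dropped`).
#'
#' @inheritParams por_scores
#' @param sizes Integer vector of subset sizes (default 1 to the number of
#'   locusts).
#' @param n_sims Simulations per size (default 100).
#' @param seed Integer seed.
#' @return A tibble `n`, `mean_r2`, `sem_r2`, `n_draws`, `n_dropped`.
#' @export
mc_locust_subsample <- function(por, sizes = NULL, n_sims = 100, seed = 1L) {
  m <- por_as_matrix(por)
  n_locusts <- nrow(m)
  sizes <- sizes %||% seq_len(n_locusts)
  if (any(sizes < 1) || any(sizes > n_locusts)) {
    abort("Subset sizes must be between 1 and the number of locusts.")
  }
  n_sims <- assert_count(n_sims)
  full_index <- por_scores(m)$preference_index

  withr::with_seed(seed, {
    purrr::map_dfr(sizes, function(n) {
      r2 <- vapply(seq_len(n_sims), function(i) {
        if (n == n_locusts) return(1)  # the subset is the full sample
        sub <- m[sample.int(n_locusts, n), , drop = FALSE]
        idx <- colSums(sub) / n
        idx <- idx - median(idx)
        r <- safe_cor(idx, full_index)
        r^2
      }, numeric(1))
      kept <- r2[!is.na(r2)]
      tibble::tibble(
        n = n,
        mean_r2 = mean(kept),
        sem_r2 = if (length(kept) > 1) sd(kept) / sqrt(length(kept)) else 0,
        n_draws = length(kept),
        n_dropped = sum(is.na(r2))
      )
    })
  })
}

#' Ordinary least-squares linear trend
#'
#' Simple OLS fit of `y` on `x` with the coefficient of determination,
#' used for covariate-vs-response trend checks (e.g. vapor pressure vs POR
#' counts, POR counts vs trial number).
#'
#' @param data A data frame containing the two variables.
#' @param x,y Column names (unquoted) of the covariate and response.
#' @return A one-row tibble `slope`, `intercept`, `r_squared`, `n`.
#' @export
#' @examples
#' linear_trend(data.frame(t = 1:5, y = 2 * (1:5) + 1), t, y)
linear_trend <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) != length(yv) || length(xv) < 3) {
    abort("Need equal-length x and y with at least 3 points.")
  }
  if (sd(xv) == 0) abort("Constant covariate: trend is undefined.")
  fit <- lm(yv ~ xv)
  rss <- sum(fit$residuals^2)
  tss <- sum((yv - mean(yv))^2)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (tss == 0) NA_real_ else 1 - rss / tss,
    n = length(xv)
  )
}
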