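# exact binomial tails by direct summation -- independent of pbinom()
binom_upper_tail <- function(total, n, p) {
  sum(vapply(total:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}
binom_lower_tail <- function(total, n, p) {
  sum(vapply(0:total, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

test_that("scores and preference indices match hand-evaluated values", {
  m <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 0, 1))
  colnames(m) <- c("a", "b", "c")
  s <- por_scores(m)
  expect_equal(s$total, c(3, 1, 1))
  expect_equal(s$norm_score, c(1, 1 / 3, 1 / 3))
  expect_equal(s$preference_index, c(2 / 3, 0, 0))

  ones <- matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  s1 <- por_scores(ones)
  expect_equal(s1$norm_score, rep(1, 3))
  expect_equal(s1$preference_index, rep(0, 3))

  # the median odor always sits at index zero; norm scores stay in [0, 1]
  set.seed(42)
  for (i in 1:20) {
    r <- matrix(rbinom(8 * 5, 1, runif(1, 0.2, 0.8)), 8, 5,
                dimnames = list(NULL, letters[1:5]))
    sr <- por_scores(r)
    expect_true(all(sr$norm_score >= 0 & sr$norm_score <= 1))
    # with an odd panel the median odor's index is exactly zero
    expect_true(any(abs(sr$preference_index) < 1e-12))
    expect_equal(median(sr$preference_index), 0)
  }

  expect_error(por_scores(matrix(numeric(0), 0, 0)), "empty")
})

test_that("valence calls agree with exhaustive binomial tail enumeration", {
  # all (n <= 12, total) pairs at several null probabilities
  for (n in c(4, 8, 12)) {
    for (p0 in c(0.25, 0.4, 0.5)) {
      for (total in 0:n) {
        up <- pbinom(total - 1, n, p0, lower.tail = FALSE)
        lo <- pbinom(total, n, p0)
        expect_equal(up, binom_upper_tail(total, n, p0), tolerance = 1e-12)
        expect_equal(lo, binom_lower_tail(total, n, p0), tolerance = 1e-12)
      }
    }
  }

  # n = 26, median norm score 0.4: total 18 is appetitive, 0 unappetitive
  m <- matrix(0, 26, 5, dimnames = list(NULL, c("a", "b", "c", "d", "e")))
  m[1:18, "a"] <- 1                      # strong responder
  m[, "b"] <- rep(c(1, 0), c(10, 16))    # 10/26
  m[, "c"] <- rep(c(1, 0), c(10, 16))
  m[, "d"] <- rep(c(1, 0), c(12, 14))
  # column e stays 0
  calls <- classify_valence(m, alpha = 0.1)
  p0 <- median(colSums(m) / 26)
  expect_equal(p0, 10 / 26)
  expect_lt(binom_upper_tail(18, 26, p0), 0.1)
  expect_identical(calls$valence_class[calls$odor_id == "a"], "appetitive")
  expect_lt(binom_lower_tail(0, 26, p0), 0.1)
  expect_identical(calls$valence_class[calls$odor_id == "e"], "unappetitive")

  # an odor at the median expectation is neutral
  expect_identical(calls$valence_class[calls$odor_id == "b"], "neutral")

  # a fully identical matrix yields all-neutral calls without error
  flat <- matrix(1, 6, 4, dimnames = list(NULL, letters[1:4]))
  expect_true(all(classify_valence(flat)$valence_class == "neutral"))
})

test_that("subsampling the full cohort reproduces the indices exactly", {
  m <- simulate_por_matrix(small_config(seed = 10))
  full <- mc_locust_subsample(m, sizes = 12, n_sims = 25, seed = 1)
  expect_equal(full$mean_r2, 1)
  expect_equal(full$sem_r2, 0)
  expect_error(mc_locust_subsample(m, sizes = 0), "between")
})

test_that("linear trends match the closed-form normal equations", {
  d <- data.frame(x = 1:6, y = 3 * (1:6) - 2)
  fit <- linear_trend(d, x, y)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 3)
  expect_equal(fit$intercept, -2)

  set.seed(7)
  r <- data.frame(x = rnorm(10), y = rnorm(10))
  fit2 <- linear_trend(r, x, y)
  # normal-equations oracle
  X <- cbind(1, r$x)
  beta <- solve(t(X) %*% X, t(X) %*% r$y)
  expect_equal(fit2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit2$slope, beta[2], tolerance = 1e-10)

  expect_error(linear_trend(data.frame(x = rep(1, 5), y = 1:5), x, y),
               "Constant")
})

test_that("POR detection applies the 6.5-sd, 30-frame, and 1.5-unit rules", {
  expect_false(detect_por_response(flat_trace()))

  # 1.2 s excursion (36 frames) to 2.0 units: above threshold and gate
  expect_true(detect_por_response(excursion_trace(2.0, 1.2)))
  # same excursion lasting 0.8 s (24 frames): too short
  expect_false(detect_por_response(excursion_trace(2.0, 0.8)))
  # above the sd threshold but below the 1.5-unit absolute gate
  expect_false(detect_por_response(excursion_trace(1.4, 1.2)))
  # with the gate disabled the same trace is a response
  expect_true(detect_por_response(excursion_trace(1.4, 1.2),
                                  min_separation = 0))

  # the absolute gate breaks scale invariance; without it, scaling is safe
  tr <- excursion_trace(2.0, 1.2)
  shrunk <- dplyr::mutate(tr, separation = separation * 0.1)
  expect_true(detect_por_response(tr))
  expect_false(detect_por_response(shrunk))
  expect_equal(detect_por_response(tr, min_separation = 0),
               detect_por_response(shrunk, min_separation = 0))

  # contiguity flag: 30 scattered frames pass by default, fail contiguously
  tr2 <- flat_trace()
  tr2$separation <- tr2$separation + rep(c(-0.01, 0.01), length.out = nrow(tr2))
  scattered <- which(tr2$time_s >= 0)[seq(1, 120, by = 4)][1:30]
  tr2$separation[scattered] <- 2
  expect_true(detect_por_response(tr2))
  expect_false(detect_por_response(tr2, contiguous = TRUE))
})

test_that("per-locust normalization is affine and offset-invariant", {
  tr <- tibble::tibble(
    locust_id = "l1", odor_id = rep(c("a", "b"), each = 5),
    separation = c(2, 4, 6, 8, 10, 2, 3, 4, 5, 6)
  )
  norm <- normalize_traces(tr)
  expect_equal(min(norm$separation), 0)
  expect_equal(max(norm$separation), 1)
  expect_equal(norm$separation[3], 0.5)  # midpoint of the 2..10 range

  set.seed(11)
  for (offset in rnorm(5, sd = 10)) {
    shifted <- dplyr::mutate(tr, separation = separation + offset)
    expect_equal(normalize_traces(shifted)$separation, norm$separation)
  }

  flat <- tibble::tibble(locust_id = "l2", odor_id = "a",
                         separation = rep(3, 10))
  expect_warning(out <- normalize_traces(flat), "zero")
  expect_true(all(out$separation == 0))
  expect_true(all(out$flat))
})
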