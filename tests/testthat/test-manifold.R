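# exhaustive complete-linkage agglomeration on a correlation-distance
# matrix: at each step scan every cluster pair for the smallest maximal
# pairwise distance -- an independent oracle for cluster_odors()
agglomerate_oracle <- function(m) {
  d <- 1 - cor(t(m))
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
      height = best_h
    )
    clusters[[best[2]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[1]]] <- NULL
  }
  merges
}

test_that("PCA trajectories agree with an SVD oracle and conserve variance", {
  set.seed(5)
  m <- matrix(rnorm(5 * 40), 5, 40)
  odor <- rep(c("a", "b"), each = 20)
  res <- pca_trajectories(m, n_components = 3, odor = odor,
                          baseline_subtract = FALSE, smooth = FALSE)

  # oracle: prcomp on the transposed matrix (SVD route, no eigen())
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  for (k in 1:3) {
    ours <- res$scores$value[res$scores$component == k]
    theirs <- pc$x[, k]
    expect_lt(min(max(abs(ours - theirs)), max(abs(ours + theirs))), 1e-8)
  }
  expect_equal(res$eigenvalues, unname(pc$sdev^2), tolerance = 1e-8)

  # trace conservation: eigenvalue sum equals total variance over PNs
  expect_equal(sum(res$eigenvalues), sum(apply(m, 1, var)), tolerance = 1e-10)

  # projections are invariant to PN ordering
  perm <- sample(5)
  res_p <- pca_trajectories(m[perm, ], n_components = 3, odor = odor,
                            baseline_subtract = FALSE, smooth = FALSE)
  expect_equal(abs(res_p$scores$value), abs(res$scores$value),
               tolerance = 1e-8)

  # a one-directional dataset loads everything on PC1
  u <- rnorm(6)
  one <- outer(u, seq(0.1, 4, length.out = 30))
  res1 <- pca_trajectories(one, n_components = 2, odor = rep("a", 30))
  expect_equal(res1$variance_explained[1], 1, tolerance = 1e-12)
  expect_equal(res1$variance_explained[2], 0, tolerance = 1e-12)
})

test_that("complete-linkage trees match exhaustive agglomeration", {
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(rnorm(4 * 12), 4, 12)
    rownames(m) <- letters[1:4]
    hc <- cluster_odors(m)
    oracle <- agglomerate_oracle(m)
    # same merge heights
    expect_equal(hc$height, purrr::map_dbl(oracle, "height"),
                 tolerance = 1e-10)
    # same cluster composition at every merge
    for (step in seq_along(oracle)) {
      ct <- cutree(hc, h = oracle[[step]]$height + 1e-9)
      members <- sort(unname(which(ct == ct[oracle[[step]]$members[1]])))
      expect_equal(members, oracle[[step]]$members)
    }
  }

  # identical vectors merge at height zero
  two <- rbind(a = c(1, 2, 3, 1), b = c(1, 2, 3, 1), c = c(3, 1, 0, 5))
  hc2 <- cluster_odors(two)
  expect_equal(min(hc2$height), 0, tolerance = 1e-12)

  const <- rbind(a = rep(1, 4), b = c(1, 2, 3, 4))
  expect_error(cluster_odors(const), "Constant.*a")
})

test_that("angle scores match a naive double loop and its symmetries", {
  set.seed(13)
  m <- matrix(abs(rnorm(6 * 10)), 6, 10)
  rownames(m) <- paste0("o", 1:6)
  labels <- c("appetitive", "appetitive", "appetitive",
              "non-appetitive", "non-appetitive", "non-appetitive")
  res <- valence_angle_scores(m, labels)

  angle <- function(u, v) {
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  for (i in 1:6) {
    app <- nonapp <- c()
    for (j in 1:6) {
      if (j == i) next
      a <- angle(m[i, ], m[j, ])
      if (labels[j] == "appetitive") app <- c(app, a) else nonapp <- c(nonapp, a)
    }
    expect_equal(res$net_score[i], mean(nonapp) - mean(app),
                 tolerance = 1e-10)
  }

  # swapping the group labels negates every net score
  swapped <- valence_angle_scores(
    m, ifelse(labels == "appetitive", "non-appetitive", "appetitive"))
  expect_equal(swapped$net_score, -res$net_score, tolerance = 1e-10)

  # positive rescaling of any vector leaves scores unchanged
  m2 <- m
  m2[2, ] <- 7.3 * m2[2, ]
  expect_equal(valence_angle_scores(m2, labels)$net_score, res$net_score,
               tolerance = 1e-10)

  # a vector equal to all appetitive and orthogonal to all non-appetitive
  target <- c(1, 0)
  mm <- rbind(t = target, a1 = target, a2 = target,
              n1 = c(0, 1), n2 = c(0, 1))
  res2 <- valence_angle_scores(
    mm, c("appetitive", "appetitive", "appetitive",
          "non-appetitive", "non-appetitive"))
  expect_equal(res2$net_score[1], 90, tolerance = 1e-10)

  expect_error(valence_angle_scores(rbind(c(0, 0), c(1, 2)),
                                    c("appetitive", "non-appetitive")),
               "[Zz]ero")
})
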