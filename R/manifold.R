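#' PCA state-space trajectories of ensemble PN activity
#'
#' Eigendecomposition of the PN-by-PN covariance of a concatenated
#' trial-averaged response matrix (e.g. 89 PNs x 1760 bins for 22 odors at
#' 80 ON bins each), projection of every time-bin population vector onto the
#' top eigenvectors, per-odor subtraction of the first bin (aligning all
#' odors to a common pre-stimulus origin), and 3-point moving-average
#' smoothing. Eigenvector signs are canonicalized so the largest-magnitude
#' loading is positive. Zero eigenvalues of a rank-deficient covariance are
#' kept and ordered last.
#'
#' @param x A response matrix from [as_response_matrix()] (PNs x bins with
#'   `odor` column attribute), or a plain matrix plus `odor`.
#' @param n_components Number of components to project onto (default 3).
#' @param odor Optional odor id per column (taken from the matrix attribute
#'   if present).
#' @param center Subtract each PN's mean across all bins before the
#'   covariance (default `TRUE`).
#' @param baseline_subtract Subtract each odor's first projected bin
#'   (default `TRUE`).
#' @param smooth Apply the 3-point moving average (default `TRUE`).
#' @return A `pn_trajectories` object: list with `scores` (tibble
#'   `odor_id`, `bin`, `time`, `component`, `value`), `rotation`
#'   (PN x component loadings), `eigenvalues`, `variance_explained`
#'   (fraction per retained component), `n_components`.
#' @export
pca_trajectories <- function(x, n_components = 3, odor = attr(x, "odor"),
                             center = TRUE, baseline_subtract = TRUE,
                             smooth = TRUE) {
  m <- unclass(as.matrix(x))
  if (nrow(m) < n_components) abort("Fewer PNs than requested components.")
  if (is.null(odor)) odor <- rep("all", ncol(m))
  times <- attr(x, "time") %||% rep(NA_real_, ncol(m))

  mc <- if (center) m - rowMeans(m) else m
  covm <- tcrossprod(mc) / (ncol(mc) - 1)
  eig <- eigen(covm, symmetric = TRUE)
  ord <- order(eig$values, decreasing = TRUE)
  vals <- pmax(eig$values[ord], 0)
  vecs <- eig$vectors[, ord, drop = FALSE]
  # canonical sign: largest-magnitude loading positive
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  proj <- t(vecs[, seq_len(n_components), drop = FALSE]) %*% mc

  odor_f <- factor(odor, levels = unique(odor))
  for (o in levels(odor_f)) {
    cols <- which(odor_f == o)
    proj[, cols] <- proj[, cols] - proj[, cols[1]]
    if (smooth) {
      for (j in seq_len(n_components)) {
        proj[j, cols] <- moving_average(proj[j, cols], 3L)
      }
    }
  }
  if (!baseline_subtract) {
    # recompute without the first-bin alignment (smoothing kept)
    proj <- t(vecs[, seq_len(n_components), drop = FALSE]) %*% mc
    if (smooth) {
      for (o in levels(odor_f)) {
        cols <- which(odor_f == o)
        for (j in seq_len(n_components)) {
          proj[j, cols] <- moving_average(proj[j, cols], 3L)
        }
      }
    }
  }

  scores <- tibble::tibble(
    odor_id = rep(as.character(odor_f), each = n_components),
    bin = rep(stats::ave(seq_along(odor_f), odor_f, FUN = seq_along),
              each = n_components),
    time = rep(times, each = n_components),
    component = rep(seq_len(n_components), times = ncol(m)),
    value = as.vector(proj)
  )
  structure(
    list(scores = scores, rotation = vecs, eigenvalues = vals,
         variance_explained = if (sum(vals) > 0) {
           vals[seq_len(n_components)] / sum(vals)
         } else rep(0, n_components),
         n_components = n_components),
    class = "pn_trajectories"
  )
}

#' @export
print.pn_trajectories <- function(x, ...) {
  cat(sprintf("<pn_trajectories> %d components, %.1f%% variance captured\n",
              x$n_components, 100 * sum(x$variance_explained)))
  invisible(x)
}

#' Hierarchical clustering of odor response vectors
#'
#' Agglomerative complete-linkage clustering of per-odor ensemble response
#' vectors under the correlation distance d = 1 - Pearson r, so odors whose
#' PN activation patterns are proportional merge at height 0 regardless of
#' overall response strength.
#'
#' @param vectors A numeric matrix, one row per odor (rownames = odor ids),
#'   columns = PNs; e.g. `t(as_response_matrix(...))` summed per odor or
#'   [valence_features()].
#' @return An object of class `hclust`.
#' @export
cluster_odors <- function(vectors) {
  m <- as.matrix(vectors)
  if (nrow(m) < 2) abort("Need at least two odor vectors to cluster.")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant response vector (undefined correlation): %s",
                  paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  d <- as.dist(1 - cor(t(m)))
  hclust(d, method = "complete")
}

#' Cosine-angle similarity of each odor to the valence groups
#'
#' For each odor's ensemble response vector, computes the angle (degrees)
#' to every other odor's vector, averages those angles separately over the
#' appetitive and the non-appetitive group (self-comparison excluded), and
#' reports the net score = mean non-appetitive angle minus mean appetitive
#' angle. Positive net scores mean the odor's ensemble code is
#' appetitive-like. Scores are invariant to positive rescaling of any
#' vector.
#'
#' @param vectors Numeric matrix, one row per odor (rownames = odor ids).
#' @param labels Character vector per odor: `"appetitive"` or anything else
#'   (neutral and unappetitive are pooled as non-appetitive).
#' @return A tibble `odor_id`, `label`, `mean_angle_appetitive`,
#'   `mean_angle_nonappetitive`, `net_score`.
#' @export
valence_angle_scores <- function(vectors, labels) {
  m <- as.matrix(vectors)
  stopifnot(nrow(m) == length(labels))
  if (any(rowSums(m^2) == 0)) abort("Zero response vector: angle undefined.")
  is_app <- labels == "appetitive"
  n <- nrow(m)
  norms <- sqrt(rowSums(m^2))
  cosines <- tcrossprod(m / norms)
  angles <- acos(pmin(pmax(cosines, -1), 1)) * 180 / pi
  diag(angles) <- NA
  ids <- rownames(m) %||% as.character(seq_len(n))

  purrr::map_dfr(seq_len(n), function(i) {
    app <- angles[i, is_app & seq_len(n) != i]
    nonapp <- angles[i, !is_app & seq_len(n) != i]
    tibble::tibble(
      odor_id = ids[i],
      label = if (is_app[i]) "appetitive" else "non-appetitive",
      mean_angle_appetitive = mean(app),
      mean_angle_nonappetitive = mean(nonapp),
      net_score = mean(nonapp) - mean(app)
    )
  })
}
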