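# slow proximal-gradient (ISTA) lasso oracle for
# (1/(2T))||y - X'w - b||^2 + alpha ||w||_1 with unpenalized intercept
prox_lasso_oracle <- function(x_pn_by_t, y, alpha, iters = 200000) {
  t_len <- length(y)
  p <- nrow(x_pn_by_t)
  w <- numeric(p)
  L <- max(eigen(tcrossprod(x_pn_by_t) / t_len, symmetric = TRUE,
                 only.values = TRUE)$values) + 1 / t_len
  step <- 1 / L
  soft <- function(z, s) sign(z) * pmax(abs(z) - s, 0)
  for (i in seq_len(iters)) {
    b <- mean(y - drop(crossprod(x_pn_by_t, w)))
    r <- y - drop(crossprod(x_pn_by_t, w)) - b
    g <- -drop(x_pn_by_t %*% r) / t_len
    w_new <- soft(w - step * g, step * alpha)
    if (max(abs(w_new - w)) < 1e-12) {
      w <- w_new
      break
    }
    w <- w_new
  }
  list(w = w, b = mean(y - drop(crossprod(x_pn_by_t, w))))
}

make_design <- function(x, y, odors = "hex", time = NULL) {
  structure(
    list(x = x, y = y, odors = odors,
         bins_per_odor = ncol(x) / length(odors),
         time = time %||% seq(-2, length.out = ncol(x) / length(odors),
                              by = 0.1),
         pn_ids = seq_len(nrow(x))),
    class = "por_design"
  )
}

test_that("the design matrix has the documented geometry", {
  cfg <- small_config(seed = 51)
  ds <- simulate_pn_spikes(cfg)
  tr <- simulate_por_traces(cfg, "ON",
                            odors = c("hex", "iaa", "bza", "cit"))
  dsg <- build_por_design(ds, tr, odors = c("hex", "iaa", "bza", "cit"))
  expect_equal(dim(dsg$x), c(cfg$n_pns, 400))
  expect_equal(length(dsg$y), 400)
  expect_equal(dsg$bins_per_odor, 100)
  # stimulus onset lands at column 21 of each segment (2 s x 10 Hz before it)
  expect_equal(dsg$time[21], 0)
  expect_equal(sum(dsg$time < 0), 20)

  expect_error(build_por_design(ds, tr, odors = c("hex", "nope")),
               "missing")

  # a dataset with no spikes gives an all-zero design of the right shape
  empty <- manual_dataset(
    tibble::tibble(pn_id = integer(0), odor_id = character(0),
                   trial = integer(0), spike_time_s = numeric(0)),
    odor_ids = c("hex", "iaa", "bza", "cit"), n_trials = 2, pn_ids = 1:3)
  dsg0 <- build_por_design(empty, tr, odors = c("hex", "iaa", "bza", "cit"))
  expect_true(all(dsg0$x == 0))
  expect_equal(dim(dsg0$x), c(3, 400))

  # a PN firing only during odor-1 ON appears only in columns 21..60
  one <- manual_dataset(
    tibble::tibble(pn_id = 1L, odor_id = "hex", trial = 1L,
                   spike_time_s = seq(0.005, 3.995, by = 0.05)),
    odor_ids = c("hex", "iaa", "bza", "cit"), n_trials = 1, pn_ids = 1L)
  dsg1 <- build_por_design(one, tr, odors = c("hex", "iaa", "bza", "cit"))
  nz <- which(dsg1$x[1, ] != 0)
  expect_true(all(nz >= 21 & nz <= 60))
})

test_that("lasso solutions satisfy KKT and match a proximal-gradient oracle", {
  set.seed(17)
  x <- matrix(rnorm(5 * 60), 5, 60)
  w_true <- c(1.5, -2, 0, 0, 0.5)
  y <- drop(crossprod(x, w_true)) + 0.3 + rnorm(60, sd = 0.2)
  dsg <- make_design(x, y, odors = "a", time = seq(0, 5.9, by = 0.1))

  fit <- fit_por_lasso(dsg, alpha = 0.05)
  oracle <- prox_lasso_oracle(x, y, alpha = 0.05)
  expect_equal(unname(fit$weights), oracle$w, tolerance = 1e-6)
  expect_equal(fit$intercept, oracle$b, tolerance = 1e-6)
  expect_lt(fit$kkt_residual, 1e-6)

  # a penalty above max|x'centered-y correlation| zeroes every weight
  big <- fit_por_lasso(dsg, alpha = 1e4)
  expect_true(all(big$weights == 0))
  expect_equal(big$intercept, mean(y), tolerance = 1e-8)

  # the L1 norm of the solution shrinks monotonically with alpha
  norms <- purrr::map_dbl(c(0.01, 0.05, 0.2, 0.5, 1),
                          ~ sum(abs(fit_por_lasso(dsg, .x)$weights)))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("predictions and their significance behave as expected", {
  set.seed(23)
  # the response itself as the only feature row: perfect correlation
  y <- abs(rnorm(200)) + sin(seq(0, 6, length.out = 200))
  x <- matrix(y, 1, 200)
  dsg <- make_design(x, y, odors = c("a", "b"),
                     time = seq(0, 9.9, by = 0.1))
  fit <- fit_por_lasso(dsg, alpha = 1e-6)
  pred <- predict_por(fit, dsg)
  expect_true(all(pred$by_odor$r > 0.999))
  expect_equal(pred$by_odor$df, c(98L, 98L))

  # permuted-time null: |r| beats the 5% critical value rarely
  cfg <- small_config(seed = 61)
  ds <- simulate_pn_spikes(cfg)
  tr <- simulate_por_traces(cfg, "ON", odors = c("hex", "iaa", "bza", "cit"))
  dsg2 <- build_por_design(ds, tr, odors = c("hex", "iaa", "bza", "cit"))
  fit2 <- fit_por_lasso(dsg2, alpha = 0.01)
  yhat <- drop(crossprod(dsg2$x, fit2$weights)) + fit2$intercept
  crit <- sqrt(qt(0.975, 398)^2 / (qt(0.975, 398)^2 + 398))
  set.seed(7)
  exceed <- purrr::map_lgl(1:400, function(i) {
    abs(cor(sample(dsg2$y), yhat)) > crit
  })
  expect_gte(mean(!exceed), 0.9)

  expect_error(predict_por(fit, dsg2), "incompatible")
})

test_that("the synthetic POR mapping recovers the appetitive ensembles", {
  cfg <- synth_config(seed = 31)
  ds <- simulate_pn_spikes(cfg)
  tr_on <- simulate_por_traces(cfg, "ON")
  tr_off <- simulate_por_traces(cfg, "OFF")
  dsg <- build_por_design(ds, tr_on)
  fits <- list(
    fit_por_lasso(dsg, paradigm = "hex_ON"),
    fit_por_lasso(build_por_design(ds, tr_off), paradigm = "hex_OFF")
  )
  pred <- predict_por(fits[[1]], dsg)
  r <- setNames(pred$by_odor$r, pred$by_odor$odor_id)
  expect_true(all(r[c("hexanol_1pct", "isoamyl_acetate")] > 0.8))

  dis <- weight_dissection(fits, dsg)
  expect_equal(nrow(dis$pairwise), 1)

  # positively weighted PNs are predominantly appetitive-ON responders
  truth <- ds$truth |>
    dplyr::filter(.data$odor_id == "hexanol_1pct")
  pos <- dis$pn_groups$pn_id[dis$pn_groups$group == "positive"]
  frac_app <- mean(truth$drives_on[truth$pn_id %in% as.integer(pos)])
  frac_all <- mean(truth$drives_on)
  expect_gt(frac_app, frac_all)

  # identical models correlate perfectly
  dup <- weight_dissection(list(fits[[1]], fits[[1]]), dsg)
  expect_equal(dup$pairwise$r, 1, tolerance = 1e-12)
})
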