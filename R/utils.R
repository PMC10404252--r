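# internal validation helpers --------------------------------------------

assert_probability <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x)), min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a whole number >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_positive <- function(x, name = deparse(substitute(x)), strict = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && all(if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be %s.", name, if (strict) "positive" else "non-negative"))
  }
  invisible(x)
}

# Pearson correlation that returns NA (without warnings) for constant input.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# logistic squashing used by the valence regressor
sigmoid <- function(x) 1 / (1 + exp(-x))

# angle between two vectors in degrees
vector_angle <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("Cannot compute an angle with a zero vector.")
  cosine <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosine))) * 180 / pi
}

# centered moving average used for trajectory smoothing; width must be odd
moving_average <- function(x, width = 3L) {
  n <- length(x)
  if (n == 0) return(x)
  half <- (width - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}
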