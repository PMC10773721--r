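# Independent brute-force oracles, kept deliberately naive (scalar double
# loops) so they share no code path with the package implementations.

oracle_gasf <- function(x) {
  n <- length(x)
  th <- acos(pmin(pmax(x, 0), 1))
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) m[i, j] <- cos(th[i] + th[j])
  m
}

oracle_gadf <- function(x) {
  n <- length(x)
  th <- acos(pmin(pmax(x, 0), 1))
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) m[i, j] <- sin(th[i] - th[j])
  m
}

oracle_mtf <- function(x, Q) {
  n <- length(x)
  bin <- function(v) min(floor(v * Q) + 1, Q)
  b <- vapply(x, bin, numeric(1))
  W <- matrix(0, Q, Q)
  for (t in 1:(n - 1)) W[b[t], b[t + 1]] <- W[b[t], b[t + 1]] + 1
  for (i in 1:Q) if (sum(W[i, ]) > 0) W[i, ] <- W[i, ] / sum(W[i, ])
  m <- matrix(0, n, n)
  for (k in 1:n) for (l in 1:n) m[k, l] <- W[b[k], b[l]]
  m
}

oracle_rp <- function(x, eps) {
  n <- length(x)
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) m[i, j] <- as.numeric(abs(x[i] - x[j]) < eps)
  m
}

# Exact Shapley value of a linear model f(x) = sum(c * x) with feature
# independence over the background: phi_j = c_j * (x_j - mean(bg_j)).
oracle_linear_shap <- function(coefs, x, background) {
  coefs * (x - colMeans(background))
}

# Small hand-built day-record table: one athlete, contiguous days, simple
# ramp loads so window contents are predictable.
make_day_records <- function(athlete = "a1", days = 10, injured_days = integer(0)) {
  vars <- load_variables()
  rec <- data.frame(athlete_id = athlete, day_index = seq_len(days))
  for (i in seq_along(vars)) rec[[vars[i]]] <- seq_len(days) + i / 10
  rec$injury <- as.integer(rec$day_index %in% injured_days)
  rec
}

# A small cohort with guaranteed injuries per athlete, for resampling tests.
make_labelled_features <- function(n_athletes, per_athlete, n_injured_each,
                                   p = 4, seed = 1) {
  set.seed(seed)
  n <- n_athletes * per_athlete
  feat <- matrix(runif(n * p), n, p)
  athlete <- rep(sprintf("a%02d", seq_len(n_athletes)), each = per_athlete)
  labels <- integer(n)
  for (a in unique(athlete)) {
    idx <- which(athlete == a)
    labels[idx[seq_len(n_injured_each)]] <- 1L
  }
  list(features = feat, labels = labels, athlete = athlete)
}
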