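#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_injurisk <- function(...) stop(sprintf(...), call. = FALSE)

#' The ten daily training-load variables
#'
#' Canonical variable order used throughout the package: per-day session
#' count, running volumes (total and by intensity zone, km), strength and
#' alternative training (hours), and three perceived ratings on a 0-10 scale.
#' Readers bind day-approach CSV columns by position; these names are the
#' defaults and can be overridden where a function accepts `variables`.
#'
#' @return Character vector of length 10.
#' @export
load_variables <- function() {
  c("nr_sessions", "total_km", "km_Z3_4", "km_Z5_T1_T2", "km_sprinting",
    "strength_training", "hours_alternative", "perceived_exertion",
    "perceived_trainingSuccess", "perceived_recovery")
}

# indices of the bounded 0-10 perceived-rating variables
rating_vars <- function() 8:10

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a child seed from a main seed and an integer salt, staying within
# 32-bit integer range.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 1000003 + salt * 7919) %% 2147483647L)
}

# Golden-ratio additive low-discrepancy sequence on (0, 1).
lds_sequence <- function(n, offset = 0) {
  phi_inv <- (sqrt(5) - 1) / 2
  (offset + seq_len(n) * phi_inv) %% 1
}

# Deterministic low-discrepancy selection of k indices out of n (without
# replacement): rank the golden-ratio sequence and take the first k.
lds_indices <- function(n, k, offset = 0) {
  stopifnot(k <= n)
  order(lds_sequence(n, offset))[seq_len(k)]
}

# Pairwise Euclidean cross-distances, computed in blocks to bound memory.
cross_dist2 <- function(A, B) {
  # squared distances; A (na x p), B (nb x p)
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Index of the overall nearest neighbour (excluding self) for each row of X.
# Ties broken by smallest index, deterministically.
nearest_neighbour <- function(X, block = 512L) {
  n <- nrow(X)
  nn <- integer(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- cross_dist2(X[idx, , drop = FALSE], X)
    d2[cbind(seq_along(idx), idx)] <- Inf
    nn[idx] <- max.col(-d2, ties.method = "first")
  }
  nn
}

# k nearest neighbours of each row of X among rows of Y (self excluded when
# self_index[i] gives the row of Y identical to row i of X).
knn_indices <- function(X, Y, k, self_index = NULL, block = 512L) {
  n <- nrow(X)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- cross_dist2(X[idx, , drop = FALSE], Y)
    if (!is.null(self_index)) {
      d2[cbind(seq_along(idx), self_index[idx])] <- Inf
    }
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

# Short stable hash of an R object (used for run manifests).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
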