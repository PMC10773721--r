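# Time-series image encodings. Each 8-step normalized series becomes an
# 8x8 matrix; a window's 10 variables stack into an 8x8x10 image.

#' Map a normalized series to polar coordinates
#'
#' Encodes a `[0, 1]`-normalized series as angles `theta_i = arccos(x_i)`
#' with radius `r_i = t_i / N` (`t_i = i`, 1-based). Values outside `[0, 1]`
#' by at most `tol` (floating error) are clamped before `arccos`; larger
#' excursions signal missing normalization and raise an error.
#'
#' @param x Numeric series in `[0, 1]`.
#' @param tol Tolerance for clamping.
#' @return List with `theta` (radians, in `[0, pi]`), `r`, and `n`.
#' @export
to_polar <- function(x, tol = 1e-8) {
  if (any(x < -tol | x > 1 + tol)) {
    stop_injurisk("series values outside [0, 1] (min %.4g, max %.4g): normalize first",
                  min(x), max(x))
  }
  x <- clamp(x, 0, 1)
  n <- length(x)
  list(theta = acos(x), r = seq_len(n) / n, n = n)
}

#' Gramian angular summation field
#'
#' `GASF[i, j] = cos(theta_i + theta_j)`. Symmetric, entries in `[-1, 1]`;
#' the main diagonal `cos(2 theta_i)` retains the original series (since
#' `x_i = cos(theta_i)` is recoverable from it).
#'
#' @param p A polar series from [to_polar()].
#' @return An `n x n` matrix.
#' @export
gasf <- function(p) outer(p$theta, p$theta, function(a, b) cos(a + b))

#' Gramian angular difference field
#'
#' `GADF[i, j] = sin(theta_i - theta_j)`. Antisymmetric with zero diagonal.
#'
#' @inheritParams gasf
#' @return An `n x n` matrix.
#' @export
gadf <- function(p) outer(p$theta, p$theta, function(a, b) sin(a - b))

#' Markov transition field
#'
#' Discretizes a `[0, 1]` series into `Q` uniform-width bins (right-closed at
#' 1), estimates the first-order transition matrix `W` by counting
#' consecutive-step transitions and row-normalizing over the origin bin, and
#' expands it along time: `M[k, l] = P(next value's bin = bin(x_l) | current
#' bin = bin(x_k))`. Bins never visited leave all-zero rows in `W`.
#'
#' @param x Numeric series in `[0, 1]`, length >= 2.
#' @param Q Number of bins (>= 2; default 5).
#' @param transpose Flip the conditioning direction of `W` (origin/
#'   destination convention switch).
#' @return List with `bins` (per-step bin index), `W` (`Q x Q`, rows =
#'   origin), and `M` (`n x n` field).
#' @export
mtf <- function(x, Q = 5L, transpose = FALSE) {
  if (Q < 2) stop_injurisk("Q must be >= 2, got %s", Q)
  if (length(x) < 2) stop_injurisk("series length must be >= 2")
  if (any(x < 0 | x > 1)) stop_injurisk("mtf expects values in [0, 1]")
  bins <- pmin(floor(x * Q) + 1L, Q)
  W <- matrix(0, Q, Q)
  for (t in seq_len(length(x) - 1)) {
    W[bins[t], bins[t + 1]] <- W[bins[t], bins[t + 1]] + 1
  }
  rs <- rowSums(W)
  pop <- rs > 0
  W[pop, ] <- W[pop, , drop = FALSE] / rs[pop]
  if (transpose) W <- t(W)
  M <- W[bins, bins, drop = FALSE]
  dimnames(M) <- NULL
  list(bins = bins, W = W, M = M)
}

#' Recurrence plot
#'
#' Binary recurrence matrix of a series' phase-space trajectory:
#' `R[l, m] = 1` iff `||S_l - S_m|| < epsilon` (Euclidean). States are
#' delay-embedded vectors `S_l = (x_l, x_{l+delay}, ..., x_{l+(dim-1) delay})`;
#' the defaults `embedding_dim = 1`, `delay = 1` use the scalar values
#' themselves so the plot has one state per time step.
#'
#' @param x Numeric series.
#' @param epsilon Distance threshold (> 0). If `NULL`, set to
#'   `eps_fraction` times the maximum pairwise state distance (with a tiny
#'   positive floor so a constant series is fully recurrent).
#' @param embedding_dim,delay Phase-space embedding parameters.
#' @param eps_fraction Fraction used for the data-driven default threshold.
#' @return List with `R` (binary `K x K` matrix), `states` (`K x dim`), and
#'   `epsilon`.
#' @export
recurrence_plot <- function(x, epsilon = NULL, embedding_dim = 1L, delay = 1L,
                            eps_fraction = 0.2) {
  n <- length(x)
  K <- n - (embedding_dim - 1L) * delay
  if (K < 1) stop_injurisk("embedding (dim %d, delay %d) longer than series (n = %d)",
                           embedding_dim, delay, n)
  states <- vapply(seq_len(embedding_dim),
                   function(j) x[(seq_len(K)) + (j - 1L) * delay],
                   numeric(K))
  states <- matrix(states, K, embedding_dim)
  D <- unname(as.matrix(stats::dist(states)))
  if (is.null(epsilon)) {
    epsilon <- max(eps_fraction * max(D), .Machine$double.eps)
  }
  if (epsilon <= 0) stop_injurisk("epsilon must be > 0, got %s", epsilon)
  list(R = (D < epsilon) * 1, states = states, epsilon = epsilon)
}

encoding_methods <- function() c("gasf", "gadf", "mtf", "rp")

#' Encode one window matrix as an image stack
#'
#' Applies the chosen encoding to each variable's 8-step series
#' independently; channel `v` of the result is the encoding of variable `v`.
#'
#' @param m Normalized window matrix (8 x 10, values in `[0, 1]`).
#' @param method One of `"gasf"`, `"gadf"`, `"mtf"`, `"rp"`.
#' @param Q MTF bin count.
#' @param epsilon,eps_fraction Recurrence-plot threshold controls; the
#'   default threshold is `eps_fraction` times the maximum pairwise distance
#'   observed across *all* channels of this window, so channels share a scale.
#' @return An `8 x 8 x 10` array.
#' @export
encode_window <- function(m, method = c("gasf", "gadf", "mtf", "rp"),
                          Q = 5L, epsilon = NULL, eps_fraction = 0.2) {
  if (!is.matrix(m) || nrow(m) != 8) {
    stop_injurisk("encode_window expects an 8-row window matrix (pad first)")
  }
  if (is.character(method) && length(method) == 1 &&
      !(method %in% encoding_methods())) {
    stop_injurisk("unknown encoding method '%s'; valid: %s", method,
                  paste(encoding_methods(), collapse = ", "))
  }
  method <- match.arg(method)
  nv <- ncol(m)
  out <- array(0, dim = c(8, 8, nv), dimnames = list(NULL, NULL, colnames(m)))
  if (method == "rp" && is.null(epsilon)) {
    maxd <- max(apply(m, 2, function(s) max(stats::dist(s))))
    epsilon <- max(eps_fraction * maxd, .Machine$double.eps)
  }
  for (v in seq_len(nv)) {
    s <- m[, v]
    out[, , v] <- switch(method,
      gasf = gasf(to_polar(s)),
      gadf = gadf(to_polar(s)),
      mtf = mtf(s, Q = Q)$M,
      rp = recurrence_plot(s, epsilon = epsilon)$R)
  }
  out
}

#' Encode a window collection
#'
#' Vectorized [encode_window()] over a `window_set`. With
#' `rescale = TRUE` (the model-input convention), MTF and RP stacks in
#' `[0, 1]` are affinely mapped to `[-1, 1]` so all encodings match the
#' auto-encoder's tanh output range; GASF/GADF are already in `[-1, 1]`.
#'
#' @param ws A padded, normalized `window_set`.
#' @param method Encoding method.
#' @param rescale Map MTF/RP output to `[-1, 1]`.
#' @param ... Passed to [encode_window()].
#' @return An `image_stack_set`: list with `x` (`n x 8 x 8 x 10`), `method`,
#'   `meta`.
#' @export
encode_windows <- function(ws, method = c("gasf", "gadf", "mtf", "rp"),
                           rescale = TRUE, ...) {
  method <- match.arg(method)
  stopifnot(inherits(ws, "window_set"))
  if (!ws$padded) stop_injurisk("pad windows to 8 rows before encoding")
  if (!ws$normalized) stop_injurisk("normalize windows before encoding")
  d <- dim(ws$x)
  n <- d[1]; nv <- d[3]
  x <- array(0, dim = c(n, 8, 8, nv),
             dimnames = list(NULL, NULL, NULL, dimnames(ws$x)[[3]]))
  for (i in seq_len(n)) {
    x[i, , , ] <- encode_window(matrix(ws$x[i, , ], 8, nv,
                                       dimnames = list(NULL, dimnames(ws$x)[[3]])),
                                method = method, ...)
  }
  if (rescale && method %in% c("mtf", "rp")) x <- 2 * x - 1
  structure(list(x = x, method = method, meta = ws$meta, rescaled = rescale),
            class = "image_stack_set")
}

#' @export
print.image_stack_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<image_stack_set> %d stacks of %d x %d x %d, method %s\n",
              d[1], d[2], d[3], d[4], x$method))
  invisible(x)
}

# Flatten stacks to an n x 640 model-input matrix.
flatten_stacks <- function(iss) {
  d <- dim(iss$x)
  matrix(iss$x, d[1], prod(d[-1]))
}
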