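# Shapley-value attribution. The estimator marginalizes absent features over
# a background (reference) set; exact subset enumeration is used when the
# player count is small (<= 10 by default), permutation sampling otherwise.

#' Shapley-value attribution of a scalar model
#'
#' Estimates per-feature Shapley contributions for each sample: feature `j`
#' absent means its value is drawn from the background set. With `p <=
#' exact_limit` players all `2^p` coalitions are enumerated (exact values);
#' otherwise `n_permutations` random permutations are averaged. Local
#' accuracy holds: contributions plus the base value (mean model output on
#' the background) reconstruct `f(x)` exactly for the exact estimator and
#' within Monte-Carlo error for the sampled one.
#'
#' @param f Vectorized model function: numeric matrix (rows = samples) ->
#'   numeric vector.
#' @param X Samples to attribute (matrix, rows = samples).
#' @param background Background/reference matrix (same columns).
#' @param n_permutations Permutations for the sampling estimator.
#' @param exact_limit Use exact enumeration when `ncol(X) <=` this.
#' @param seed Integer seed (sampling estimator only).
#' @param groups Optional list of column-index vectors: attribute at the
#'   group level (players = groups), e.g. the 10 image channels of a
#'   flattened stack. Output then has one column per group.
#' @return List with `values` (n x players matrix of signed contributions)
#'   and `base_value`.
#' @export
shapley_attribution <- function(f, X, background, n_permutations = 128L,
                                exact_limit = 10L, seed = 1L, groups = NULL) {
  X <- as.matrix(X); background <- as.matrix(background)
  if (nrow(background) == 0) stop_injurisk("background set is empty")
  if (is.null(groups)) groups <- as.list(seq_len(ncol(X)))
  p <- length(groups)
  base_out <- f(background)
  if (any(!is.finite(base_out))) stop_injurisk("model produced non-finite outputs")
  base_value <- mean(base_out)
  vals <- if (p <= exact_limit) {
    shap_exact(f, X, background, groups)
  } else {
    shap_sample(f, X, background, groups, n_permutations, seed)
  }
  colnames(vals) <- names(groups)
  list(values = vals, base_value = base_value)
}

# Multi-output exact enumeration: f returns an n x m matrix; coalitions are
# evaluated in batches so large models amortize their per-call overhead.
# Returns a list of m (n x p) contribution matrices.
shap_exact_multi <- function(f, X, background, groups, batch_masks = 8L) {
  n <- nrow(X); p <- length(groups); nb <- nrow(background)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  nm <- nrow(masks)
  bg_rep <- background[rep(seq_len(nb), times = n), , drop = FALSE]
  x_rows <- rep(seq_len(n), each = nb)
  probe <- f(X[1, , drop = FALSE])
  m_out <- NCOL(probe)
  V <- array(0, dim = c(nm, n, m_out))
  for (start in seq(1L, nm, by = batch_masks)) {
    ms <- start:min(start + batch_masks - 1L, nm)
    H <- bg_rep[rep(seq_len(nrow(bg_rep)), times = length(ms)), , drop = FALSE]
    for (k in seq_along(ms)) {
      cols <- unlist(groups[masks[ms[k], ]])
      if (length(cols) > 0) {
        rows <- (k - 1L) * n * nb + seq_len(n * nb)
        H[rows, cols] <- X[x_rows, cols, drop = FALSE]
      }
    }
    out <- f(H)
    if (any(!is.finite(out))) stop_injurisk("model produced non-finite outputs")
    out <- array(as.matrix(out), dim = c(nb * n, length(ms), m_out))
    for (k in seq_along(ms)) {
      sub <- array(out[, k, ], dim = c(nb, n * m_out))
      V[ms[k], , ] <- matrix(colMeans(sub), n, m_out)
    }
  }
  sizes <- rowSums(masks)
  key <- masks %*% (2^(seq_len(p) - 1))
  wts <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  lapply(seq_len(m_out), function(o) {
    vals <- matrix(0, n, p)
    for (j in seq_len(p)) {
      without <- which(!masks[, j])
      with_idx <- match(key[without] + 2^(j - 1), key)
      w <- wts[sizes[without] + 1]
      vals[, j] <- colSums(w * (V[with_idx, , o, drop = FALSE] -
                                  V[without, , o, drop = FALSE]))
    }
    vals
  })
}

shap_exact <- function(f, X, background, groups) {
  n <- nrow(X); p <- length(groups); nb <- nrow(background)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  V <- matrix(0, nrow(masks), n)
  for (s in seq_len(nrow(masks))) {
    mask <- masks[s, ]
    cols <- unlist(groups[mask])
    H <- background[rep(seq_len(nb), times = n), , drop = FALSE]
    if (length(cols) > 0) {
      H[, cols] <- X[rep(seq_len(n), each = nb), cols, drop = FALSE]
    }
    out <- f(H)
    V[s, ] <- colMeans(matrix(out, nb, n))
  }
  sizes <- rowSums(masks)
  key <- masks %*% (2^(seq_len(p) - 1))
  vals <- matrix(0, n, p)
  wts <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  for (j in seq_len(p)) {
    without <- which(!masks[, j])
    with_key <- key[without] + 2^(j - 1)
    with_idx <- match(with_key, key)
    w <- wts[sizes[without] + 1]
    vals[, j] <- colSums(w * (V[with_idx, , drop = FALSE] - V[without, , drop = FALSE]))
  }
  vals
}

shap_sample <- function(f, X, background, groups, n_permutations, seed) {
  set.seed(as.integer(seed))
  n <- nrow(X); p <- length(groups); nb <- nrow(background)
  vals <- matrix(0, n, p)
  for (it in seq_len(n_permutations)) {
    perm <- sample.int(p)
    mask <- rep(FALSE, p)
    prev <- coalition_value(f, X, background, groups, mask)
    for (j in perm) {
      mask[j] <- TRUE
      cur <- coalition_value(f, X, background, groups, mask)
      vals[, j] <- vals[, j] + (cur - prev)
      prev <- cur
    }
  }
  vals / n_permutations
}

# value of coalition S (mask over groups) for every sample: mean over
# background rows of f(x on S-columns, background elsewhere)
coalition_value <- function(f, X, background, groups, mask) {
  n <- nrow(X); nb <- nrow(background)
  cols <- unlist(groups[mask])
  H <- background[rep(seq_len(nb), times = n), , drop = FALSE]
  if (length(cols) > 0) {
    H[, cols] <- X[rep(seq_len(n), each = nb), cols, drop = FALSE]
  }
  out <- f(H)
  if (any(!is.finite(out))) stop_injurisk("model produced non-finite outputs")
  colMeans(matrix(out, nb, n))
}

#' Mean-(absolute-)contribution importance
#'
#' Importance of feature `j` is the mean over samples of its Shapley
#' contribution, taken in absolute value by default (signed contributions of
#' opposite direction would otherwise cancel); the literal signed mean is
#' available with `absolute = FALSE`.
#'
#' @param shap_values Matrix of contributions (samples x features) or the
#'   list returned by [shapley_attribution()].
#' @param absolute Take absolute values before averaging.
#' @return Named numeric vector of importances.
#' @export
importance <- function(shap_values, absolute = TRUE) {
  if (is.list(shap_values)) shap_values <- shap_values$values
  if (NROW(shap_values) == 0) stop_injurisk("no attribution samples")
  if (absolute) colMeans(abs(shap_values)) else colMeans(shap_values)
}

relative_importance <- function(imp) {
  s <- sum(imp)
  if (s == 0) return(imp)
  imp / s
}

#' Latent-variable and input-variable importance
#'
#' Two attribution surfaces of the fitted pipeline:
#' * surface A — for each latent variable, the importance of each of the 10
#'   input variables, computed by channel-level Shapley attribution of the
#'   encoder (each image channel is one player, which aggregates pixel
#'   contributions within the channel);
#' * surface B — the importance of the latent variables for the classifier
#'   output, normalized to relative importances (summing to 1).
#'
#' @param encoder A fitted `dcae_model`.
#' @param classifier A fitted `dnn_model`.
#' @param stacks Image stacks of the samples to attribute.
#' @param background Image stacks used as the reference distribution.
#' @param n_samples,n_background Optional down-sampling of the two sets (for
#'   tractable exact enumeration); `NULL` uses everything.
#' @param seed Integer seed for the down-sampling.
#' @return An `attribution_report`: `variable_importance` (latent x
#'   variable matrix), `latent_importance`, `latent_relative_importance`,
#'   and the raw per-surface Shapley values.
#' @export
latent_variable_importance <- function(encoder, classifier, stacks, background,
                                       n_samples = 50L, n_background = 10L,
                                       seed = 1L) {
  if (!inherits(encoder, "dcae_model")) stop_injurisk("encoder is not a dcae_model")
  if (!inherits(classifier, "dnn_model")) stop_injurisk("classifier is not a dnn_model")
  X <- stacks_to_matrix(stacks, encoder$spec)
  B <- stacks_to_matrix(background, encoder$spec)
  vars <- if (inherits(stacks, "image_stack_set"))
    dimnames(stacks$x)[[4]] %||% paste0("var", seq_len(encoder$spec$channels))
  else paste0("var", seq_len(encoder$spec$channels))
  set.seed(as.integer(seed))
  if (!is.null(n_samples) && nrow(X) > n_samples) {
    X <- X[sample.int(nrow(X), n_samples), , drop = FALSE]
  }
  if (!is.null(n_background) && nrow(B) > n_background) {
    B <- B[sample.int(nrow(B), n_background), , drop = FALSE]
  }
  nch <- encoder$spec$channels
  groups <- stats::setNames(lapply(seq_len(nch), function(c) (c - 1L) * 64L + 1:64),
                            vars)
  ld <- encoder$spec$latent_dim
  A <- matrix(0, ld, nch, dimnames = list(paste0("latent", seq_len(ld)), vars))
  fenc <- function(M) dcae_encode(encoder, M)
  base_enc <- colMeans(fenc(B))
  shapA <- shap_exact_multi(fenc, X, B, groups)
  for (k in seq_len(ld)) {
    colnames(shapA[[k]]) <- vars
    A[k, ] <- importance(shapA[[k]])
  }
  shapA <- lapply(seq_len(ld), function(k) {
    list(values = shapA[[k]], base_value = base_enc[k])
  })
  lat_X <- dcae_encode(encoder, X)
  lat_B <- dcae_encode(encoder, B)
  fB <- function(M) predict(classifier, M)
  shB <- shapley_attribution(fB, lat_X, lat_B, seed = seed)
  impB <- stats::setNames(importance(shB), paste0("latent", seq_len(ld)))
  structure(list(variable_importance = A,
                 latent_importance = impB,
                 latent_relative_importance = relative_importance(impB),
                 shap_encoder = shapA, shap_classifier = shB),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report> latent relative importance:\n")
  print(round(x$latent_relative_importance, 3))
  invisible(x)
}
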