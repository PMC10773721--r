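# Model layer: deep convolutional auto-encoder (DCAE) for representation
# learning on encoded window images, and a focal-loss deep network (DNN)
# classifying the latent representation.

#' Auto-encoder architecture specification
#'
#' Symmetric convolutional auto-encoder on 8x8x10 image stacks. The encoder
#' is conv(3x3) -> pool(2) -> conv(3x3) -> pool(2) -> dense latent; the
#' decoder mirrors it with nearest-neighbour 2x upsampling
#' (8 -> 4 -> 2 -> 4 -> 8) and a tanh output convolution back to 10
#' channels. Hidden layers use SELU activations with batch normalization and
#' dropout; the linear bottleneck provides the latent features. Training
#' minimizes mean squared reconstruction error with adadelta (initial step
#' 1.0, accumulation decay 0.95).
#'
#' @param latent_dim Bottleneck width (default 5).
#' @param conv_filters Encoder conv channel counts (length 2).
#' @param dropout_rate Dropout rate for hidden layers.
#' @param epochs,batch Training schedule (defaults 100 / 512).
#' @param lr,rho Adadelta initial step and decay.
#' @param channels Input channel count.
#' @return An `autoencoder_spec` list.
#' @export
autoencoder_spec <- function(latent_dim = 5L, conv_filters = c(32L, 64L),
                             dropout_rate = 0.1, epochs = 100L, batch = 512L,
                             lr = 1.0, rho = 0.95, channels = 10L) {
  stopifnot(length(conv_filters) == 2, latent_dim >= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 conv_filters = as.integer(conv_filters),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, rho = rho,
                 channels = as.integer(channels)),
            class = "autoencoder_spec")
}

#' Classifier architecture specification
#'
#' Four SELU hidden layers of 50 units each (batch normalization + dropout),
#' a single sigmoid output unit, focal loss, and the same adadelta schedule
#' as the auto-encoder.
#'
#' @param hidden Hidden layer widths.
#' @param dropout_rate Dropout rate.
#' @param epochs,batch,lr,rho Training schedule.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(hidden = rep(50L, 4L), dropout_rate = 0.1,
                            epochs = 100L, batch = 512L, lr = 1.0, rho = 0.95) {
  structure(list(hidden = as.integer(hidden), dropout_rate = dropout_rate,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, rho = rho),
            class = "classifier_spec")
}

#' Focal-loss parameters
#'
#' @param alpha Class-balance coefficient in (0, 1); weights the positive
#'   (minority) class.
#' @param gamma Focusing coefficient (>= 0); larger values down-weight
#'   easy-to-classify samples.
#' @return A `focal_loss_params` list.
#' @export
focal_loss_params <- function(alpha = 0.986, gamma = 3.5) {
  if (alpha <= 0 || alpha >= 1) stop_injurisk("alpha must lie in (0, 1)")
  if (gamma < 0) stop_injurisk("gamma must be >= 0")
  structure(list(alpha = alpha, gamma = gamma), class = "focal_loss_params")
}

#' Class-balance coefficient from sample counts
#'
#' `alpha = 1 - n_minority / n_total`: one minus the minority share of the
#' sample, so the rarer the positive class, the more the loss up-weights it.
#'
#' @param n_minority Minority-class count (> 0).
#' @param n_total Total count (> `n_minority`).
#' @return The alpha coefficient.
#' @export
compute_alpha <- function(n_minority, n_total) {
  if (n_total <= 0 || n_minority <= 0) stop_injurisk("counts must be positive")
  if (n_minority >= n_total) stop_injurisk("n_minority must be < n_total")
  1 - n_minority / n_total
}

#' Focal loss
#'
#' Per-sample loss `-alpha (1 - p)^gamma log(p)` for positive labels and
#' `-(1 - alpha) p^gamma log(1 - p)` for negative labels, averaged over the
#' batch. At `gamma = 0`, `alpha = 0.5` this is exactly half the binary
#' cross-entropy. Probabilities are clamped to `[clamp, 1 - clamp]`.
#'
#' @param p Predicted positive-class probabilities.
#' @param y Binary labels.
#' @param params A [focal_loss_params()].
#' @param clamp Numerical clamp for probabilities.
#' @return Mean loss (non-negative scalar).
#' @export
focal_loss <- function(p, y, params = focal_loss_params(), clamp = 1e-7) {
  if (!all(y %in% c(0, 1))) stop_injurisk("labels must be binary 0/1")
  p <- pmin(pmax(p, clamp), 1 - clamp)
  a <- params$alpha; g <- params$gamma
  l <- ifelse(y == 1, -a * (1 - p)^g * log(p), -(1 - a) * p^g * log(1 - p))
  mean(l)
}

# loss closure over the sigmoid output: returns value and gradient wrt p
focal_loss_fn <- function(params, clamp = 1e-7) {
  a <- params$alpha; g <- params$gamma
  function(pred, y) {
    p <- pmin(pmax(as.numeric(pred), clamp), 1 - clamp)
    n <- length(p)
    pos <- y == 1
    l <- ifelse(pos, -a * (1 - p)^g * log(p), -(1 - a) * p^g * log(1 - p))
    dp <- ifelse(pos,
                 a * (g * (1 - p)^pmax(g - 1, 0) * log(p) - (1 - p)^g / p),
                 -(1 - a) * (g * p^pmax(g - 1, 0) * log(1 - p) - p^g / (1 - p)))
    list(value = mean(l), grad = matrix(dp / n, n, 1))
  }
}

build_dcae_layers <- function(spec) {
  f <- spec$conv_filters
  ch <- spec$channels
  ld <- spec$latent_dim
  dr <- spec$dropout_rate
  enc <- list(
    nn_conv(8L, 8L, ch, f[1]), nn_batchnorm(f[1], 64L), nn_act("selu"),
    nn_dropout(dr), nn_pool(8L, 8L, f[1]),
    nn_conv(4L, 4L, f[1], f[2]), nn_batchnorm(f[2], 16L), nn_act("selu"),
    nn_dropout(dr), nn_pool(4L, 4L, f[2]),
    nn_dense(4L * f[2], ld)  # linear bottleneck
  )
  dec <- list(
    nn_dense(ld, 4L * f[2]), nn_batchnorm(f[2], 4L), nn_act("selu"),
    nn_dropout(dr), nn_upsample(2L, 2L, f[2]),
    nn_conv(4L, 4L, f[2], f[1]), nn_batchnorm(f[1], 16L), nn_act("selu"),
    nn_dropout(dr), nn_upsample(4L, 4L, f[1]),
    nn_conv(8L, 8L, f[1], ch), nn_act("tanh")
  )
  list(layers = c(enc, dec), latent_at = length(enc))
}

#' Fit the deep convolutional auto-encoder
#'
#' Trains the DCAE of [autoencoder_spec()] to reconstruct encoded window
#' image stacks under mean squared error. Input stacks must be in the tanh
#' range `[-1, 1]` (see `rescale` in [encode_windows()]).
#'
#' @param stacks An `image_stack_set` or an `n x 8 x 8 x C` array.
#' @param spec An [autoencoder_spec()].
#' @param seed Integer seed (weight init, shuffling, dropout).
#' @param validation Optional held-out `image_stack_set`/array for a
#'   per-epoch validation reconstruction loss.
#' @param epochs Optional override of `spec$epochs`.
#' @param verbose Print per-epoch losses.
#' @return A `dcae_model` with the trained layers, the latent position, the
#'   spec, and the loss `history` (one row per epoch).
#' @export
dcae_fit <- function(stacks, spec = autoencoder_spec(), seed = 1L,
                     validation = NULL, epochs = NULL, verbose = FALSE) {
  X <- stacks_to_matrix(stacks, spec)
  if (max(abs(X)) > 1 + 1e-6) {
    stop_injurisk("stack values outside [-1, 1]; encode with rescale = TRUE")
  }
  set.seed(as.integer(seed))  # weight initialization
  arch <- build_dcae_layers(spec)
  mse <- function(pred, y) {
    d <- pred - y
    list(value = mean(d^2), grad = 2 * d / length(d))
  }
  val <- if (!is.null(validation)) {
    XV <- stacks_to_matrix(validation, spec)
    list(X = XV, Y = XV)
  }
  fit <- net_train(arch$layers, X, X, mse, epochs = epochs %||% spec$epochs,
                   batch = spec$batch, lr = spec$lr, rho = spec$rho,
                   seed = derive_seed(seed, 11), validation = val,
                   verbose = verbose)
  structure(list(layers = fit$layers, latent_at = arch$latent_at, spec = spec,
                 history = fit$history),
            class = "dcae_model")
}

stacks_to_matrix <- function(stacks, spec) {
  if (inherits(stacks, "image_stack_set")) {
    X <- flatten_stacks(stacks)
  } else if (is.array(stacks) && length(dim(stacks)) == 4) {
    X <- matrix(stacks, dim(stacks)[1], prod(dim(stacks)[-1]))
  } else if (is.matrix(stacks)) {
    X <- stacks
  } else stop_injurisk("expected an image_stack_set or n x 8 x 8 x C array")
  expected <- 64L * spec$channels
  if (ncol(X) != expected) {
    stop_injurisk("stack feature width %d does not match spec (%d)", ncol(X), expected)
  }
  X
}

#' @export
print.dcae_model <- function(x, ...) {
  cat(sprintf("<dcae_model> latent_dim %d, conv filters %s, %d epochs (final loss %.5f)\n",
              x$spec$latent_dim, paste(x$spec$conv_filters, collapse = "/"),
              nrow(x$history), utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Encode image stacks to latent vectors
#'
#' Deterministic inference pass through the trained encoder (dropout off,
#' batch normalization in inference mode).
#'
#' @param model A fitted `dcae_model`.
#' @param stacks Image stacks (see [dcae_fit()]).
#' @return An `n x latent_dim` matrix.
#' @export
dcae_encode <- function(model, stacks) {
  if (!inherits(model, "dcae_model")) stop_injurisk("model is not a trained dcae_model")
  X <- stacks_to_matrix(stacks, model$spec)
  net_predict(model$layers[seq_len(model$latent_at)], X)
}

#' Reconstruct image stacks through the auto-encoder
#' @param model A fitted `dcae_model`.
#' @param stacks Image stacks.
#' @return Matrix of reconstructions (one row per stack, flattened).
#' @export
dcae_reconstruct <- function(model, stacks) {
  X <- stacks_to_matrix(stacks, model$spec)
  net_predict(model$layers, X)
}

#' Fit the focal-loss deep network classifier
#'
#' Trains the classifier of [classifier_spec()] on latent vectors. Latents
#' are standardized internally (training mean/SD stored with the model).
#' `alpha` defaults to [compute_alpha()] on the supplied labels.
#'
#' @param latents Numeric matrix of latent features.
#' @param labels Binary labels (1 = injury).
#' @param spec A [classifier_spec()].
#' @param focal A [focal_loss_params()]; `NULL` uses
#'   `focal_loss_params(compute_alpha(sum(y), length(y)), 3.5)`.
#' @param seed Integer seed.
#' @param epochs Optional override of `spec$epochs`.
#' @param verbose Print per-epoch losses.
#' @return A `dnn_model`.
#' @export
dnn_fit <- function(latents, labels, spec = classifier_spec(), focal = NULL,
                    seed = 1L, epochs = NULL, verbose = FALSE) {
  latents <- as.matrix(latents)
  if (any(!is.finite(latents))) stop_injurisk("latents contain non-finite values")
  if (!all(labels %in% c(0, 1))) stop_injurisk("labels must be binary 0/1")
  if (is.null(focal)) {
    focal <- focal_loss_params(compute_alpha(max(sum(labels == 1), 1),
                                             length(labels)), 3.5)
  }
  center <- colMeans(latents)
  scale <- apply(latents, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(latents, 2, center, "-"), 2, scale, "/")
  set.seed(as.integer(seed))
  layers <- list()
  d <- ncol(Xs)
  for (h in spec$hidden) {
    layers <- c(layers, list(nn_dense(d, h), nn_batchnorm(h), nn_act("selu"),
                             nn_dropout(spec$dropout_rate)))
    d <- h
  }
  layers <- c(layers, list(nn_dense(d, 1L), nn_act("sigmoid")))
  fit <- net_train(layers, Xs, labels, focal_loss_fn(focal),
                   epochs = epochs %||% spec$epochs, batch = spec$batch,
                   lr = spec$lr, rho = spec$rho, seed = derive_seed(seed, 13))
  structure(list(layers = fit$layers, spec = spec, focal = focal,
                 center = center, scale = scale, history = fit$history),
            class = "dnn_model")
}

#' @export
print.dnn_model <- function(x, ...) {
  cat(sprintf("<dnn_model> hidden %s, focal(alpha=%.3f, gamma=%.1f), final loss %.6f\n",
              paste(x$spec$hidden, collapse = "-"), x$focal$alpha,
              x$focal$gamma, utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Predict injury probabilities from latent vectors
#' @param object A fitted `dnn_model`.
#' @param newdata Latent matrix.
#' @param ... Unused.
#' @return Probabilities in (0, 1).
#' @export
predict.dnn_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (any(!is.finite(newdata))) stop_injurisk("latents contain non-finite values")
  Xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  as.numeric(net_predict(object$layers, Xs))
}

#' End-to-end risk prediction for a window collection
#'
#' Composition classifier(encoder(encoding(normalization))) — takes raw,
#' unpadded windows plus a normalization state and returns next-day injury
#' probabilities.
#'
#' @param encoder A fitted `dcae_model`.
#' @param classifier A fitted `dnn_model`.
#' @param ws A `window_set` (raw or normalized; raw windows require
#'   `norm_state`).
#' @param method Encoding method used at training time.
#' @param norm_state Normalization state to apply when `ws` is raw.
#' @param pad Padding mode for unpadded windows.
#' @return Numeric vector of injury probabilities.
#' @export
predict_risk <- function(encoder, classifier, ws, method = "gasf",
                         norm_state = NULL, pad = "edge") {
  stopifnot(inherits(ws, "window_set"))
  if (!ws$normalized) ws <- normalize_window_set(ws, state = norm_state)
  if (!ws$padded) ws <- pad_window_set(ws, pad)
  stacks <- encode_windows(ws, method = method, rescale = TRUE)
  predict(classifier, dcae_encode(encoder, stacks))
}
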