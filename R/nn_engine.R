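# Minimal dense/convolutional neural-network engine.
#
# All activations flow as N x D matrices; a conv feature map of height H,
# width W and C channels is stored per sample in R array order dim(H, W, C),
# i.e. column j of the matrix is (h, w, c) with h fastest. Convolutions use
# im2col (gather by precomputed index, one BLAS gemm) and a precomputed
# sparse scatter matrix for the input gradient. Optimization is adadelta
# (adaptive per-parameter steps; initial step scale 1.0, accumulation decay
# rho), the only optimizer the architecture specs use.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

flat_index <- function(h, w, c, H, W) h + (w - 1L) * H + (c - 1L) * H * W

# ---- layer constructors -----------------------------------------------------

nn_conv <- function(H, W, in_ch, out_ch, ksize = 3L) {
  half <- (ksize - 1L) %/% 2L
  HW <- H * W
  K <- ksize * ksize * in_ch
  # gather index: for offset/channel k (k fastest over (dh, dw, c)) and
  # position pos, the source column in [1, H*W*in_ch], or the zero column.
  idx <- integer(HW * K)
  src_of_col <- integer(HW * K)  # 0 where padding
  col <- 0L
  for (c in seq_len(in_ch)) for (dw in -half:half) for (dh in -half:half) {
    for (w in seq_len(W)) for (h in seq_len(H)) {
      pos <- h + (w - 1L) * H
      col <- col + 1L
      hh <- h + dh; ww <- w + dw
      src <- if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        flat_index(hh, ww, c, H, W) else 0L
      # order columns pos-fastest within k
      j <- (((c - 1L) * ksize * ksize +
             (dw + half) * ksize + (dh + half)) * HW) + pos
      idx[j] <- if (src > 0L) src else H * W * in_ch + 1L  # zero column
      src_of_col[j] <- src
    }
  }
  nz <- src_of_col > 0L
  scatter <- Matrix::sparseMatrix(i = which(nz), j = src_of_col[nz], x = 1,
                                  dims = c(HW * K, H * W * in_ch))
  list(type = "conv", H = H, W = W, HW = HW, in_ch = in_ch, out_ch = out_ch,
       K = K, idx = idx, scatter = scatter,
       params = list(W = matrix(stats::rnorm(K * out_ch, 0, sqrt(1 / K)), K, out_ch),
                     b = rep(0, out_ch)))
}

conv_forward <- function(layer, X) {
  N <- nrow(X)
  Xext <- cbind(X, 0)
  M <- Xext[, layer$idx, drop = FALSE]            # N x (HW*K), pos fastest
  dim(M) <- c(N * layer$HW, layer$K)              # same linear order, no copy
  out <- M %*% layer$params$W                     # (N*HW) x out_ch
  out <- out + rep(layer$params$b, each = nrow(out))
  dim(out) <- c(N, layer$HW * layer$out_ch)
  list(out = out, cache = list(M = M, N = N))
}

conv_backward <- function(layer, cache, dY) {
  N <- cache$N
  dOut <- dY
  dim(dOut) <- c(N * layer$HW, layer$out_ch)
  dW <- crossprod(cache$M, dOut)
  db <- colSums(dOut)
  dM <- tcrossprod(dOut, layer$params$W)          # (N*HW) x K
  dim(dM) <- c(N, layer$HW * layer$K)
  dX <- as.matrix(dM %*% layer$scatter)
  list(dX = dX, grads = list(W = dW, b = db))
}

# 2x2 average pooling (H, W even)
nn_pool <- function(H, W, ch) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ii <- integer(0); jj <- integer(0)
  for (c in seq_len(ch)) for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
    out <- flat_index(ho, wo, c, Ho, Wo)
    for (dw in 0:1) for (dh in 0:1) {
      ii <- c(ii, flat_index(2L * ho - 1L + dh, 2L * wo - 1L + dw, c, H, W))
      jj <- c(jj, out)
    }
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 0.25,
                            dims = c(H * W * ch, Ho * Wo * ch))
  list(type = "map", P = P)
}

# nearest-neighbour 2x upsampling
nn_upsample <- function(H, W, ch) {
  Ho <- 2L * H; Wo <- 2L * W
  ii <- integer(0); jj <- integer(0)
  for (c in seq_len(ch)) for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
    ii <- c(ii, flat_index((ho + 1L) %/% 2L, (wo + 1L) %/% 2L, c, H, W))
    jj <- c(jj, flat_index(ho, wo, c, Ho, Wo))
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(H * W * ch, Ho * Wo * ch))
  list(type = "map", P = P)
}

map_forward <- function(layer, X) list(out = as.matrix(X %*% layer$P), cache = NULL)
map_backward <- function(layer, cache, dY) {
  list(dX = as.matrix(dY %*% Matrix::t(layer$P)), grads = NULL)
}

nn_dense <- function(in_dim, out_dim) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = matrix(stats::rnorm(in_dim * out_dim, 0, sqrt(1 / in_dim)),
                                in_dim, out_dim),
                     b = rep(0, out_dim)))
}

dense_forward <- function(layer, X) {
  out <- X %*% layer$params$W
  list(out = out + rep(layer$params$b, each = nrow(out)),
       cache = list(X = X))
}

dense_backward <- function(layer, cache, dY) {
  list(dX = tcrossprod(dY, layer$params$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

# Batch normalization per channel; for conv maps `spatial` = H*W so the
# statistic pools over batch and positions. Running moments are kept for
# inference mode.
nn_batchnorm <- function(channels, spatial = 1L, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", channels = channels, spatial = spatial,
       momentum = momentum, eps = eps,
       params = list(gamma = rep(1, channels), beta = rep(0, channels)),
       state = list(mean = rep(0, channels), var = rep(1, channels)))
}

bn_forward <- function(layer, X, training) {
  N <- nrow(X)
  Xc <- X
  dim(Xc) <- c(N * layer$spatial, layer$channels)
  if (training) {
    mu <- colMeans(Xc)
    v <- colMeans(Xc^2) - mu^2
    layer$state$mean <- layer$momentum * layer$state$mean + (1 - layer$momentum) * mu
    layer$state$var <- layer$momentum * layer$state$var + (1 - layer$momentum) * v
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
  }
  std <- sqrt(v + layer$eps)
  m <- nrow(Xc)
  xhat <- (Xc - rep(mu, each = m)) / rep(std, each = m)
  out <- xhat * rep(layer$params$gamma, each = m) +
    rep(layer$params$beta, each = m)
  dim(out) <- dim(X)
  list(out = out,
       cache = list(xhat = xhat, std = std, N = N, training = training),
       layer = layer)
}

bn_backward <- function(layer, cache, dY) {
  N <- cache$N
  dYc <- dY
  dim(dYc) <- c(N * layer$spatial, layer$channels)
  m <- nrow(dYc)
  dgamma <- colSums(dYc * cache$xhat)
  dbeta <- colSums(dYc)
  dxhat <- dYc * rep(layer$params$gamma, each = m)
  if (cache$training) {
    dx <- (dxhat - rep(colMeans(dxhat), each = m) -
             cache$xhat * rep(colSums(dxhat * cache$xhat) / m, each = m)) /
      rep(cache$std, each = m)
  } else {
    dx <- dxhat / rep(cache$std, each = m)
  }
  dim(dx) <- dim(dY)
  list(dX = dx, grads = list(gamma = dgamma, beta = dbeta))
}

nn_act <- function(fun) list(type = "act", fun = fun)

act_forward <- function(layer, X) {
  out <- switch(layer$fun,
    selu = {
      o <- X
      neg <- X < 0
      o[neg] <- SELU_ALPHA * (exp(X[neg]) - 1)
      SELU_LAMBDA * o
    },
    tanh = tanh(X),
    sigmoid = stats::plogis(X),
    linear = X)
  list(out = out, cache = list(X = X, out = out))
}

act_backward <- function(layer, cache, dY) {
  g <- switch(layer$fun,
    selu = {
      g <- cache$out + SELU_LAMBDA * SELU_ALPHA
      g[cache$X > 0] <- SELU_LAMBDA
      g
    },
    tanh = 1 - cache$out^2,
    sigmoid = cache$out * (1 - cache$out),
    linear = 1)
  list(dX = dY * g, grads = NULL)
}

nn_dropout <- function(rate) list(type = "dropout", rate = rate)

dropout_forward <- function(layer, X, training) {
  if (!training || layer$rate <= 0) {
    return(list(out = X, cache = list(mask = NULL)))
  }
  mask <- matrix(stats::runif(length(X)) >= layer$rate, nrow(X), ncol(X)) /
    (1 - layer$rate)
  list(out = X * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, cache, dY) {
  list(dX = if (is.null(cache$mask)) dY else dY * cache$mask, grads = NULL)
}

# ---- network ----------------------------------------------------------------

net_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_forward(l, X),
      map = map_forward(l, X),
      dense = dense_forward(l, X),
      bn = bn_forward(l, X, training),
      act = act_forward(l, X),
      dropout = dropout_forward(l, X, training))
    if (l$type == "bn" && training) layers[[i]] <- r$layer  # running stats
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_backward(l, caches[[i]], dOut),
      map = map_backward(l, caches[[i]], dOut),
      dense = dense_backward(l, caches[[i]], dOut),
      bn = bn_backward(l, caches[[i]], dOut),
      act = act_backward(l, caches[[i]], dOut),
      dropout = dropout_backward(l, caches[[i]], dOut))
    dOut <- r$dX
    grads[i] <- list(r$grads)  # keep NULL slots (pool/act layers have no params)
  }
  list(grads = grads, dInput = dOut)
}

adadelta_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$params)) return(NULL)
    lapply(l$params, function(p) list(Eg2 = p * 0, Edx2 = p * 0))
  })
}

adadelta_step <- function(layers, grads, state, lr = 1.0, rho = 0.95, eps = 1e-6) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      s <- state[[i]][[nm]]
      s$Eg2 <- rho * s$Eg2 + (1 - rho) * g^2
      dx <- -sqrt(s$Edx2 + eps) / sqrt(s$Eg2 + eps) * g * lr
      s$Edx2 <- rho * s$Edx2 + (1 - rho) * dx^2
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] + dx
      state[[i]][[nm]] <- s
    }
  }
  list(layers = layers, state = state)
}

# Generic minibatch training loop. loss_fn(pred, y) -> list(value, grad).
net_train <- function(layers, X, Y, loss_fn, epochs, batch, lr = 1.0,
                      rho = 0.95, seed = 1L, validation = NULL,
                      verbose = FALSE) {
  set.seed(as.integer(seed))
  state <- adadelta_init(layers)
  n <- nrow(X)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch)) {
      bi <- ord[start:min(start + batch - 1L, n)]
      fw <- net_forward(layers, X[bi, , drop = FALSE], training = TRUE)
      layers <- fw$layers
      lo <- loss_fn(fw$out, if (is.matrix(Y)) Y[bi, , drop = FALSE] else Y[bi])
      bw <- net_backward(layers, fw$caches, lo$grad)
      upd <- adadelta_step(layers, bw$grads, state, lr = lr, rho = rho)
      layers <- upd$layers
      state <- upd$state
      losses <- c(losses, lo$value)
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      pv <- net_forward(layers, validation$X, training = FALSE)$out
      val_loss <- loss_fn(pv, validation$Y)$value
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.6f%s", ep, mean(losses),
                      if (is.na(val_loss)) "" else sprintf("  val %.6f", val_loss)))
    }
  }
  list(layers = layers, history = history)
}

# Inference on large inputs in chunks to bound im2col memory.
net_predict <- function(layers, X, chunk = 2048L) {
  n <- nrow(X)
  out <- NULL
  for (start in seq(1L, n, by = chunk)) {
    bi <- start:min(start + chunk - 1L, n)
    o <- net_forward(layers, X[bi, , drop = FALSE], training = FALSE)$out
    out <- rbind(out, o)
  }
  out
}
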