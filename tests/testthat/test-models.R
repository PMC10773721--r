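test_that("focal loss matches hand-evaluated values and reductions", {
  expect_equal(focal_loss(0.9, 1, focal_loss_params(0.25, 2)),
               -0.25 * 0.1^2 * log(0.9), tolerance = 1e-12)
  # gamma = 0, alpha = 0.5 reduces to half the binary cross-entropy
  set.seed(1)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(focal_loss(p, y, focal_loss_params(0.5, 0)), 0.5 * bce,
               tolerance = 1e-12)
  # perfect prediction drives the loss to zero as the clamp tightens
  expect_lt(focal_loss(1, 1, focal_loss_params(0.9, 2), clamp = 1e-12),
            focal_loss(1, 1, focal_loss_params(0.9, 2), clamp = 1e-4))
  expect_error(focal_loss(0.5, 2, focal_loss_params()), "binary")
})

test_that("focal loss is strictly decreasing in the predicted probability for y = 1", {
  p <- seq(0.01, 0.99, by = 0.01)
  l <- vapply(p, function(pp) focal_loss(pp, 1, focal_loss_params(0.986, 3.5)),
              numeric(1))
  expect_true(all(diff(l) < 0))
})

test_that("alpha is one minus the minority share", {
  expect_equal(compute_alpha(1, 2), 0.5)
  for (k in c(1, 7, 50)) expect_equal(compute_alpha(k, 10 * k), 0.9)
  expect_error(compute_alpha(0, 10), "positive")
  expect_error(compute_alpha(10, 10), "n_minority")
})

test_that("focal loss parameter validation enforces its domain", {
  expect_error(focal_loss_params(alpha = 0), "alpha")
  expect_error(focal_loss_params(gamma = -1), "gamma")
})

test_that("analytic gradients match finite differences through the full stack", {
  eng <- asNamespace("injurisk")
  set.seed(4)
  layers <- list(eng$nn_conv(4L, 4L, 2L, 3L), eng$nn_batchnorm(3L, 16L),
                 eng$nn_act("selu"), eng$nn_pool(4L, 4L, 3L),
                 eng$nn_upsample(2L, 2L, 3L), eng$nn_conv(4L, 4L, 3L, 2L),
                 eng$nn_act("tanh"))
  X <- matrix(rnorm(6 * 32), 6, 32)
  Y <- matrix(rnorm(6 * 32), 6, 32)
  mse <- function(pred, y) {
    d <- pred - y
    list(value = mean(d^2), grad = 2 * d / length(d))
  }
  fw <- eng$net_forward(layers, X, training = TRUE)
  bw <- eng$net_backward(fw$layers, fw$caches, mse(fw$out, Y)$grad)
  h <- 1e-6
  for (li in c(1, 2, 6)) {
    for (nm in names(layers[[li]]$params)) {
      p0 <- layers[[li]]$params[[nm]]
      for (k in seq_len(min(3, length(p0)))) {
        layers[[li]]$params[[nm]][k] <- p0[k] + h
        f1 <- mse(eng$net_forward(layers, X, TRUE)$out, Y)$value
        layers[[li]]$params[[nm]][k] <- p0[k] - h
        f2 <- mse(eng$net_forward(layers, X, TRUE)$out, Y)$value
        layers[[li]]$params[[nm]][k] <- p0[k]
        expect_equal(bw$grads[[li]][[nm]][k], (f1 - f2) / (2 * h),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("the auto-encoder learns a representable fixed point", {
  # constant dataset: reconstruction loss must approach zero
  st <- array(0.5, dim = c(40, 8, 8, 10))
  spec <- autoencoder_spec(conv_filters = c(8L, 16L), epochs = 40, batch = 20,
                           dropout_rate = 0)
  m <- dcae_fit(st, spec, seed = 5)
  expect_equal(nrow(m$history), 40)
  expect_lt(tail(m$history$loss, 1), 0.5 * m$history$loss[1])
  expect_lt(tail(m$history$loss, 1), 0.02)
  # shape contract: reconstruction matches input width
  rec <- dcae_reconstruct(m, st)
  expect_equal(dim(rec), c(40, 640))
})

test_that("latent encoding is deterministic at inference", {
  set.seed(6)
  st <- array(runif(30 * 640, -1, 1), dim = c(30, 8, 8, 10))
  m <- dcae_fit(st, autoencoder_spec(conv_filters = c(8L, 16L), epochs = 3,
                                     batch = 15), seed = 7)
  l1 <- dcae_encode(m, st)
  l2 <- dcae_encode(m, st)
  expect_identical(l1, l2)
  expect_equal(dim(l1), c(30, 5))
  expect_error(dcae_encode(list(), st), "dcae_model")
  expect_error(dcae_fit(array(5, dim = c(4, 8, 8, 10))), "\\[-1, 1\\]")
  expect_error(dcae_fit(matrix(0, 4, 100)), "width")
})

test_that("identical seeds reproduce training exactly", {
  st <- array(runif(24 * 640, -1, 1), dim = c(24, 8, 8, 10))
  m1 <- dcae_fit(st, autoencoder_spec(conv_filters = c(4L, 8L), epochs = 2,
                                      batch = 12), seed = 3)
  m2 <- dcae_fit(st, autoencoder_spec(conv_filters = c(4L, 8L), epochs = 2,
                                      batch = 12), seed = 3)
  expect_identical(m1$history, m2$history)
  expect_identical(dcae_encode(m1, st), dcae_encode(m2, st))
})

test_that("the classifier separates linearly separable latents", {
  set.seed(8)
  n <- 200
  lat <- rbind(matrix(rnorm(n * 5, 2), n, 5), matrix(rnorm(n * 5, -2), n, 5))
  y <- c(rep(1, n), rep(0, n))
  clf <- dnn_fit(lat, y, classifier_spec(epochs = 40, batch = 64),
                 focal = focal_loss_params(0.5, 0), seed = 9)
  p <- predict(clf, lat)
  expect_true(all(p > 0 & p < 1))
  m <- classification_metrics(y, p)
  expect_gte(m$sensitivity, 0.95)
  expect_gte(m$specificity, 0.95)
})

test_that("training on permuted labels yields chance-level discrimination", {
  set.seed(10)
  lat <- matrix(rnorm(600 * 5), 600, 5)
  y <- rbinom(600, 1, 0.5)
  clf <- dnn_fit(lat[1:300, ], y[1:300], classifier_spec(epochs = 30, batch = 64),
                 focal = focal_loss_params(0.5, 0), seed = 11)
  p_test <- predict(clf, lat[301:600, ])
  auc <- auc_rank(y[301:600], p_test)
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("classifier input validation rejects non-finite latents", {
  expect_error(dnn_fit(matrix(c(1, NA, 3, 4), 2, 2), c(0, 1)), "finite")
  expect_error(dnn_fit(matrix(1:4, 2, 2), c(0, 2)), "binary")
})
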