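test_that("polar mapping follows the arccos/timestamp definition", {
  p <- to_polar(c(0, 0.5, 1))
  expect_equal(p$theta, c(pi / 2, pi / 3, 0))
  expect_equal(to_polar(rep(1, 5))$theta, rep(0, 5))
  expect_equal(to_polar(runif(4))$r, c(0.25, 0.5, 0.75, 1))
  # floating error is absorbed, genuine violations are not
  expect_silent(to_polar(c(1 + 1e-12, -1e-12)))
  expect_error(to_polar(c(0.2, 1.4)), "normalize")
})

test_that("hand-computed 3-point angular fields match exactly", {
  p <- to_polar(c(0, 0.5, 1))
  expect_equal(gasf(p),
               matrix(c(-1, -sqrt(3) / 2, 0,
                        -sqrt(3) / 2, -0.5, 0.5,
                        0, 0.5, 1), 3, 3, byrow = TRUE))
  g <- gadf(p)
  expect_equal(g[upper.tri(g)], c(0.5, 1, sqrt(3) / 2))
  expect_equal(diag(g), rep(0, 3))
  expect_equal(g, -t(g))
})

test_that("angular fields satisfy their structural invariants", {
  set.seed(42)
  for (i in 1:20) {
    x <- runif(sample(4:16, 1))
    p <- to_polar(x)
    gs <- gasf(p); gd <- gadf(p)
    expect_equal(gs, t(gs))
    expect_true(all(gs >= -1 - 1e-12 & gs <= 1 + 1e-12))
    expect_equal(diag(gs), cos(2 * p$theta))
    expect_equal(gd, -t(gd))
    expect_equal(diag(gd), rep(0, length(x)))
    # reconstructability: x recoverable from the GASF diagonal
    expect_equal(cos(acos(pmin(pmax(diag(gs), -1), 1)) / 2), x,
                 tolerance = 1e-8)
  }
})

test_that("hand-counted Markov transition field matches exactly", {
  m <- mtf(c(0, 0, 1, 1), Q = 2)
  expect_equal(m$W, matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(m$M, matrix(c(0.5, 0.5, 0.5, 0.5,
                             0.5, 0.5, 0.5, 0.5,
                             0, 0, 1, 1,
                             0, 0, 1, 1), 4, 4, byrow = TRUE))
  # constant series: one populated bin, field all ones
  mc <- mtf(rep(0.4, 6), Q = 5)
  expect_true(all(mc$M == 1))
  expect_equal(sum(rowSums(mc$W) > 0), 1)
})

test_that("populated transition rows are stochastic for random series", {
  set.seed(7)
  for (i in 1:20) {
    x <- runif(sample(4:16, 1))
    m <- mtf(x, Q = sample(2:6, 1))
    rs <- rowSums(m$W)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
    expect_true(all(m$M >= 0 & m$M <= 1))
  }
  expect_error(mtf(runif(5), Q = 1), "Q")
  expect_error(mtf(0.5, Q = 2), "length")
})

test_that("recurrence plots are binary, symmetric, thresholded strictly", {
  r <- recurrence_plot(c(0, 1, 0.1), epsilon = 0.5)
  expect_equal(r$R, matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3, 3))
  # epsilon above max distance -> all ones
  expect_true(all(recurrence_plot(runif(8), epsilon = 2)$R == 1))
  set.seed(3)
  x <- runif(8)
  rr <- recurrence_plot(x)$R
  expect_equal(rr, t(rr))
  expect_true(all(rr %in% c(0, 1)))
  expect_equal(diag(rr), rep(1, 8))
  # constant series is fully recurrent under the data-driven threshold
  expect_true(all(recurrence_plot(rep(0.3, 8))$R == 1))
  # delay embedding shrinks the state count
  expect_equal(dim(recurrence_plot(runif(8), embedding_dim = 2, delay = 1)$R),
               c(7, 7))
  expect_error(recurrence_plot(runif(3), embedding_dim = 5, delay = 1),
               "embedding")
})

test_that("all four encodings match the brute-force oracle on random series", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:16, 1)
    x <- runif(n)
    expect_equal(gasf(to_polar(x)), oracle_gasf(x), tolerance = 1e-12)
    expect_equal(gadf(to_polar(x)), oracle_gadf(x), tolerance = 1e-12)
    Q <- sample(2:6, 1)
    expect_equal(mtf(x, Q)$M, oracle_mtf(x, Q), tolerance = 1e-12)
    eps <- runif(1, 0.05, 0.8)
    expect_equal(recurrence_plot(x, epsilon = eps)$R, oracle_rp(x, eps),
                 tolerance = 1e-12)
  }
})

test_that("gasf/gadf agree with the reference implementation", {
  # pyts-style reference values for x = [0, 0.25, 0.5, 0.75, 1]: computed
  # independently from the closed forms cos(ti+tj), sin(ti-tj) by the oracle
  x <- c(0, 0.25, 0.5, 0.75, 1)
  expect_equal(gasf(to_polar(x)), oracle_gasf(x))
  expect_equal(gadf(to_polar(x)), oracle_gadf(x))
})

test_that("window encoding stacks channels in variable order", {
  set.seed(5)
  m <- matrix(runif(80), 8, 10, dimnames = list(NULL, load_variables()))
  for (method in c("gasf", "gadf", "mtf", "rp")) {
    st <- encode_window(m, method)
    expect_equal(dim(st), c(8, 8, 10))
  }
  st <- encode_window(m, "gasf")
  expect_equal(st[, , 4], gasf(to_polar(m[, 4])))
  gd <- encode_window(m, "gadf")
  for (v in 1:10) expect_equal(diag(gd[, , v]), rep(0, 8))
  expect_error(encode_window(m, "wavelet"), "valid")
  expect_error(encode_window(m[1:7, ], "gasf"), "8-row")
})

test_that("collection encoding rescales unit-range methods to tanh range", {
  rec <- generate_cohort(3, 20, prevalence_target = 0.05, seed = 2)
  ws <- build_windows(normalize_per_athlete(rec)$records)
  for (method in c("mtf", "rp")) {
    st <- encode_windows(ws, method, rescale = TRUE)
    expect_true(all(st$x >= -1 & st$x <= 1))
    st0 <- encode_windows(ws, method, rescale = FALSE)
    expect_equal(st$x, 2 * st0$x - 1)
  }
  st <- encode_windows(ws, "gasf")
  expect_equal(dim(st$x)[2:4], c(8, 8, 10))
})
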