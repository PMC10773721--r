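test_that("balanced sampling yields exactly k per class per athlete", {
  d <- make_labelled_features(2, 10, 2)
  s <- balanced_per_athlete_sample(d$features, d$labels, d$athlete, k = 3, seed = 1)
  expect_equal(length(s$labels), 12)
  expect_equal(sum(s$labels == 1), 6)
  expect_equal(sum(s$labels == 0), 6)
  expect_error(balanced_per_athlete_sample(d$features, d$labels, d$athlete, 0),
               "positive")
})

test_that("scarce classes are drawn with replacement", {
  d <- make_labelled_features(1, 10, 1)  # single athlete, one injured sample
  d$athlete <- rep("a01", 10)
  s <- balanced_per_athlete_sample(d$features, d$labels, d$athlete, k = 3, seed = 2)
  inj_rows <- s$index[s$labels == 1]
  expect_equal(length(inj_rows), 3)
  expect_equal(length(unique(inj_rows)), 1)  # the lone injured sample, 3 times
})

test_that("athletes without injuries are excluded and reported", {
  d <- make_labelled_features(3, 8, 1)
  d$labels[d$athlete == "a02"] <- 0L
  s <- balanced_per_athlete_sample(d$features, d$labels, d$athlete, k = 2, seed = 3)
  expect_equal(s$excluded, "a02")
  expect_equal(sum(s$labels == 1), sum(s$labels == 0))
})

test_that("unbalanced subsampling hits the exact count contract", {
  d <- make_labelled_features(4, 30, 10)
  s1 <- balanced_per_athlete_sample(d$features, d$labels, d$athlete, 10, seed = 4)
  # paper-scale arithmetic: 650 injured, round(650 / 0.136) = 4779 uninjured
  s2 <- unbalanced_subsample(s1$features, s1$labels, 650, 0.136, seed = 5)
  expect_equal(sum(s2$labels == 1), 650)
  expect_equal(sum(s2$labels == 0), 4779)
  s3 <- unbalanced_subsample(s1$features, s1$labels, 10, 0.5, seed = 6)
  expect_equal(as.integer(table(s3$labels)), c(20L, 10L))
  s4 <- unbalanced_subsample(s1$features, s1$labels, 40, 1, seed = 7)
  expect_equal(sum(s4$labels == 1), sum(s4$labels == 0))
  expect_error(unbalanced_subsample(s1$features, s1$labels, 10, 0), "ratio")
})

test_that("low-discrepancy selection is deterministic and exhaustive-free", {
  d <- make_labelled_features(4, 30, 10)
  s1 <- balanced_per_athlete_sample(d$features, d$labels, d$athlete, 10, seed = 4)
  a <- unbalanced_subsample(s1$features, s1$labels, 20, 0.5, lds_offset = 0.3)
  b <- unbalanced_subsample(s1$features, s1$labels, 20, 0.5, lds_offset = 0.3)
  expect_identical(a$index, b$index)
  c2 <- unbalanced_subsample(s1$features, s1$labels, 20, 0.5, lds_offset = 0.7)
  expect_false(identical(a$index, c2$index))
})

test_that("tomek removal deletes only majority link members", {
  # 1-D: majority 0.0 and minority 0.1 are mutual nearest neighbours; the
  # second majority point at 5.0 is not in any link
  feat <- matrix(c(0.0, 0.1, 5.0), 3, 1)
  labs <- c(0L, 1L, 0L)
  out <- tomek_majority_removal(feat, labs)
  expect_equal(out$removed, 1L)
  expect_equal(out$labels, c(1L, 0L))
  expect_equal(sum(out$labels == 1), 1)

  # perfectly separated classes: nearest neighbours are within-class
  feat2 <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), 6, 1)
  labs2 <- c(1L, 1L, 1L, 0L, 0L, 0L)
  out2 <- tomek_majority_removal(feat2, labs2)
  expect_equal(length(out2$removed), 0)
  expect_equal(out2$labels, labs2)
  expect_error(tomek_majority_removal(feat2, rep(1L, 6)), "both classes")
})

test_that("tomek removal never reduces the minority class on random data", {
  set.seed(9)
  for (i in 1:5) {
    n <- 120
    feat <- matrix(rnorm(n * 3), n, 3)
    labs <- rbinom(n, 1, 0.2)
    if (length(unique(labs)) < 2) next
    out <- tomek_majority_removal(feat, labs)
    expect_equal(sum(out$labels == 1), sum(labs == 1))
    expect_lte(length(out$labels), length(labs))
  }
})

test_that("smote interpolation is convex between parent and neighbour", {
  set.seed(10)
  n_min <- 25
  Xmin <- matrix(runif(n_min * 2), n_min, 2)
  Xmaj <- matrix(runif(120 * 2, 2, 3), 120, 2)
  feat <- rbind(Xmin, Xmaj)
  labs <- c(rep(1L, n_min), rep(0L, 120))
  out <- smote_oversample(feat, labs, final_ratio = 1, smote_k = 5, seed = 11)
  expect_equal(sum(out$labels == 1), 120)
  pv <- out$provenance
  syn <- out$features[(nrow(feat) + 1):nrow(out$features), , drop = FALSE]
  for (i in seq_len(nrow(pv))) {
    d <- feat[pv$parent[i], ]; dn <- feat[pv$neighbour[i], ]
    expect_equal(unname(syn[i, ]), unname(d + pv$u[i] * (dn - d)), tolerance = 1e-12)
  }
  # convex hull membership in the axis-aligned sense
  expect_true(all(syn >= min(Xmin) - 1e-12 & syn <= max(Xmin) + 1e-12))
  expect_error(smote_oversample(feat[1:8, ], labs[1:8], smote_k = 5), "smaller k")
})

test_that("literal interpolation mode extrapolates away from the neighbour", {
  feat <- rbind(matrix(c(0, 0, 1, 1, 0.5, 0.2, 0.1, 0.9, 0.8, 0.3,
                         0.4, 0.6), 6, 2), matrix(5, 30, 2))
  labs <- c(rep(1L, 6), rep(0L, 30))
  lit <- smote_oversample(feat, labs, final_ratio = 0.5, smote_k = 3,
                          seed = 12, literal = TRUE)
  pv <- lit$provenance
  syn <- lit$features[(nrow(feat) + 1):nrow(lit$features), , drop = FALSE]
  for (i in seq_len(nrow(pv))) {
    d <- feat[pv$parent[i], ]; dn <- feat[pv$neighbour[i], ]
    expect_equal(unname(syn[i, ]), unname(d + pv$u[i] * (d - dn)), tolerance = 1e-12)
  }
})

test_that("the three-step composition reports exact per-step counts", {
  d <- make_labelled_features(8, 40, 3, p = 6, seed = 13)
  plan <- resampling_plan(per_athlete_k = 4, n_injured_target = 60,
                          ratio = 0.2, smote_k = 4, seed = 14)
  rs <- multiple_resample(d$features, d$labels, d$athlete, plan)
  counts <- rs$provenance$counts
  expect_equal(unname(counts["step1_balanced", ]), c(32, 32))
  expect_equal(unname(counts["step2_unbalanced", ]), c(60, 300))
  # tomek: minority unchanged, majority non-increasing
  expect_equal(counts["step3_tomek", "injured"], counts["step2_unbalanced", "injured"])
  expect_lte(counts["step3_tomek", "uninjured"], counts["step2_unbalanced", "uninjured"])
  # smote balances to the majority count
  expect_equal(counts["step4_smote", "injured"], counts["step4_smote", "uninjured"])

  rs2 <- multiple_resample(d$features, d$labels, d$athlete, plan)
  expect_identical(rs$features, rs2$features)

  d0 <- d; d0$labels[] <- 0L
  expect_error(multiple_resample(d0$features, d0$labels, d0$athlete, plan),
               "no injured|both")
})
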