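# Three-step multiple resampling: (1) per-athlete balanced sampling, so no
# single high-risk athlete dominates the injured class; (2) controlled
# unbalanced subsampling back to a realistic minority:majority ratio;
# (3) SMOTETomek — Tomek-link cleaning restricted to the majority class,
# then SMOTE interpolation of the minority class. Operates on flattened
# window feature vectors (resampling precedes image encoding, so synthetic
# samples are valid series).

#' Resampling plan
#'
#' Parameters of the three-step rebalancing procedure.
#'
#' @param per_athlete_k Draws per class per athlete in Step 1; `NULL` (the
#'   default) uses the ceiling of the mean injured-window count over retained
#'   athletes.
#' @param n_injured_target Injured-sample count after Step 2 (default 650).
#' @param ratio Step-2 minority/majority sampling ratio (default 0.136), so
#'   the majority count is `round(n_injured_target / ratio)`.
#' @param smote_k SMOTE neighbour count.
#' @param final_ratio Minority:majority balance SMOTE oversamples to
#'   (1 = fully balanced).
#' @param smote_literal Use the literal interpolation direction
#'   `d + u (d - d_n)` instead of the conventional `d + u (d_n - d)`.
#' @param seed Integer seed for all three steps.
#' @return A `resampling_plan` list.
#' @export
resampling_plan <- function(per_athlete_k = NULL, n_injured_target = 650L,
                            ratio = 0.136, smote_k = 5L, final_ratio = 1,
                            smote_literal = FALSE, seed = 1L) {
  if (ratio <= 0 || ratio > 1) stop_injurisk("ratio must lie in (0, 1], got %s", ratio)
  if (n_injured_target < 1) stop_injurisk("n_injured_target must be >= 1")
  if (smote_k < 1) stop_injurisk("smote_k must be >= 1")
  structure(list(per_athlete_k = per_athlete_k,
                 n_injured_target = as.integer(n_injured_target),
                 ratio = ratio, smote_k = as.integer(smote_k),
                 final_ratio = final_ratio, smote_literal = smote_literal,
                 seed = as.integer(seed)),
            class = "resampling_plan")
}

#' Step 1: balanced per-athlete sampling
#'
#' Each athlete with at least one injured and one uninjured sample
#' contributes exactly `k` injured and `k` uninjured samples, drawn with
#' replacement when fewer than `k` are available. Athletes without injured
#' samples are excluded (and reported), so the output class ratio is exactly
#' 1:1 and unbiased across athletes.
#'
#' @param features Numeric feature matrix (rows = samples).
#' @param labels Binary labels (1 = injured).
#' @param athlete Athlete id per row.
#' @param k Draws per class per athlete.
#' @param seed Integer seed.
#' @return List with `features`, `labels`, `index` (source row of each
#'   draw), and `excluded` (athletes without injured samples).
#' @export
balanced_per_athlete_sample <- function(features, labels, athlete, k, seed = 1L) {
  if (k <= 0) stop_injurisk("k must be positive, got %s", k)
  set.seed(as.integer(seed))
  idx <- integer(0); excluded <- character(0)
  for (a in unique(athlete)) {
    inj <- which(athlete == a & labels == 1)
    ok <- which(athlete == a & labels == 0)
    if (length(inj) == 0 || length(ok) == 0) { excluded <- c(excluded, a); next }
    pick <- function(pool) pool[sample.int(length(pool), k,
                                           replace = length(pool) < k)]
    idx <- c(idx, pick(inj), pick(ok))
  }
  if (length(idx) == 0) {
    stop_injurisk("no athlete has both injured and uninjured samples")
  }
  list(features = features[idx, , drop = FALSE], labels = labels[idx],
       index = idx, excluded = excluded)
}

#' Step 2: controlled unbalanced subsampling
#'
#' Draws exactly `n_injured_target` injured samples and
#' `round(n_injured_target / ratio)` uninjured samples from the balanced set
#' (without replacement when enough are available). Duplicates introduced by
#' Step 1 may persist. When `lds_offset` is supplied, selection uses the
#' deterministic golden-ratio low-discrepancy ordering instead of pseudo-
#' random draws (used by the repeated hold-out protocol to decorrelate the
#' fitting subsets across repeats).
#'
#' @param features,labels As in [balanced_per_athlete_sample()].
#' @param n_injured_target,ratio See [resampling_plan()].
#' @param seed Integer seed.
#' @param lds_offset Optional offset in `[0, 1)` for low-discrepancy
#'   selection.
#' @return List with `features`, `labels`, `index`.
#' @export
unbalanced_subsample <- function(features, labels, n_injured_target = 650L,
                                 ratio = 0.136, seed = 1L, lds_offset = NULL) {
  if (ratio <= 0) stop_injurisk("ratio must be > 0, got %s", ratio)
  if (length(labels) == 0) stop_injurisk("empty balanced set")
  n_maj <- round(n_injured_target / ratio)
  set.seed(as.integer(seed))
  draw <- function(pool, m, off) {
    if (!is.null(lds_offset)) {
      if (length(pool) >= m) pool[lds_indices(length(pool), m, lds_offset + off)]
      else pool[pmax(1L, ceiling(lds_sequence(m, lds_offset + off) * length(pool)))]
    } else {
      pool[sample.int(length(pool), m, replace = length(pool) < m)]
    }
  }
  idx <- c(draw(which(labels == 1), n_injured_target, 0),
           draw(which(labels == 0), n_maj, 0.5))
  list(features = features[idx, , drop = FALSE], labels = labels[idx], index = idx)
}

#' Step 3a: Tomek-link cleaning of the majority class
#'
#' A Tomek link is a pair of opposite-class samples that are mutual nearest
#' neighbours (Euclidean distance on the feature vectors). Only the
#' majority-class member of each link is removed; minority samples are never
#' touched.
#'
#' @param features,labels Feature matrix and binary labels.
#' @return List with `features`, `labels`, `removed` (row indices removed),
#'   and `n_links`.
#' @export
tomek_majority_removal <- function(features, labels) {
  if (length(unique(labels)) < 2) stop_injurisk("both classes must be present")
  minority <- if (sum(labels == 1) <= sum(labels == 0)) 1 else 0
  nn <- nearest_neighbour(features)
  i <- seq_along(labels)
  mutual <- nn[nn[i]] == i & labels[i] != labels[nn[i]]
  link_member <- which(mutual & labels != minority)
  keep <- setdiff(i, link_member)
  list(features = features[keep, , drop = FALSE], labels = labels[keep],
       removed = link_member, n_links = length(link_member))
}

#' Step 3b: SMOTE oversampling of the minority class
#'
#' Generates synthetic minority samples by linear interpolation
#' `d_new = d + u (d_n - d)` with `u ~ Uniform[0, 1)`, where `d_n` is drawn
#' uniformly from `d`'s `smote_k` nearest minority neighbours, until the
#' minority count reaches `ceiling(final_ratio * majority count)`. Every
#' synthetic point therefore lies on a segment between two minority samples
#' (inside the minority convex hull). The literal-direction variant
#' `d + u (d - d_n)` is available via `literal = TRUE`.
#'
#' @param features,labels Feature matrix and binary labels.
#' @param final_ratio Target minority:majority ratio.
#' @param smote_k Neighbour count (must be < minority count).
#' @param seed Integer seed.
#' @param literal Use the literal interpolation direction.
#' @return List with `features`, `labels` (originals followed by synthetic
#'   minority rows) and `provenance` (parent row, neighbour row, `u` per
#'   synthetic sample).
#' @export
smote_oversample <- function(features, labels, final_ratio = 1, smote_k = 5L,
                             seed = 1L, literal = FALSE) {
  minority <- if (sum(labels == 1) <= sum(labels == 0)) 1 else 0
  min_idx <- which(labels == minority)
  n_min <- length(min_idx); n_maj <- length(labels) - n_min
  if (n_min <= smote_k) {
    stop_injurisk("minority count (%d) must exceed smote_k (%d); use a smaller k",
                  n_min, smote_k)
  }
  target <- ceiling(final_ratio * n_maj)
  n_new <- max(0L, target - n_min)
  if (n_new == 0L) {
    return(list(features = features, labels = labels,
                provenance = data.frame(parent = integer(0),
                                        neighbour = integer(0), u = numeric(0))))
  }
  set.seed(as.integer(seed))
  Xm <- features[min_idx, , drop = FALSE]
  nb <- knn_indices(Xm, Xm, smote_k, self_index = seq_len(n_min))
  parent <- sample.int(n_min, n_new, replace = TRUE)
  pick <- nb[cbind(parent, sample.int(smote_k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  d <- Xm[parent, , drop = FALSE]
  dn <- Xm[pick, , drop = FALSE]
  d_new <- if (literal) d + u * (d - dn) else d + u * (dn - d)
  list(features = rbind(features, d_new),
       labels = c(labels, rep(minority, n_new)),
       provenance = data.frame(parent = min_idx[parent],
                               neighbour = min_idx[pick], u = u))
}

#' Full three-step multiple resampling
#'
#' Composes [balanced_per_athlete_sample()], [unbalanced_subsample()],
#' [tomek_majority_removal()] and [smote_oversample()] in order, recording
#' sample counts after every step.
#'
#' @param features,labels,athlete Training samples (rows), binary labels and
#'   athlete ids.
#' @param plan A [resampling_plan()].
#' @param lds_offset Optional low-discrepancy offset for Step 2.
#' @return A `resample_result`: list with `features`, `labels`,
#'   `provenance` (per-step counts, Tomek removals, SMOTE records).
#' @export
multiple_resample <- function(features, labels, athlete, plan = resampling_plan(),
                              lds_offset = NULL) {
  stopifnot(inherits(plan, "resampling_plan"))
  k <- plan$per_athlete_k
  if (is.null(k)) {
    per_ath_inj <- tapply(labels, athlete, sum)
    per_ath_inj <- per_ath_inj[per_ath_inj > 0]
    if (length(per_ath_inj) == 0) stop_injurisk("cohort contains no injured samples")
    k <- ceiling(mean(per_ath_inj))
  }
  s1 <- balanced_per_athlete_sample(features, labels, athlete, k,
                                    seed = derive_seed(plan$seed, 1))
  s2 <- unbalanced_subsample(s1$features, s1$labels, plan$n_injured_target,
                             plan$ratio, seed = derive_seed(plan$seed, 2),
                             lds_offset = lds_offset)
  s3 <- tomek_majority_removal(s2$features, s2$labels)
  s4 <- smote_oversample(s3$features, s3$labels, plan$final_ratio, plan$smote_k,
                         seed = derive_seed(plan$seed, 3),
                         literal = plan$smote_literal)
  counts <- function(l) c(injured = sum(l == 1), uninjured = sum(l == 0))
  prov <- list(
    per_athlete_k = k,
    excluded_athletes = s1$excluded,
    counts = rbind(input = counts(labels), step1_balanced = counts(s1$labels),
                   step2_unbalanced = counts(s2$labels),
                   step3_tomek = counts(s3$labels),
                   step4_smote = counts(s4$labels)),
    tomek_removed = s3$removed,
    smote = s4$provenance,
    seed = plan$seed
  )
  structure(list(features = s4$features, labels = s4$labels, provenance = prov),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat("<resample_result> counts by step:\n")
  print(x$provenance$counts)
  invisible(x)
}
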