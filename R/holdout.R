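# Repeated hold-out protocol: athlete-level train/test split, per-repeat
# resampling driven by a low-discrepancy sequence, DCAE + DNN fitting,
# internal validation on the whole training set, external testing on
# held-out athletes.

#' Repeated hold-out evaluation protocol
#'
#' Runs the full pipeline `repeats` times with consistent parameters. The
#' athlete split is fixed; per repeat, the training windows are rebalanced
#' by [multiple_resample()] (Step-2 subset selection driven by a
#' golden-ratio low-discrepancy sequence with a per-repeat offset, so the
#' fitting subsets differ systematically rather than by pseudo-random
#' chance), encoded, and used to fit the auto-encoder and classifier. Each
#' repeat is validated on the *entire* training set (internal validity) and
#' tested on the held-out athletes (external validity).
#'
#' @param records Day records (raw, as from [generate_cohort()]).
#' @param train_athletes,test_athletes Disjoint athlete-id vectors.
#' @param method Encoding method (`"gasf"`, `"gadf"`, `"mtf"`, `"rp"`).
#' @param plan A [resampling_plan()].
#' @param ae_spec,clf_spec Architecture specifications.
#' @param focal `NULL` (alpha from the training prevalence, gamma 3.5) or a
#'   [focal_loss_params()].
#' @param repeats Number of repeats (default 5).
#' @param threshold Decision threshold for confusion metrics.
#' @param epochs Optional epoch override applied to both networks.
#' @param seed Master seed; everything else derives from it.
#' @param verbose Progress messages.
#' @return A `run_report`: per-repeat `metric_set`s for the validation and
#'   test surfaces, their mean and SD per metric, the last repeat's fitted
#'   models, and the normalization state.
#' @export
holdout_protocol <- function(records, train_athletes, test_athletes,
                             method = "gasf", plan = resampling_plan(),
                             ae_spec = autoencoder_spec(),
                             clf_spec = classifier_spec(), focal = NULL,
                             repeats = 5L, threshold = 0.5, epochs = NULL,
                             seed = 1L, verbose = FALSE) {
  if (length(intersect(train_athletes, test_athletes)) > 0) {
    stop_injurisk("athletes appear in both the training and test split: %s",
                  paste(intersect(train_athletes, test_athletes), collapse = ", "))
  }
  train_rec <- records[records$athlete_id %in% train_athletes, ]
  test_rec <- records[records$athlete_id %in% test_athletes, ]
  if (nrow(train_rec) == 0 || nrow(test_rec) == 0) {
    stop_injurisk("empty train or test split")
  }

  # per-athlete normalization over each athlete's own history
  train_norm <- normalize_per_athlete(train_rec)
  test_norm <- normalize_per_athlete(test_rec)
  train_ws <- build_windows(train_norm$records, pad = "edge", quiet = !verbose)
  test_ws <- build_windows(test_norm$records, pad = "edge", quiet = !verbose)

  train_stacks <- encode_windows(train_ws, method = method, rescale = TRUE)
  test_stacks <- encode_windows(test_ws, method = method, rescale = TRUE)
  feat <- flatten_windows(train_ws)

  if (is.null(focal)) {
    focal <- focal_loss_params(
      compute_alpha(max(sum(train_ws$meta$label), 1), nrow(train_ws$meta)), 3.5)
  }

  phi_inv <- (sqrt(5) - 1) / 2
  base_offset <- (as.integer(seed) %% 1000L) / 1000L
  val_runs <- list(); test_runs <- list()
  encoder <- NULL; classifier <- NULL
  for (r in seq_len(repeats)) {
    if (verbose) message(sprintf("repeat %d/%d", r, repeats))
    plan_r <- plan
    plan_r$seed <- derive_seed(seed, 100 + r)
    rs <- multiple_resample(feat, train_ws$meta$label, train_ws$meta$athlete_id,
                            plan_r, lds_offset = (base_offset + r * phi_inv) %% 1)
    rs_arr <- unflatten_windows(clamp(rs$features, 0, 1), train_ws)
    rs_ws <- new_window_set(rs_arr,
                            data.frame(athlete_id = NA, day_index = NA,
                                       label = rs$labels),
                            padded = TRUE, normalized = TRUE)
    rs_stacks <- encode_windows(rs_ws, method = method, rescale = TRUE)
    encoder <- dcae_fit(rs_stacks, ae_spec, seed = derive_seed(seed, 200 + r),
                        epochs = epochs, verbose = verbose)
    lat_fit <- dcae_encode(encoder, rs_stacks)
    classifier <- dnn_fit(lat_fit, rs$labels, clf_spec, focal = focal,
                          seed = derive_seed(seed, 300 + r), epochs = epochs)
    val_probs <- predict(classifier, dcae_encode(encoder, train_stacks))
    test_probs <- predict(classifier, dcae_encode(encoder, test_stacks))
    val_runs[[r]] <- classification_metrics(train_ws$meta$label, val_probs, threshold)
    test_runs[[r]] <- classification_metrics(test_ws$meta$label, test_probs, threshold)
  }

  structure(list(
    validation = summarize_runs(val_runs),
    test = summarize_runs(test_runs),
    repeats = repeats, method = method, threshold = threshold,
    focal = focal, seed = seed,
    encoder = encoder, classifier = classifier,
    norm_state = list(train = train_norm$state, test = test_norm$state),
    windows = list(train = train_ws, test = test_ws)
  ), class = "run_report")
}

summarize_runs <- function(runs) {
  per <- do.call(rbind, lapply(runs, function(m) {
    data.frame(auc = m$auc, sensitivity = m$sensitivity,
               specificity = m$specificity, gmean = m$gmean)
  }))
  list(per_repeat = per,
       mean = vapply(per, mean, numeric(1)),
       sd = vapply(per, stats::sd, numeric(1)))
}

#' @export
print.run_report <- function(x, ...) {
  fmt <- function(s) paste(sprintf("%s %.3f +/- %.3f", names(s$mean), s$mean,
                                   ifelse(is.na(s$sd), 0, s$sd)),
                           collapse = ", ")
  cat(sprintf("<run_report> %s, %d repeats\n  validation: %s\n  test:       %s\n",
              x$method, x$repeats, fmt(x$validation), fmt(x$test)))
  invisible(x)
}

#' Export a run report as data frames
#' @param report A `run_report`.
#' @return List of data frames (`per_repeat` with a `surface` column, and
#'   `summary`).
#' @export
run_report_tables <- function(report) {
  pr <- rbind(cbind(surface = "validation", report$validation$per_repeat),
              cbind(surface = "test", report$test$per_repeat))
  sm <- rbind(
    data.frame(surface = "validation", metric = names(report$validation$mean),
               mean = unname(report$validation$mean), sd = unname(report$validation$sd)),
    data.frame(surface = "test", metric = names(report$test$mean),
               mean = unname(report$test$mean), sd = unname(report$test$sd)))
  list(per_repeat = pr, summary = sm)
}
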