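#' Generate a synthetic athlete training-log cohort
#'
#' Simulates day-level training logs for a cohort of runners with the
#' statistical structure a load-based injury-risk model assumes: rare injury
#' events, athlete-specific load scales, weekly periodization with occasional
#' high-volume blocks, and a plantable risk signal linking recent training
#' volume to injury probability.
#'
#' Each athlete has a profile (baseline daily volume, day-to-day spread, rest
#' probability, injury susceptibility). Daily loads for the ten variables
#' (see [load_variables()]) are drawn from that profile. Injury on day `t`
#' (for `t >= 8`) follows a logistic model whose linear predictor combines
#' two standardized load summaries over the preceding week:
#' the 7-day cumulative training volume (total km plus alternative-training
#' hours) and the acute day-over-day jump (yesterday's volume minus the mean
#' of the six days before it), weighted by `risk_coefficients`. The intercept
#' is calibrated by bisection against the realized draws so the achieved
#' injury prevalence over eligible days matches `prevalence_target` up to
#' count quantization; supplying `intercept` skips
#' calibration (useful for studying coefficient effects at a fixed baseline).
#'
#' @param n_athletes Number of athletes (>= 2).
#' @param n_days Days of log per athlete (>= 14).
#' @param prevalence_target Target fraction of eligible (day >= 8)
#'   athlete-days with an injury, in (0, 0.5).
#' @param risk_coefficients Length-2 numeric: effect per SD of
#'   (cumulative 7-day volume, acute jump) on the log-odds of injury.
#'   `c(0, 0)` yields i.i.d. injuries at the base rate.
#' @param susceptibility_sd SD of the athlete-level random intercept.
#' @param intercept Optional fixed logistic intercept; if `NULL` (default) it
#'   is calibrated to `prevalence_target`.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return A `data.frame` with columns `athlete_id`, `day_index`, the ten
#'   load variables, and binary `injury` (injury occurring on that day;
#'   always 0 for days 1-7, which precede the first full week of history).
#'   The attribute `"risk"` holds the generator's latent linear predictor and
#'   probability per eligible athlete-day, for signal-recovery diagnostics.
#' @export
generate_cohort <- function(n_athletes, n_days,
                            prevalence_target = 0.013,
                            risk_coefficients = c(volume = 1.5, spike = 1.0),
                            susceptibility_sd = 0.4,
                            intercept = NULL,
                            seed = 1L) {
  if (n_athletes < 2) stop_injurisk("n_athletes must be >= 2, got %s", n_athletes)
  if (n_days < 14) stop_injurisk("n_days must be >= 14, got %s", n_days)
  if (prevalence_target <= 0 || prevalence_target >= 0.5) {
    stop_injurisk("prevalence_target must lie in (0, 0.5), got %s", prevalence_target)
  }
  stopifnot(length(risk_coefficients) == 2)
  set.seed(as.integer(seed))

  vars <- load_variables()
  ids <- sprintf("ath%03d", seq_len(n_athletes))

  profiles <- data.frame(
    athlete_id = ids,
    base_km = stats::rlnorm(n_athletes, log(9), 0.25),
    rest_prob = stats::runif(n_athletes, 0.2, 0.35),
    strength_prob = stats::runif(n_athletes, 0.25, 0.45),
    alt_prob = stats::runif(n_athletes, 0.2, 0.4),
    susceptibility = stats::rnorm(n_athletes, 0, susceptibility_sd)
  )

  one_athlete <- function(a) {
    p <- profiles[a, ]
    # weekly-ish cycle plus occasional high-volume blocks
    weeks <- ceiling(n_days / 7)
    spike_week <- stats::runif(weeks) < 0.08
    cyc <- 1 + 0.25 * sin(2 * pi * seq_len(n_days) / 28)
    cyc <- cyc * ifelse(spike_week[ceiling(seq_len(n_days) / 7)], 1.5, 1)
    rest <- stats::runif(n_days) < p$rest_prob
    sessions <- ifelse(rest, 0L, 1L + (stats::runif(n_days) < 0.15))
    km <- pmax(0, stats::rnorm(n_days, p$base_km * cyc, 0.35 * p$base_km)) *
      (sessions > 0)
    z34 <- km * stats::rbeta(n_days, 2, 8)
    z5 <- km * stats::rbeta(n_days, 1.5, 12)
    sprint <- km * stats::rbeta(n_days, 1, 30)
    strength <- (stats::runif(n_days) < p$strength_prob) *
      stats::runif(n_days, 0.3, 1.5) * (sessions > 0)
    alt <- (stats::runif(n_days) < p$alt_prob) * stats::runif(n_days, 0.5, 2)
    rel_load <- km / p$base_km
    exertion <- ifelse(sessions > 0,
                       clamp(stats::rnorm(n_days, 3 + 3.5 * rel_load, 1.2), 0, 10), 0)
    success <- ifelse(sessions > 0,
                      clamp(stats::rnorm(n_days, 6.5, 1.5), 0, 10), 0)
    recovery <- clamp(stats::rnorm(n_days, 6.5 - 1.5 * rel_load, 1.2), 0, 10)
    data.frame(
      athlete_id = p$athlete_id, day_index = seq_len(n_days),
      nr_sessions = as.numeric(sessions), total_km = km, km_Z3_4 = z34,
      km_Z5_T1_T2 = z5, km_sprinting = sprint, strength_training = strength,
      hours_alternative = alt, perceived_exertion = exertion,
      perceived_trainingSuccess = success, perceived_recovery = recovery
    )
  }
  records <- do.call(rbind, lapply(seq_len(n_athletes), one_athlete))
  rownames(records) <- NULL

  # latent risk summaries per eligible athlete-day (day >= 8)
  vol <- records$total_km + records$hours_alternative
  risk <- do.call(rbind, lapply(seq_len(n_athletes), function(a) {
    i0 <- (a - 1) * n_days
    v <- vol[i0 + seq_len(n_days)]
    t <- 8:n_days
    cum7 <- vapply(t, function(d) sum(v[(d - 7):(d - 1)]), numeric(1))
    jump <- vapply(t, function(d) v[d - 1] - mean(v[(d - 7):(d - 2)]), numeric(1))
    data.frame(athlete_id = ids[a], day_index = t, cum7 = cum7, jump = jump,
               susceptibility = profiles$susceptibility[a])
  }))
  zc <- as.numeric(scale(risk$cum7))
  zj <- as.numeric(scale(risk$jump))
  base_lp <- risk$susceptibility + risk_coefficients[[1]] * zc +
    risk_coefficients[[2]] * zj

  # injuries drawn last so that identical seeds couple the uniforms across
  # different risk_coefficients settings; the indicator u < plogis(c + lp)
  # is monotone in the intercept c, so calibration can bisect on the
  # *realized* injury count rather than its expectation, making the achieved
  # prevalence match the target up to count quantization for any seed
  u <- stats::runif(nrow(risk))
  calibrated <- is.null(intercept)
  if (calibrated) {
    count <- function(c0) sum(u < stats::plogis(c0 + base_lp))
    target_n <- round(prevalence_target * nrow(risk))
    lo <- -30; hi <- 10
    if (count(hi) < target_n) {
      stop_injurisk(
        "cannot calibrate intercept: achieved prevalence at most %.5f, target %.5f",
        count(hi) / nrow(risk), prevalence_target)
    }
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (count(mid) < target_n) lo <- mid else hi <- mid
    }
    intercept <- hi
  }
  risk$lp <- intercept + base_lp
  risk$p <- stats::plogis(risk$lp)
  risk$injury <- as.integer(u < risk$p)

  records$injury <- 0L
  key <- paste(records$athlete_id, records$day_index)
  rk <- paste(risk$athlete_id, risk$day_index)
  records$injury[match(rk, key)] <- risk$injury

  realized <- mean(risk$injury)
  if (calibrated && abs(realized - prevalence_target) > 0.3 * prevalence_target) {
    stop_injurisk(
      "calibration failed: achieved prevalence %.5f outside +/-30%% of target %.5f",
      realized, prevalence_target)
  }
  attr(records, "risk") <- risk
  attr(records, "intercept") <- intercept
  records
}

#' Write day records as a day-approach CSV of sliding windows
#'
#' Converts day-level records into the day-approach layout: one row per
#' (athlete, prediction day) holding the 70 feature values of the 7 preceding
#' days, the athlete id, the prediction-day index, and the injury label.
#' Feature columns are grouped by variable, 7 day-columns per variable named
#' `<variable>_0` ... `<variable>_6`, oldest day first (`_6` is the day
#' immediately before the prediction day).
#'
#' @param records Day records as returned by [generate_cohort()].
#' @param path Output CSV path (UTF-8, header row).
#' @param variables Variable names expected in `records`.
#' @return Invisibly, the number of window rows written.
#' @export
write_day_approach_csv <- function(records, path, variables = load_variables()) {
  ws <- build_windows(records, pad = "none", variables = variables, quiet = TRUE)
  if (nrow(ws$meta) == 0) {
    stop_injurisk("no complete 7-day windows: every athlete needs >= 8 consecutive days")
  }
  n <- dim(ws$x)[1]
  feat <- matrix(ws$x, n, 70)  # (n, 7, 10): columns = variable-major groups, day oldest first
  colnames(feat) <- as.vector(vapply(variables, function(v) paste0(v, "_", 0:6),
                                     character(7)))
  out <- data.frame(feat, check.names = FALSE)
  out$athlete_id <- ws$meta$athlete_id
  out$day_index <- ws$meta$day_index
  out$injury <- ws$meta$label
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(n)
}

#' Read a day-approach CSV into a window collection
#'
#' Binds columns by position: the first 70 numeric columns are the features
#' (10 variable groups of 7 days each, oldest day first within a group),
#' followed by the athlete id, an optional `day_index` column, and the binary
#' injury label as the last column. Column naming is not required to match
#' [write_day_approach_csv()]; the public day-approach dataset layout (70
#' features, id, label) is accepted as-is.
#'
#' @param path CSV path.
#' @param variables Names to assign to the 10 variable groups.
#' @return A `window_set` (unpadded, unnormalized): list with `x`, an
#'   `n x 7 x 10` array of raw window matrices (rows = days, oldest first),
#'   and `meta` (`athlete_id`, `day_index`, `label`).
#' @export
read_day_approach_csv <- function(path, variables = load_variables()) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  nc <- ncol(df)
  if (nc != 72 && nc != 73) {
    stop_injurisk("expected 72 or 73 columns (70 features + id [+ day_index] + label), found %d", nc)
  }
  has_day <- nc == 73
  feat_cols <- 1:70
  id_col <- 71L
  day_col <- if (has_day) 72L else NA_integer_
  lab_col <- nc
  for (j in feat_cols) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop_injurisk("non-numeric value in feature column %d (%s), row %d",
                    j, names(df)[j], bad %||% 1L)
    }
    if (anyNA(df[[j]])) {
      stop_injurisk("missing value in feature column %d (%s), row %d",
                    j, names(df)[j], which(is.na(df[[j]]))[1])
    }
  }
  lab <- df[[lab_col]]
  if (anyNA(lab) || !all(lab %in% c(0, 1))) {
    bad <- which(is.na(lab) | !(lab %in% c(0, 1)))[1]
    stop_injurisk("label column must be binary 0/1; offending row %d", bad)
  }
  n <- nrow(df)
  x <- array(as.matrix(df[, feat_cols]), dim = c(n, 7, 10),
             dimnames = list(NULL, NULL, variables))
  meta <- data.frame(
    athlete_id = as.character(df[[id_col]]),
    day_index = if (has_day) as.integer(df[[day_col]]) else NA_integer_,
    label = as.integer(lab)
  )
  new_window_set(x, meta, padded = FALSE, normalized = FALSE)
}
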