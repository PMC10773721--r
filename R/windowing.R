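# Window construction: reshape day records into 7x10 matrices, pad to 8x10,
# and min-max normalize per athlete so that load patterns are comparable
# across athletes with very different absolute training volumes.

new_window_set <- function(x, meta, padded, normalized, normalization = NULL) {
  structure(list(x = x, meta = meta, padded = padded, normalized = normalized,
                 normalization = normalization),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<window_set> %d windows (%d x %d), %d athletes, %d injured (%.2f%%)\n",
              d[1], d[2], d[3], length(unique(x$meta$athlete_id)),
              sum(x$meta$label), 100 * mean(x$meta$label)))
  cat(sprintf("  padded: %s, normalized: %s\n", x$padded, x$normalized))
  invisible(x)
}

#' Per-athlete min-max normalization
#'
#' Rescales every load variable to `[0, 1]` *within each athlete*, using that
#' athlete's observed minimum and maximum over their full available history:
#' `x~ = (x - x_min) / (x_max - x_min)`. Variables that are constant for an
#' athlete map to 0 by convention. Normalizing within athletes lets a model
#' compare load *patterns* across athletes whose absolute volumes differ.
#'
#' @param records Day records (as from [generate_cohort()]).
#' @param state Optional previously computed normalization state to reuse
#'   (e.g., apply train-time state to new data from the same athletes).
#' @param variables Variable columns to normalize.
#' @return List with `records` (normalized copy) and `state`, a data frame of
#'   per (athlete, variable) `x_min`/`x_max`.
#' @export
normalize_per_athlete <- function(records, state = NULL,
                                  variables = load_variables()) {
  stopifnot(all(variables %in% names(records)))
  if (nrow(records) == 0) stop_injurisk("no records to normalize")
  if (is.null(state)) {
    state <- do.call(rbind, lapply(split(records, records$athlete_id), function(r) {
      data.frame(athlete_id = r$athlete_id[1], variable = variables,
                 x_min = vapply(variables, function(v) min(r[[v]]), numeric(1)),
                 x_max = vapply(variables, function(v) max(r[[v]]), numeric(1)))
    }))
    rownames(state) <- NULL
  }
  out <- records
  for (a in unique(records$athlete_id)) {
    rows <- records$athlete_id == a
    st <- state[state$athlete_id == a, ]
    if (nrow(st) == 0) stop_injurisk("no normalization state for athlete %s", a)
    for (v in variables) {
      s <- st[st$variable == v, ]
      rng <- s$x_max - s$x_min
      out[rows, v] <- if (rng > 0) (records[rows, v] - s$x_min) / rng else 0
    }
  }
  list(records = out, state = state)
}

#' Pad a 7-row window to 8 rows
#'
#' The auto-encoder halves and doubles the spatial size twice, so window
#' images must be 8x8; the 7-day window is padded with one extra time-step.
#' Edge padding (default) repeats the last observed day, adding no artificial
#' discontinuity to the angular/recurrence encodings; zero padding is
#' available as an alternative.
#'
#' @param m Numeric matrix with exactly 7 rows.
#' @param mode `"edge"` (repeat last row) or `"zero"` (append a zero row).
#' @return An 8-row matrix.
#' @export
pad_window <- function(m, mode = c("edge", "zero")) {
  mode <- match.arg(mode)
  if (!is.matrix(m) || nrow(m) != 7) {
    stop_injurisk("pad_window expects a 7-row matrix, got %s rows",
                  if (is.matrix(m)) nrow(m) else "non-matrix")
  }
  rbind(m, if (mode == "edge") m[7, ] else rep(0, ncol(m)))
}

#' Build sliding prediction windows from day records
#'
#' Emits one window per eligible prediction day: the 7 consecutive days
#' before day `t` form the window matrix (rows = days, oldest first) and the
#' label is day `t`'s injury indicator. Windows never cross athletes, and a
#' prediction day whose 7-day history has a gap in `day_index` is skipped.
#'
#' @param records Day records (optionally normalized first).
#' @param pad `"edge"`, `"zero"` (see [pad_window()]) or `"none"` to keep 7
#'   rows (used for CSV serialization).
#' @param variables Variable columns, in window-column order.
#' @param quiet Suppress the skipped-window message.
#' @return A `window_set`; `x` is `n x 8 x 10` (or `n x 7 x 10` for
#'   `pad = "none"`), `meta` has `athlete_id`, `day_index` (prediction day)
#'   and `label`.
#' @export
build_windows <- function(records, pad = c("edge", "zero", "none"),
                          variables = load_variables(), quiet = FALSE) {
  pad <- match.arg(pad)
  stopifnot(all(c("athlete_id", "day_index", "injury") %in% names(records)))
  mats <- list(); ath <- character(); day <- integer(); lab <- integer()
  skipped <- 0L
  for (r in split(records, records$athlete_id)) {
    r <- r[order(r$day_index), ]
    if (anyDuplicated(r$day_index)) {
      stop_injurisk("duplicate day_index for athlete %s", r$athlete_id[1])
    }
    present <- r$day_index
    lookup <- stats::setNames(seq_len(nrow(r)), present)
    m_all <- as.matrix(r[, variables])
    for (t in present[present >= min(present) + 7]) {
      hist_days <- (t - 7):(t - 1)
      if (!all(hist_days %in% present)) { skipped <- skipped + 1L; next }
      m <- m_all[lookup[as.character(hist_days)], , drop = FALSE]
      if (pad != "none") m <- pad_window(m, pad)
      mats[[length(mats) + 1L]] <- m
      ath <- c(ath, r$athlete_id[1]); day <- c(day, t)
      lab <- c(lab, r$injury[lookup[as.character(t)]])
    }
  }
  if (skipped > 0 && !quiet) {
    message(sprintf("build_windows: skipped %d prediction days with gapped history", skipped))
  }
  nr <- if (pad == "none") 7L else 8L
  n <- length(mats)
  x <- array(0, dim = c(n, nr, length(variables)),
             dimnames = list(NULL, NULL, variables))
  for (i in seq_len(n)) x[i, , ] <- mats[[i]]
  normalized <- all(x >= 0 & x <= 1)
  new_window_set(x, data.frame(athlete_id = ath, day_index = day, label = lab),
                 padded = pad != "none", normalized = normalized)
}

#' Normalize a window collection per athlete
#'
#' Same transform as [normalize_per_athlete()], but operating on an already
#' windowed collection (e.g., read from a day-approach CSV, where the day
#' records are no longer available): each athlete's per-variable min/max is
#' taken over all entries of that athlete's windows.
#'
#' @param ws A `window_set`.
#' @param state Optional reusable normalization state.
#' @return A normalized `window_set` with `normalization` state attached.
#' @export
normalize_window_set <- function(ws, state = NULL) {
  stopifnot(inherits(ws, "window_set"))
  vars <- dimnames(ws$x)[[3]]
  x <- ws$x
  if (is.null(state)) {
    state <- do.call(rbind, lapply(unique(ws$meta$athlete_id), function(a) {
      xa <- x[ws$meta$athlete_id == a, , , drop = FALSE]
      data.frame(athlete_id = a, variable = vars,
                 x_min = apply(xa, 3, min), x_max = apply(xa, 3, max))
    }))
    rownames(state) <- NULL
  }
  for (a in unique(ws$meta$athlete_id)) {
    rows <- which(ws$meta$athlete_id == a)
    st <- state[state$athlete_id == a, ]
    if (nrow(st) == 0) stop_injurisk("no normalization state for athlete %s", a)
    for (v in seq_along(vars)) {
      s <- st[st$variable == vars[v], ]
      rng <- s$x_max - s$x_min
      x[rows, , v] <- if (rng > 0) (x[rows, , v] - s$x_min) / rng else 0
    }
  }
  x <- clamp(x, 0, 1)  # reused state may not cover new extremes
  new_window_set(x, ws$meta, padded = ws$padded, normalized = TRUE,
                 normalization = state)
}

#' Pad all windows in a collection
#' @param ws An unpadded `window_set` (7-row windows).
#' @param mode See [pad_window()].
#' @return A padded `window_set` (8-row windows).
#' @export
pad_window_set <- function(ws, mode = c("edge", "zero")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ws, "window_set"))
  if (ws$padded) return(ws)
  d <- dim(ws$x)
  x <- array(0, dim = c(d[1], 8, d[3]), dimnames = dimnames(ws$x))
  x[, 1:7, ] <- ws$x
  x[, 8, ] <- if (mode == "edge") ws$x[, 7, ] else 0
  new_window_set(x, ws$meta, padded = TRUE, normalized = ws$normalized,
                 normalization = ws$normalization)
}

# Flatten windows to an n x (rows*10) feature matrix (time fastest within
# each variable), and back. Resampling operates on this representation.
flatten_windows <- function(ws) {
  d <- dim(ws$x)
  matrix(ws$x, d[1], d[2] * d[3])
}

unflatten_windows <- function(feat, template) {
  d <- dim(template$x)
  stopifnot(ncol(feat) == d[2] * d[3])
  array(feat, dim = c(nrow(feat), d[2], d[3]),
        dimnames = list(NULL, NULL, dimnames(template$x)[[3]]))
}
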