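#' Time to next exacerbation for each day
#'
#' For each query day, the number of days until the next clinician-diagnosed
#' exacerbation on or after that day; days with no later event get the
#' standard value `horizon` (default 200 days, longer than any observation
#' period).
#'
#' @param days Integer vector of query days.
#' @param event_days Integer vector of diagnosis days (may be empty).
#' @param horizon Standard time to exacerbation when no event follows.
#' @return Integer vector of the same length as `days`.
#' @export
label_time_to_exacerbation <- function(days, event_days, horizon = 200L) {
  event_days <- sort(as.integer(event_days))
  vapply(as.integer(days), function(d) {
    nxt <- event_days[event_days >= d]
    if (length(nxt)) nxt[1] - d else as.integer(horizon)
  }, integer(1))
}

#' Extract the 42-per-marker temporal feature vector at an anchor day
#'
#' The window spans the 14 daily time points `anchor - 13, ..., anchor`.
#' For each marker and each window day: the value, the differential from
#' the previous day (the first window day uses the day before the window
#' when available, else 0), and the window-local integral (cumulative sum
#' from the window start through that day) — 14 x 3 = 42 values per marker.
#' Ordering within a marker: all 14 values, then all 14 differentials, then
#' all 14 integrals, window-chronological; markers in sorted-name order.
#'
#' @param filtered Long data frame for one patient: `day`, `marker`, and a
#'   value column (default `filtered_value`).
#' @param anchor_day The window's last day.
#' @param window_days Window span in days (default 13, i.e. 14 time points).
#' @param value_col Name of the value column.
#' @return Named numeric vector of length `42 * n_markers`
#'   (`<marker>.value.<k>`, `<marker>.diff.<k>`, `<marker>.integral.<k>`),
#'   or `NULL` (with a message) if any in-window value is unavailable.
#' @export
extract_window <- function(filtered, anchor_day, window_days = 13L,
                           value_col = "filtered_value") {
  stopifnot(is.data.frame(filtered),
            all(c("day", "marker", value_col) %in% names(filtered)))
  wdays <- seq(anchor_day - window_days, anchor_day)
  n_pts <- length(wdays)
  mks <- sort(unique(filtered$marker))
  out <- numeric(0)
  for (mk in mks) {
    sub <- filtered[filtered$marker == mk, ]
    v <- sub[[value_col]][match(wdays, sub$day)]
    if (anyNA(v)) {
      message("window at anchor ", anchor_day, " skipped for marker '", mk,
              "': insufficient history")
      return(NULL)
    }
    prev <- sub[[value_col]][match(anchor_day - window_days - 1L, sub$day)]
    d1 <- if (length(prev) == 1 && !is.na(prev)) v[1] - prev else 0
    dif <- c(d1, diff(v))
    itg <- cumsum(v)
    k <- seq_len(n_pts)
    vec <- c(v, dif, itg)
    names(vec) <- c(paste0(mk, ".value.", k), paste0(mk, ".diff.", k),
                    paste0(mk, ".integral.", k))
    out <- c(out, vec)
  }
  out
}

#' Build the rolling-window feature database
#'
#' Rolls a 14-point window through each patient's filtered series one day at
#' a time and assembles two disjoint sets:
#' * development: all windows anchored within `window_days` days before (and
#'   including) each diagnosis day, plus a seeded random sample of stable-day
#'   windows (stable = at least `stable_gap` days from any event);
#' * production (blinded): windows anchored in the recovery span
#'   `(diagnosis, diagnosis + recovery_days]`, plus every window from
#'   patients with no exacerbations.
#'
#' Each window carries its time-to-exacerbation label (`horizon` for
#' non-exacerbators).
#'
#' @param filtered Long data frame `(patient_id, day, marker,
#'   filtered_value)` (from [filter_cohort()], or raw log values with a
#'   renamed column).
#' @param events Data frame `(patient_id, day)` of diagnosis days.
#' @param window_days Window span (default 13).
#' @param recovery_days Post-event recovery span excluded from development
#'   (default 42).
#' @param stable_gap Minimum distance from any event for a stable anchor
#'   (default 42).
#' @param stable_ratio Stable development windows sampled per exacerbation
#'   window (default 3).
#' @param horizon Standard tte for non-exacerbators (default 200).
#' @param seed Seed for the stable-day sample.
#' @param value_col Value column name (default `filtered_value`).
#' @return Object of class `feature_db`: list with `development` and
#'   `production` data frames (`patient_id`, `anchor_day`, `tte`, then
#'   feature columns) and a `manifest` list (window length, marker order,
#'   exclusion rules, seed).
#' @export
build_database <- function(filtered, events, window_days = 13L,
                           recovery_days = 42L, stable_gap = 42L,
                           stable_ratio = 3, horizon = 200L, seed = 1L,
                           value_col = "filtered_value") {
  stopifnot(is.data.frame(filtered), is.data.frame(events))
  mks <- sort(unique(filtered$marker))
  pats <- unique(filtered$patient_id)

  dev_rows <- list()
  prod_rows <- list()
  set.seed(seed)

  for (pid in pats) {
    sub <- filtered[filtered$patient_id == pid, ]
    ev <- sort(events$day[events$patient_id == pid])
    dmin <- min(sub$day)
    dmax <- max(sub$day)
    anchors <- seq(dmin + window_days, dmax)
    if (!length(anchors)) next
    tte <- label_time_to_exacerbation(anchors, ev, horizon)

    dist_mat <- outer(anchors, ev, "-")  # anchor - diagnosis day
    in_exac <- apply(dist_mat, 1,
                     function(r) any(r >= -window_days & r <= 0))
    in_recov <- apply(dist_mat, 1,
                      function(r) any(r > 0 & r <= recovery_days))
    stable <- apply(dist_mat, 1, function(r) all(abs(r) >= stable_gap)) &
      !in_recov & !in_exac

    grab <- function(idx) {
      rows <- lapply(idx, function(i) {
        feat <- extract_window(sub, anchors[i], window_days, value_col)
        if (is.null(feat)) return(NULL)
        cbind(data.frame(patient_id = pid, anchor_day = anchors[i],
                         tte = tte[i], stringsAsFactors = FALSE),
              as.data.frame(t(feat)))
      })
      rows[!vapply(rows, is.null, logical(1))]
    }

    if (length(ev)) {
      exac_idx <- which(in_exac)
      stable_idx <- which(stable)
      n_stable <- min(length(stable_idx),
                      ceiling(stable_ratio * length(exac_idx)))
      samp <- if (n_stable > 0) sort(sample(stable_idx, n_stable)) else integer(0)
      dev_rows <- c(dev_rows, grab(exac_idx), grab(samp))
      prod_rows <- c(prod_rows, grab(which(in_recov)))
    } else {
      prod_rows <- c(prod_rows, grab(seq_along(anchors)))
    }
  }

  development <- if (length(dev_rows)) do.call(rbind, dev_rows) else NULL
  production <- if (length(prod_rows)) do.call(rbind, prod_rows) else
    data.frame()
  if (is.null(development) || !nrow(development))
    stop("zero development windows: no exacerbation run-ups in the input",
         call. = FALSE)
  rownames(development) <- NULL
  if (nrow(production)) rownames(production) <- NULL

  structure(list(
    development = development, production = production,
    manifest = list(window_days = window_days, n_window_points = window_days + 1L,
                    markers = mks, features_per_marker = 3L * (window_days + 1L),
                    recovery_days = recovery_days, stable_gap = stable_gap,
                    stable_ratio = stable_ratio, horizon = horizon,
                    seed = seed)),
    class = "feature_db")
}

#' @export
print.feature_db <- function(x, ...) {
  cat("Feature database:", nrow(x$development), "development windows,",
      nrow(x$production), "production windows;",
      length(x$manifest$markers), "markers x",
      x$manifest$features_per_marker, "features\n")
  invisible(x)
}

feature_columns <- function(db) {
  setdiff(names(db$development), c("patient_id", "anchor_day", "tte"))
}
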