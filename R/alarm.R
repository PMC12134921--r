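#' Decision-rule configuration
#'
#' Daily risk scores are mapped to green (score > `amber_cutoff`) or amber
#' (score <= `amber_cutoff`; the boundary is amber-inclusive since the green
#' rule is strict). A day turns red when at least `red_rule[1]` of the
#' trailing `red_rule[2]` days (inclusive) are amber or red — amber-or-red
#' because a red day was amber-triggering by construction and must not reset
#' its own run.
#'
#' Two cutoffs are carried: `amber_cutoff` (default 13.4, the traffic-light
#' operating point) and `roc_cutoff` (default 21.19, the windowed-ROC
#' operating point) — they play different roles and are configured
#' separately.
#'
#' @param amber_cutoff Risk-score cutoff for amber (default 13.4 days).
#' @param roc_cutoff Windowed-ROC operating cutoff (default 21.19 days).
#' @param red_rule Integer pair: ambers required, trailing days (default
#'   c(6, 7)).
#' @param window_days Exacerbation window length before diagnosis (default
#'   13).
#' @param recovery_check_day Day after diagnosis at which recovery status is
#'   assessed (default 14).
#' @return Object of class `decision_config`.
#' @export
decision_config <- function(amber_cutoff = 13.4, roc_cutoff = 21.19,
                            red_rule = c(6L, 7L), window_days = 13L,
                            recovery_check_day = 14L) {
  stopifnot(length(red_rule) == 2, red_rule[1] <= red_rule[2],
            red_rule[1] >= 1, window_days >= 1)
  structure(list(amber_cutoff = amber_cutoff, roc_cutoff = roc_cutoff,
                 red_rule = as.integer(red_rule),
                 window_days = as.integer(window_days),
                 recovery_check_day = as.integer(recovery_check_day)),
            class = "decision_config")
}

#' Classify daily risk scores into green/amber/red outcomes
#'
#' @param scores Numeric vector of daily risk scores on a contiguous daily
#'   grid; `NA` days carry the previous day's outcome forward (logged via a
#'   message).
#' @param config A [decision_config()].
#' @return Character vector (`"green"`, `"amber"`, `"red"`) per day.
#' @export
classify_days <- function(scores, config = decision_config()) {
  stopifnot(inherits(config, "decision_config"))
  n <- length(scores)
  if (anyNA(scores)) {
    message(sum(is.na(scores)), " missing day(s): previous outcome carried forward")
    for (i in seq_len(n))
      if (is.na(scores[i]) && i > 1) scores[i] <- scores[i - 1]
  }
  amber <- !is.na(scores) & scores <= config$amber_cutoff
  need <- config$red_rule[1]
  span <- config$red_rule[2]
  out <- ifelse(amber, "amber", "green")
  # red when >= `need` amber(-or-red) days among the trailing `span` days
  run <- cumsum(amber)
  for (t in seq_len(n)) {
    lo <- max(1L, t - span + 1L)
    n_amber <- run[t] - if (lo > 1) run[lo - 1] else 0L
    if (n_amber >= need) out[t] <- "red"
  }
  out
}

#' Merge consecutive red days into called events
#'
#' @param outcomes Character vector from [classify_days()].
#' @return Data frame `(start, end)` of maximal red runs (day indices);
#'   zero rows when no reds.
#' @export
call_events <- function(outcomes) {
  red <- outcomes == "red"
  if (!any(red)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(red)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Evaluate called events against clinician-diagnosed exacerbations
#'
#' Window per true event: `[diagnosis - window_days, diagnosis]`. A true
#' event with at least one red day inside its window is a TP, otherwise an
#' FN. A called event (maximal red run) lying wholly outside all windows is
#' one FP — a run counts once, never per-day. TN is counted at day level
#' over the supplied stable days: `tn_green` counts green stable days (the
#' strict definition) and `tn_nonred` counts non-red stable days (the
#' event-arithmetic convention); PPV/NPV use `tn_green` unless
#' `tn = "nonred"`.
#'
#' @param outcomes Daily outcomes from [classify_days()] (day i = day
#'   `days[i]`, default 1..n).
#' @param true_events Integer vector of diagnosis days.
#' @param stable_days Integer vector of days counted as stable for the
#'   day-level TN denominator.
#' @param config A [decision_config()].
#' @param days Day indices of `outcomes` (default `seq_along(outcomes)`).
#' @param tn `"green"` or `"nonred"` TN convention for NPV.
#' @return Object of class `alarm_evaluation`: counts `tp`, `fp`, `fn`,
#'   `tn`, `tn_green`, `tn_nonred`, percentages `sensitivity`,
#'   `specificity_day`, `ppv`, `npv`, plus `called`, `lead_times`.
#' @export
evaluate_alarms <- function(outcomes, true_events, stable_days,
                            config = decision_config(),
                            days = seq_along(outcomes), tn = c("green", "nonred")) {
  stopifnot(inherits(config, "decision_config"))
  tn <- match.arg(tn)
  true_events <- sort(unique(as.integer(true_events)))
  if (length(true_events) > 1 &&
      any(diff(true_events) <= config$window_days))
    stop("overlapping true-event windows", call. = FALSE)
  called <- call_events(outcomes)
  called$start_day <- days[called$start]
  called$end_day <- days[called$end]

  in_window <- function(d)
    any(vapply(true_events, function(D)
      d >= D - config$window_days && d <= D, logical(1)))
  red_days <- days[outcomes == "red"]

  tp <- 0L
  fn <- 0L
  leads <- integer(0)
  for (D in true_events) {
    win_reds <- red_days[red_days >= D - config$window_days & red_days <= D]
    if (length(win_reds)) {
      tp <- tp + 1L
      # lead time: diagnosis minus first red day of the run touching the window
      run <- called[called$start_day <= win_reds[1] &
                      called$end_day >= win_reds[1], ]
      leads <- c(leads, D - run$start_day[1])
    } else {
      fn <- fn + 1L
    }
  }
  fp <- 0L
  if (nrow(called)) {
    for (i in seq_len(nrow(called))) {
      run_days <- seq(called$start_day[i], called$end_day[i])
      if (!any(vapply(run_days, in_window, logical(1)))) fp <- fp + 1L
    }
  }
  st_out <- outcomes[match(stable_days, days)]
  tn_green <- sum(st_out == "green", na.rm = TRUE)
  tn_nonred <- sum(st_out != "red", na.rm = TRUE)
  tn_used <- if (tn == "green") tn_green else tn_nonred

  pv <- alarm_predictive_values(tp, fp, fn, tn_used)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn_used,
                 tn_green = tn_green, tn_nonred = tn_nonred,
                 sensitivity = 100 * tp / max(tp + fn, 1),
                 specificity_day = 100 * tn_nonred /
                   max(length(stable_days), 1),
                 ppv = pv$ppv, npv = pv$npv,
                 called = called, lead_times = leads,
                 n_true_events = length(true_events)),
            class = "alarm_evaluation")
}

#' Event-level predictive values from alarm counts
#'
#' PPV = 100 TP / (TP + FP) with a run of consecutive red days counted as
#' one called event; NPV = 100 TN / (FN + TN) with TN counted over stable
#' days.
#'
#' @param tp,fp,fn,tn Counts.
#' @return Named list `ppv`, `npv` in percent (`NA` on empty denominator).
#' @export
alarm_predictive_values <- function(tp, fp, fn, tn) {
  list(ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       npv = if (fn + tn > 0) 100 * tn / (fn + tn) else NA_real_)
}

#' @export
print.alarm_evaluation <- function(x, ...) {
  cat(sprintf(paste0("Alarm evaluation: TP %d  FP %d  FN %d  TN %d\n",
                     "sensitivity %.1f%%  day-level specificity %.1f%%  ",
                     "PPV %.2f%%  NPV %.2f%%\n"),
              x$tp, x$fp, x$fn, x$tn, x$sensitivity, x$specificity_day,
              x$ppv, x$npv))
  if (length(x$lead_times))
    cat(sprintf("lead time median %.0f (IQR %.0f-%.0f) days\n",
                median(x$lead_times),
                quantile(x$lead_times, 0.25), quantile(x$lead_times, 0.75)))
  invisible(x)
}

#' Median (IQR) early-warning lead time
#'
#' Lead time per detected event: diagnosis day minus the first red day of
#' the run whose reds fall inside the event's window.
#'
#' @param evaluation An [evaluate_alarms()] result.
#' @return Named list `median`, `q1`, `q3`, `lead_times`.
#' @export
lead_time_summary <- function(evaluation) {
  stopifnot(inherits(evaluation, "alarm_evaluation"))
  lt <- evaluation$lead_times
  if (!length(lt)) return(list(median = NA_real_, q1 = NA_real_,
                               q3 = NA_real_, lead_times = lt))
  list(median = median(lt), q1 = unname(quantile(lt, 0.25)),
       q3 = unname(quantile(lt, 0.75)), lead_times = lt)
}

#' Fraction of events recovered (non-red) at the recovery check day
#'
#' @param outcomes Daily outcomes.
#' @param true_events Diagnosis days.
#' @param config A [decision_config()]; the check is at
#'   `diagnosis + recovery_check_day`.
#' @param days Day indices of `outcomes`.
#' @return Proportion in `[0, 1]` of assessable events whose check-day
#'   outcome is green or amber; events without follow-up are excluded with
#'   a message.
#' @export
recovery_status <- function(outcomes, true_events,
                            config = decision_config(),
                            days = seq_along(outcomes)) {
  stopifnot(inherits(config, "decision_config"))
  check <- as.integer(true_events) + config$recovery_check_day
  idx <- match(check, days)
  drop <- is.na(idx)
  if (any(drop))
    message(sum(drop), " event(s) without ", config$recovery_check_day,
            "-day follow-up excluded")
  idx <- idx[!drop]
  if (!length(idx)) return(NA_real_)
  mean(outcomes[idx] != "red")
}
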