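#' Write / read the long-format longitudinal CSV
#'
#' Interchange format for daily test results: columns `patient_id, day,
#' marker, value, batch_id, missing_flag`, UTF-8, '.' decimal, integer day
#' indices from study start. `value` holds the linear-scale concentration
#' and is empty on missing days.
#'
#' @param cohort An `exalert_cohort` (or its `series` data frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_longitudinal_csv <- function(cohort, path) {
  series <- if (inherits(cohort, "exalert_cohort")) cohort$series else cohort
  out <- data.frame(patient_id = series$patient_id, day = series$day,
                    marker = series$marker,
                    value = series$value,
                    batch_id = series$batch_id,
                    missing_flag = as.integer(series$missing))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_longitudinal_csv
#' @param events_path Output file for the events CSV (`patient_id, day`).
#' @export
write_events_csv <- function(cohort, events_path) {
  events <- if (inherits(cohort, "exalert_cohort")) cohort$events else cohort
  write.csv(events[c("patient_id", "day")], events_path, row.names = FALSE,
            quote = FALSE)
  invisible(events_path)
}

#' Read a longitudinal CSV into cohort structures
#'
#' Validates the header (`patient_id, day, marker, value, batch_id`, with
#' `missing_flag` optional), integer days, positive-or-missing
#' concentrations (empty field = missing, never zero), and per-patient
#' non-decreasing batch ids. Adds `log_value = log10(value)`.
#'
#' @param path CSV path.
#' @return A long series data frame as in [generate_cohort()]'s `series`.
#' @export
read_longitudinal_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  expected <- c("patient_id", "day", "marker", "value", "batch_id")
  extra <- setdiff(names(df), c(expected, "missing_flag"))
  if (length(extra) || !all(expected %in% names(df)))
    stop("unexpected header; expected columns: ",
         paste(c(expected, "[missing_flag]"), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$day) || any(df$day != as.integer(df$day)))
    stop("'day' must be integer", call. = FALSE)
  bad <- which(!is.na(df$value) & df$value <= 0)
  if (length(bad))
    stop("non-positive concentration at row ", bad[1], call. = FALSE)
  for (pid in unique(df$patient_id)) {
    for (mk in unique(df$marker)) {
      idx <- which(df$patient_id == pid & df$marker == mk)
      o <- idx[order(df$day[idx])]
      if (is.unsorted(df$batch_id[o])) {
        row <- o[which(diff(df$batch_id[o]) < 0)[1] + 1L]
        stop("non-monotone batch_id at row ", row, call. = FALSE)
      }
    }
  }
  df$missing <- is.na(df$value)
  df$log_value <- log10(df$value)
  df$day <- as.integer(df$day)
  df[c("patient_id", "day", "marker", "log_value", "value", "batch_id",
       "missing")]
}

#' Read an events CSV
#'
#' @param path CSV with columns `patient_id, day`.
#' @return Data frame `(patient_id, day)`.
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "day") %in% names(df)))
    stop("events CSV needs columns patient_id, day", call. = FALSE)
  df$day <- as.integer(df$day)
  df[c("patient_id", "day")]
}

#' Pipeline configuration
#'
#' Bundles the stage configurations and a root seed from which every stage
#' that consumes randomness derives a sub-seed.
#'
#' @param cohort A [cohort_config()].
#' @param effect_sizes Per-marker log10 shifts for the paired discovery
#'   samples (default: `shift_magnitude` for informative markers, 0
#'   otherwise).
#' @param priors A [dlm_priors()].
#' @param mcmc List with `n_iter`, `n_burn`, `thin` for the DLM stage.
#' @param ann An [ann_config()].
#' @param decision A [decision_config()].
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "discover", "fit_dlm", "features", "train", "predict",
#'   "alarm", "evaluate")`. Disabling `fit_dlm` makes the feature stage
#'   operate on raw log10 values (documented fallback).
#' @param calibrate_cutoff If `TRUE` (default), the alarm stage replaces
#'   `decision$amber_cutoff` with the Youden-optimal risk cutoff separating
#'   13-day pre-exacerbation windows from the rest of the development set —
#'   the same data-driven construction that produced the reference
#'   operating points; `FALSE` keeps the configured cutoff.
#' @param stable_ratio,seed Passed through to the feature stage / root seed.
#' @param filter_component State component used as the feature value
#'   (default `"fluct"`: the filtered deviation from the personalised
#'   baseline, which makes features comparable across patients; see
#'   [kalman_filter()]).
#' @param out_dir Output directory for stage files (`NULL` = keep results in
#'   memory only).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            effect_sizes = NULL,
                            priors = dlm_priors(),
                            mcmc = list(n_iter = 1500L, n_burn = 500L,
                                        thin = 2L),
                            ann = ann_config(max_steps = 3L, n_mc_splits = 2L,
                                             hidden_nodes_grid = c(2L, 4L)),
                            decision = decision_config(),
                            stages = c("simulate", "discover", "fit_dlm",
                                       "features", "train", "predict",
                                       "alarm", "evaluate"),
                            stable_ratio = 3, seed = 1L,
                            calibrate_cutoff = TRUE,
                            filter_component = "fluct", out_dir = NULL) {
  all_stages <- c("simulate", "discover", "fit_dlm", "features", "train",
                  "predict", "alarm", "evaluate")
  stopifnot(all(stages %in% all_stages))
  if (is.null(effect_sizes)) {
    effect_sizes <- setNames(
      ifelse(cohort$marker_names %in% cohort$informative_markers,
             cohort$shift_magnitude, 0), cohort$marker_names)
  }
  structure(list(cohort = cohort, effect_sizes = effect_sizes,
                 priors = priors, mcmc = mcmc, ann = ann,
                 decision = decision, stages = stages,
                 stable_ratio = stable_ratio,
                 seed = as.integer(seed),
                 calibrate_cutoff = isTRUE(calibrate_cutoff),
                 filter_component = filter_component, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order: simulate a cohort, run the paired
#' discovery screen and panel fit, fit the DLM per marker and causally
#' filter every series, build the rolling-window feature database, select
#' inputs and train the risk network, predict daily risk scores, apply the
#' traffic-light rules, and evaluate. Re-running with an identical
#' configuration reproduces all outputs exactly.
#'
#' The DLM stage fits one model per marker on the series of the first
#' patient with the most complete data for that marker, and filters every
#' series with the marker's posterior-mean parameters (per-marker prior
#' sharing; per-series fitting is available directly via [fit_dlm()]).
#'
#' @param config A [pipeline_config()].
#' @return A report list with the per-stage results that were run:
#'   `cohort`, `screen`, `panel`, `dlm_fits`, `filtered`, `db`, `trace`,
#'   `model`, `risk`, `alarms`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  res <- list()
  save_csv <- function(df, name) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
    }
  }

  if ("simulate" %in% st) {
    res$cohort <- generate_cohort(config$cohort)
    if (!is.null(config$out_dir)) {
      write_longitudinal_csv(res$cohort,
                             file.path(config$out_dir, "series.csv"))
      write_events_csv(res$cohort, file.path(config$out_dir, "events.csv"))
    }
  }

  if ("discover" %in% st) {
    pairs <- generate_paired_samples(config$cohort, config$effect_sizes)
    res$screen <- screen_biomarkers(pairs)
    save_csv(as.data.frame(res$screen), "screen.csv")
    sel <- res$screen$marker[res$screen$selected]
    if (length(sel) >= 2) {
      res$panel <- tryCatch(fit_panel(pairs, sel), error = function(e) {
        warning("panel fit failed: ", conditionMessage(e))
        NULL
      })
      if (!is.null(res$panel) && !is.null(config$out_dir))
        jsonlite::write_json(
          list(intercept = res$panel$intercept,
               coefficients = as.list(res$panel$coefficients),
               retained_markers = res$panel$retained_markers),
          file.path(config$out_dir, "panel.json"),
          digits = NA, auto_unbox = TRUE)
    }
  }

  if (any(c("features", "predict", "alarm", "evaluate") %in% st) &&
      is.null(res$cohort))
    stop("stage 'simulate' must run before downstream stages", call. = FALSE)

  if ("fit_dlm" %in% st) {
    series <- res$cohort$series
    fits <- list()
    for (mk in config$cohort$marker_names) {
      smk <- series[series$marker == mk, ]
      counts <- tapply(!smk$missing, smk$patient_id, sum)
      pid <- names(counts)[which.max(counts)]
      fits[[mk]] <- fit_dlm(smk[smk$patient_id == pid, ],
                            priors = config$priors,
                            n_iter = config$mcmc$n_iter,
                            n_burn = config$mcmc$n_burn,
                            thin = config$mcmc$thin,
                            seed = config$seed + match(mk, config$cohort$marker_names))
    }
    res$dlm_fits <- fits
  }

  if (any(c("features", "predict", "alarm", "evaluate", "train") %in% st)) {
    if (!is.null(res$dlm_fits)) {
      params <- lapply(res$dlm_fits, `[[`, "params")
      res$filtered <- filter_cohort(res$cohort, params,
                                    component = config$filter_component)
    } else {
      # fallback: raw log10 values stand in for filtered values
      s <- res$cohort$series
      res$filtered <- data.frame(patient_id = s$patient_id, day = s$day,
                                 marker = s$marker,
                                 filtered_value = s$log_value,
                                 filtered_sd = NA_real_,
                                 observed = !s$missing)
    }
    save_csv(res$filtered, "filtered.csv")
  }

  if ("features" %in% st || "train" %in% st) {
    res$db <- build_database(res$filtered, res$cohort$events,
                             window_days = config$decision$window_days,
                             recovery_days = config$cohort$recovery_days,
                             stable_ratio = config$stable_ratio,
                             seed = config$seed + 101L)
  }

  if ("train" %in% st) {
    cfg_ann <- config$ann
    cfg_ann$seed <- config$seed + 211L
    res$trace <- stepwise_select(res$db, cfg_ann)
    res$model <- train_final(res$db, res$trace)
    if (!is.null(config$out_dir))
      write_ann_json(res$model, file.path(config$out_dir, "model.json"))
  }

  if ("predict" %in% st && !is.null(res$model)) {
    risk <- list()
    for (pid in unique(res$filtered$patient_id)) {
      sub <- res$filtered[res$filtered$patient_id == pid, ]
      anchors <- seq(min(sub$day) + config$decision$window_days, max(sub$day))
      feats <- lapply(anchors, function(a)
        extract_window(sub, a, config$decision$window_days))
      keep <- !vapply(feats, is.null, logical(1))
      if (!any(keep)) next
      fm <- do.call(rbind, feats[keep])
      risk[[pid]] <- data.frame(patient_id = pid, day = anchors[keep],
                                risk_score = predict_risk(res$model, fm))
    }
    res$risk <- do.call(rbind, risk)
    rownames(res$risk) <- NULL
    save_csv(res$risk, "risk.csv")
  }

  if ("alarm" %in% st && !is.null(res$risk)) {
    decision <- config$decision
    if (config$calibrate_cutoff && !is.null(res$model) &&
        !is.null(res$db)) {
      dev <- res$db$development
      dev_risk <- predict_risk(res$model, dev)
      pos <- dev$tte <= decision$window_days
      if (any(pos) && !all(pos)) {
        yd <- youden_cutoff(roc_auc(-dev_risk, pos, ci = FALSE))
        decision$amber_cutoff <- -yd$cutoff
        res$calibrated_cutoff <- decision$amber_cutoff
      }
    }
    evals <- list()
    outcomes_all <- list()
    for (pid in unique(res$risk$patient_id)) {
      sub <- res$risk[res$risk$patient_id == pid, ]
      outc <- classify_days(sub$risk_score, decision)
      outcomes_all[[pid]] <- data.frame(patient_id = pid, day = sub$day,
                                        outcome = outc)
      ev <- res$cohort$events$day[res$cohort$events$patient_id == pid]
      stable <- sub$day[vapply(sub$day, function(d)
        !length(ev) || all(abs(d - ev) > config$cohort$recovery_days),
        logical(1))]
      evals[[pid]] <- evaluate_alarms(outc, ev, stable, decision,
                                      days = sub$day)
    }
    res$alarms <- evals
    res$outcomes <- do.call(rbind, outcomes_all)
    save_csv(res$outcomes, "outcomes.csv")
  }

  if ("evaluate" %in% st && !is.null(res$alarms)) {
    tp <- sum(vapply(res$alarms, `[[`, integer(1), "tp"))
    fp <- sum(vapply(res$alarms, `[[`, integer(1), "fp"))
    fn <- sum(vapply(res$alarms, `[[`, integer(1), "fn"))
    tn <- sum(vapply(res$alarms, `[[`, integer(1), "tn"))
    leads <- unlist(lapply(res$alarms, `[[`, "lead_times"))
    pv <- alarm_predictive_values(tp, fp, fn, tn)
    miss_n <- sum(res$cohort$series$missing)
    total_n <- nrow(res$cohort$series)
    res$report <- list(
      events = list(tp = tp, fp = fp, fn = fn, tn = tn,
                    ppv = pv$ppv, npv = pv$npv,
                    sensitivity = 100 * tp / max(tp + fn, 1)),
      lead_time = if (length(leads))
        list(median = median(leads),
             q1 = unname(quantile(leads, 0.25)),
             q3 = unname(quantile(leads, 0.75))) else NULL,
      compliance = compliance_summary(total_n, total_n - miss_n,
                                      total_n - miss_n))
    if (!is.null(config$out_dir))
      jsonlite::write_json(res$report,
                           file.path(config$out_dir, "report.json"),
                           digits = NA, auto_unbox = TRUE)
  }
  res
}
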