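#' Configuration for the synthetic telemonitoring cohort
#'
#' Defines the statistical structure of simulated daily home urine-biomarker
#' series: a per-patient log10 baseline, a slow random-walk drift, step
#' changes at test-device batch boundaries, an AR(1) day-to-day fluctuation,
#' observation noise, completely-at-random missingness, a linear
#' pre-exacerbation rise in the informative markers over a `lead_days`
#' lead-in, and an exponential post-exacerbation recovery decay.
#'
#' All concentrations are generated on the log10 scale; `ar_sd` and `obs_sd`
#' default to 0.04 log10 units, i.e. day-to-day fluctuations of roughly
#' plus or minus 10% of the local level on the linear scale.
#'
#' @param n_patients Number of patients.
#' @param n_days Study days per patient.
#' @param marker_names Character vector of biomarker identifiers.
#' @param baseline_mean,baseline_sd Mean and between-patient SD of the
#'   per-patient log10 baseline concentration.
#' @param drift_sd Per-day SD of the slow random-walk drift (log10 units).
#' @param ar_coef AR(1) coefficient of the short-term fluctuation, in (-1, 1).
#' @param ar_sd Innovation SD of the AR(1) fluctuation (log10 units).
#' @param obs_sd Observation-noise SD (log10 units).
#' @param batch_length Days per test-device batch.
#' @param batch_sd SD of the log10 step change at each batch boundary.
#' @param missing_prob Probability that a day's test is missing (MCAR).
#' @param exac_hazard Per-day exacerbation hazard while at risk.
#' @param lead_days Length of the pre-exacerbation biomarker rise (days).
#' @param shift_magnitude Peak pre-exacerbation log10 rise of informative
#'   markers, reached on the diagnosis day.
#' @param recovery_days Post-exacerbation recovery span (days); the rise
#'   decays exponentially with half-life `recovery_days / 4`.
#' @param informative_markers Subset of `marker_names` that carry the
#'   pre-exacerbation shift.
#' @param seed Integer seed; fanned out to per-patient and per-series
#'   substreams so adding a patient does not perturb the others.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 30L, n_days = 180L,
                          marker_names = c("NGAL", "TIMP1", "CRP",
                                           "fibrinogen", "CC16"),
                          baseline_mean = 2, baseline_sd = 0.3,
                          drift_sd = 0.005,
                          ar_coef = 0.7, ar_sd = 0.04, obs_sd = 0.04,
                          batch_length = 28L, batch_sd = 0.05,
                          missing_prob = 0.12,
                          exac_hazard = 0.003,
                          lead_days = 13L, shift_magnitude = 0.3,
                          recovery_days = 42L,
                          informative_markers = marker_names,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_days = as.integer(n_days),
              marker_names = as.character(marker_names),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              drift_sd = drift_sd, ar_coef = ar_coef, ar_sd = ar_sd,
              obs_sd = obs_sd, batch_length = as.integer(batch_length),
              batch_sd = batch_sd, missing_prob = missing_prob,
              exac_hazard = exac_hazard, lead_days = as.integer(lead_days),
              shift_magnitude = shift_magnitude,
              recovery_days = as.integer(recovery_days),
              informative_markers = as.character(informative_markers),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid cohort_config field '", field, "': ", what,
                          call. = FALSE)
  }
  chk(cfg$n_patients >= 1, "n_patients", "must be >= 1")
  chk(cfg$n_days >= 1, "n_days", "must be >= 1")
  chk(length(cfg$marker_names) >= 1 && !anyDuplicated(cfg$marker_names),
      "marker_names", "must be non-empty and unique")
  for (f in c("baseline_sd", "drift_sd", "ar_sd", "obs_sd", "batch_sd"))
    chk(is.finite(cfg[[f]]) && cfg[[f]] >= 0, f, "must be a finite sd >= 0")
  chk(is.finite(cfg$ar_coef) && abs(cfg$ar_coef) < 1, "ar_coef",
      "must lie in (-1, 1)")
  for (f in c("missing_prob", "exac_hazard"))
    chk(is.finite(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f,
        "must be a probability in [0, 1]")
  chk(cfg$lead_days >= 1, "lead_days", "must be >= 1")
  chk(cfg$recovery_days >= 0, "recovery_days", "must be >= 0")
  chk(cfg$batch_length >= 1, "batch_length", "must be >= 1")
  chk(all(cfg$informative_markers %in% cfg$marker_names),
      "informative_markers", "must be a subset of marker_names")
  invisible(cfg)
}

# deterministic substream seed; adding patients/markers never perturbs
# existing series (patient i, marker j each get their own stream)
substream_seed <- function(seed, patient, marker = 0L) {
  (as.integer(seed) * 48271L %% 2147483647L +
     patient * 10007L + marker * 101L) %% 2147483647L
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates one log10-concentration series per patient and marker, plus an
#' event table of exacerbation (clinician-diagnosis) days. The signal is
#' baseline + random-walk drift + batch step offsets + AR(1) fluctuation +
#' pre-exacerbation shift (informative markers only: a linear ramp from 0 at
#' `diagnosis - lead_days` to `shift_magnitude` on the diagnosis day, then
#' exponential decay with half-life `recovery_days / 4`) + observation noise.
#' Missing days are drawn independently with probability `missing_prob`.
#' Successive events within a patient are separated by more than
#' `recovery_days`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `exalert_cohort`: a list with
#'   * `series`: long data frame `(patient_id, day, marker, log_value, value,
#'     batch_id, missing)` where `log_value`/`value` are `NA` on missing days,
#'   * `events`: data frame `(patient_id, day)` of diagnosis days,
#'   * `config`: the generating configuration.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  days <- seq_len(cfg$n_days)
  batch_id <- (days - 1L) %/% cfg$batch_length + 1L

  ev_list <- vector("list", cfg$n_patients)
  ser_list <- vector("list", cfg$n_patients)

  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%03d", i)

    # patient substream: events, then batch offsets (shared across markers)
    set.seed(substream_seed(cfg$seed, i, 0L))
    ev <- integer(0)
    if (cfg$exac_hazard > 0) {
      blocked_until <- 0L
      u <- runif(cfg$n_days)
      for (d in days) {
        if (d > blocked_until && u[d] < cfg$exac_hazard) {
          ev <- c(ev, d)
          blocked_until <- d + cfg$recovery_days
        }
      }
    }
    n_batches <- max(batch_id)
    batch_offset_by_batch <- c(0, rnorm(n_batches - 1L, 0, cfg$batch_sd))
    batch_offset <- cumsum(batch_offset_by_batch)[batch_id]

    shift_profile <- exac_shift_profile(days, ev, cfg$lead_days,
                                        cfg$recovery_days)

    per_marker <- vector("list", length(cfg$marker_names))
    for (j in seq_along(cfg$marker_names)) {
      mk <- cfg$marker_names[j]
      set.seed(substream_seed(cfg$seed, i, j))
      baseline <- rnorm(1, cfg$baseline_mean, cfg$baseline_sd)
      drift <- cumsum(rnorm(cfg$n_days, 0, cfg$drift_sd))
      s <- numeric(cfg$n_days)
      s_prev <- if (cfg$ar_sd > 0)
        rnorm(1, 0, cfg$ar_sd / sqrt(1 - cfg$ar_coef^2)) else 0
      inn <- rnorm(cfg$n_days, 0, cfg$ar_sd)
      for (d in days) {
        s_prev <- cfg$ar_coef * s_prev + inn[d]
        s[d] <- s_prev
      }
      eps <- rnorm(cfg$n_days, 0, cfg$obs_sd)
      shift <- if (mk %in% cfg$informative_markers)
        cfg$shift_magnitude * shift_profile else 0
      logv <- baseline + drift + batch_offset + s + shift + eps
      miss <- runif(cfg$n_days) < cfg$missing_prob
      logv[miss] <- NA_real_
      per_marker[[j]] <- data.frame(
        patient_id = pid, day = days, marker = mk,
        log_value = logv, value = 10^logv,
        batch_id = batch_id, missing = miss,
        stringsAsFactors = FALSE)
    }
    ser_list[[i]] <- do.call(rbind, per_marker)
    ev_list[[i]] <- if (length(ev))
      data.frame(patient_id = pid, day = ev, stringsAsFactors = FALSE)
    else NULL
  }

  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(patient_id = character(0), day = integer(0))
  out <- list(series = do.call(rbind, ser_list), events = events,
              config = cfg)
  class(out) <- "exalert_cohort"
  out
}

# ramp 0 -> 1 over lead_days ending at each diagnosis day, then exponential
# decay with half-life recovery_days/4; profiles from multiple events add
exac_shift_profile <- function(days, event_days, lead_days, recovery_days) {
  prof <- numeric(length(days))
  half_life <- max(recovery_days / 4, 1e-9)
  for (D in event_days) {
    rel <- days - D
    up <- rel >= -lead_days & rel <= 0
    prof[up] <- prof[up] + (1 + rel[up] / lead_days)
    dn <- rel > 0
    prof[dn] <- prof[dn] + 2^(-rel[dn] / half_life)
  }
  prof
}

#' @export
print.exalert_cohort <- function(x, ...) {
  cat("Synthetic telemonitoring cohort:",
      x$config$n_patients, "patients x", x$config$n_days, "days x",
      length(x$config$marker_names), "markers;",
      nrow(x$events), "exacerbation events\n")
  invisible(x)
}

#' Generate paired stable/exacerbation samples
#'
#' Produces one stable and one exacerbation concentration per patient and
#' marker (linear scale) for the discovery stage. Stable values are lognormal
#' around the per-patient baseline; exacerbation values are shifted on the
#' log10 scale by `effect_sizes`. With zero effect sizes the two members of
#' each pair are exchangeable.
#'
#' @param config A [cohort_config()]; `n_patients`, `baseline_mean`,
#'   `baseline_sd`, `obs_sd`, `marker_names` and `seed` are used.
#' @param effect_sizes Named numeric vector of per-marker log10 shifts
#'   (names in `config$marker_names`; unnamed scalar recycles to all).
#' @return A `paired_samples` data frame: `patient_id`, `state`
#'   (`"stable"`/`"exacerbation"`), one column per marker (concentrations).
#' @export
generate_paired_samples <- function(config, effect_sizes = 0) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  mks <- config$marker_names
  if (is.null(names(effect_sizes))) {
    if (length(effect_sizes) == 1) effect_sizes <- rep(effect_sizes, length(mks))
    stopifnot(length(effect_sizes) == length(mks))
    names(effect_sizes) <- mks
  }
  eff <- setNames(numeric(length(mks)), mks)
  eff[names(effect_sizes)] <- effect_sizes
  if (any(!is.finite(eff)))
    stop("non-finite effect size for marker(s): ",
         paste(names(eff)[!is.finite(eff)], collapse = ", "), call. = FALSE)

  set.seed(substream_seed(config$seed, 0L, 0L))
  n <- config$n_patients
  stable <- exac <- matrix(NA_real_, n, length(mks),
                           dimnames = list(NULL, mks))
  for (j in seq_along(mks)) {
    baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
    stable[, j] <- 10^(baseline + rnorm(n, 0, config$obs_sd))
    exac[, j] <- 10^(baseline + eff[j] + rnorm(n, 0, config$obs_sd))
  }
  pid <- sprintf("P%03d", seq_len(n))
  out <- rbind(
    data.frame(patient_id = pid, state = "stable", stable,
               stringsAsFactors = FALSE, check.names = FALSE),
    data.frame(patient_id = pid, state = "exacerbation", exac,
               stringsAsFactors = FALSE, check.names = FALSE))
  rownames(out) <- NULL
  class(out) <- c("paired_samples", "data.frame")
  out
}
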