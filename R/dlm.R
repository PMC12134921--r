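#' Dynamic linear model parameters
#'
#' The per-biomarker state-space model has four variances and one
#' autoregressive coefficient: observation variance `V`, level (slow-drift)
#' innovation variance `W_mu`, AR(1) innovation variance `W_s` with
#' coefficient `phi`, and batch-step variance `W_b` injected only at
#' device-batch boundaries. All variances are on the squared log10 scale.
#'
#' @param V,W_mu,W_s,W_b Variances, all >= 0.
#' @param phi AR(1) coefficient in (-1, 1).
#' @return Object of class `dlm_params`.
#' @export
dlm_params <- function(V = 0.0016, W_mu = 2.5e-05, W_s = 0.0016,
                       W_b = 0.0025, phi = 0.7) {
  stopifnot(V >= 0, W_mu >= 0, W_s >= 0, W_b >= 0, abs(phi) < 1)
  structure(list(V = V, W_mu = W_mu, W_s = W_s, W_b = W_b, phi = phi),
            class = "dlm_params")
}

#' @export
print.dlm_params <- function(x, ...) {
  cat(sprintf("DLM params: V=%.3g W_mu=%.3g W_s=%.3g W_b=%.3g phi=%.3f\n",
              x$V, x$W_mu, x$W_s, x$W_b, x$phi))
  invisible(x)
}

#' Priors for the dynamic linear model
#'
#' Inverse-gamma priors on each variance and a uniform prior on the AR
#' coefficient. Because the model works on log10 concentrations, a prior
#' judgement that day-to-day variation is about plus or minus 10% of the
#' local level translates into a prior mean SD of about 0.04 log10 units for
#' the observation and AR components; the slow drift gets a weaker prior
#' (mean SD 0.01).
#'
#' @param v_shape,v_scale Inverse-gamma shape/scale for `V`.
#' @param wmu_shape,wmu_scale For `W_mu`.
#' @param ws_shape,ws_scale For `W_s`.
#' @param wb_shape,wb_scale For `W_b`.
#' @param phi_lo,phi_hi Uniform support of `phi`, within (-1, 1).
#' @param m0,C0 Prior mean and variance of the initial level.
#' @return Object of class `dlm_priors`.
#' @export
dlm_priors <- function(v_shape = 2, v_scale = 0.0016,
                       wmu_shape = 2, wmu_scale = 1e-04,
                       ws_shape = 2, ws_scale = 0.0016,
                       wb_shape = 2, wb_scale = 0.0025,
                       phi_lo = 0, phi_hi = 0.99,
                       m0 = NULL, C0 = 1) {
  shp <- c(v_shape, wmu_shape, ws_shape, wb_shape)
  scl <- c(v_scale, wmu_scale, ws_scale, wb_scale)
  stopifnot(all(shp > 0), all(scl > 0),
            phi_lo < phi_hi, phi_lo > -1, phi_hi < 1, C0 >= 0)
  structure(list(shape = shp, scale = scl, phi_lo = phi_lo, phi_hi = phi_hi,
                 m0 = m0, C0 = C0), class = "dlm_priors")
}

# coerce a series to the canonical per-series frame: contiguous integer
# days, log_value (NA = missing), batch_id (non-decreasing)
as_series_frame <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("day", "log_value", "batch_id") %in% names(series)))
  series <- series[order(series$day), ]
  if (anyDuplicated(series$day)) stop("duplicate days in series", call. = FALSE)
  if (is.unsorted(series$batch_id))
    stop("batch_id must be non-decreasing over days", call. = FALSE)
  full <- data.frame(day = seq(min(series$day), max(series$day)))
  out <- merge(full, series[c("day", "log_value", "batch_id")],
               by = "day", all.x = TRUE)
  # days absent from the input are missing; carry the batch id forward
  if (anyNA(out$batch_id)) {
    for (i in seq_len(nrow(out)))
      if (is.na(out$batch_id[i]) && i > 1) out$batch_id[i] <- out$batch_id[i - 1]
    out$batch_id[is.na(out$batch_id)] <- out$batch_id[which(!is.na(out$batch_id))[1]]
  }
  out
}

#' Strictly causal Kalman filter for one biomarker series
#'
#' Runs the state-space filter over (level, AR fluctuation, batch offset)
#' and reports, for each day t, the filtered mean and SD of the requested
#' state component given observations on days <= t only. On missing days
#' the update step is skipped (pure prediction).
#'
#' Components: `"level_fluct"` (default) is level + fluctuation, the
#' physiological signal with the device-batch offset removed; `"fluct"` is
#' the short-term fluctuation alone, i.e. the deviation from the patient's
#' personalised (slowly drifting) baseline; `"level"` is the baseline
#' itself; `"all"` adds the batch offset back.
#'
#' @param series Data frame with `day`, `log_value` (NA = missing),
#'   `batch_id`.
#' @param params A [dlm_params()].
#' @param m0 Prior mean of the initial level; default: first non-missing
#'   observation.
#' @param C0 Prior variance of the initial level (default 1).
#' @param component Which state combination to report (see Details).
#' @return Data frame of class `filtered_series`: `day`, `filtered_value`,
#'   `filtered_sd`, `observed`; attribute `loglik` holds the
#'   prediction-error-decomposition log-likelihood.
#' @export
kalman_filter <- function(series, params, m0 = NULL, C0 = 1,
                          component = c("level_fluct", "fluct", "level",
                                        "all")) {
  stopifnot(inherits(params, "dlm_params"))
  component <- match.arg(component)
  sf <- as_series_frame(series)
  y <- sf$log_value
  if (any(!is.finite(y) & !is.na(y)))
    stop("non-finite observations in series", call. = FALSE)
  if (is.null(m0)) {
    first_obs <- y[!is.na(y)][1]
    m0 <- if (is.na(first_obs)) 0 else first_obs
  }
  res <- kalman_filter_cpp(ifelse(is.na(y), NA_real_, y),
                           as.integer(sf$batch_id),
                           params$V, params$W_mu, params$W_s, params$W_b,
                           params$phi, m0, C0)
  val <- switch(component,
                level_fluct = as.numeric(res$filtered),
                fluct = res$state_mean[, 2],
                level = res$state_mean[, 1],
                all = as.numeric(res$filtered_with_batch))
  vr <- switch(component,
               level_fluct = as.numeric(res$filtered_var),
               fluct = as.numeric(res$fluct_var),
               level = as.numeric(res$level_var),
               all = as.numeric(res$filtered_with_batch_var))
  out <- data.frame(
    day = sf$day,
    filtered_value = val,
    filtered_sd = sqrt(pmax(vr, 0)),
    observed = as.logical(res$observed))
  attr(out, "loglik") <- res$loglik
  attr(out, "params") <- params
  attr(out, "component") <- component
  class(out) <- c("filtered_series", "data.frame")
  out
}

#' Filter log-likelihood of a series under given parameters
#'
#' Log-likelihood of the observed values by the prediction-error
#' decomposition of the causal filter.
#'
#' @inheritParams kalman_filter
#' @return Scalar log-likelihood.
#' @export
dlm_loglik <- function(series, params, m0 = NULL, C0 = 1) {
  attr(kalman_filter(series, params, m0 = m0, C0 = C0), "loglik")
}

#' Fit the dynamic linear model by MCMC
#'
#' Gibbs sampler alternating (a) the (level, AR) state path by
#' forward-filtering backward-sampling, (b) a conjugate joint draw of the
#' batch step innovations, (c) inverse-gamma updates of the four variances,
#' (d) a random-walk Metropolis update of the AR coefficient on its uniform
#' support, and (e) imputation of missing observations from their
#' conditional normal (missingness assumed non-informative). With no batch
#' changes in the series, the posterior of `W_b` is its prior.
#'
#' @param series Data frame with `day`, `log_value` (NA = missing),
#'   `batch_id`; at least 10 non-missing observations.
#' @param priors A [dlm_priors()].
#' @param n_iter,n_burn,thin MCMC controls (defaults 4000 / 1000 / 2).
#' @param seed Integer seed; identical seed, data and priors reproduce the
#'   draw sequence exactly.
#' @param fixed Optional named list fixing parameters (any of `V`, `W_mu`,
#'   `W_s`, `W_b`, `phi`), e.g. `list(phi = 0)`; fixed parameters are not
#'   sampled.
#' @param phi_prop_sd Metropolis proposal SD for `phi` (default 0.05).
#' @param store_states Keep thinned draws of the (level + AR) path?
#' @return Object of class `dlm_fit`: `draws` (data frame of parameter
#'   draws), `params` (posterior means as [dlm_params()]), `states`
#'   (matrix of state-path draws or NULL), `imputed`, `missing_days`,
#'   `phi_accept_rate`, `mcmc` (the configuration).
#' @export
fit_dlm <- function(series, priors = dlm_priors(), n_iter = 4000L,
                    n_burn = 1000L, thin = 2L, seed = 1L, fixed = list(),
                    phi_prop_sd = 0.05, store_states = FALSE) {
  stopifnot(inherits(priors, "dlm_priors"), n_iter > n_burn, thin >= 1)
  sf <- as_series_frame(series)
  y <- sf$log_value
  if (any(!is.finite(y) & !is.na(y)))
    stop("non-finite observations in series", call. = FALSE)
  if (sum(!is.na(y)) < 10)
    stop("need at least 10 non-missing observations", call. = FALSE)

  m0 <- priors$m0
  if (is.null(m0)) m0 <- y[!is.na(y)][1]
  fx <- rep(NA_real_, 5)
  names(fx) <- c("V", "W_mu", "W_s", "W_b", "phi")
  for (nm in names(fixed)) {
    if (!nm %in% names(fx)) stop("unknown fixed parameter: ", nm, call. = FALSE)
    fx[nm] <- fixed[[nm]]
  }

  set.seed(seed)
  res <- dlm_gibbs_cpp(ifelse(is.na(y), NA_real_, y),
                       as.integer(sf$batch_id),
                       priors$shape, priors$scale,
                       priors$phi_lo, priors$phi_hi,
                       unname(fx), m0, priors$C0,
                       as.integer(n_iter), as.integer(n_burn),
                       as.integer(thin), phi_prop_sd, store_states)
  draws <- as.data.frame(res$draws)
  names(draws) <- c("V", "W_mu", "W_s", "W_b", "phi")
  pm <- colMeans(draws)
  structure(list(
    draws = draws,
    params = dlm_params(V = pm[["V"]], W_mu = pm[["W_mu"]],
                        W_s = pm[["W_s"]], W_b = pm[["W_b"]],
                        phi = pm[["phi"]]),
    states = if (store_states) res$states else NULL,
    imputed = res$imputed,
    missing_days = sf$day[res$missing_days],
    phi_accept_rate = res$phi_accept_rate,
    mcmc = list(n_iter = n_iter, n_burn = n_burn, thin = thin, seed = seed),
    m0 = m0, priors = priors),
    class = "dlm_fit")
}

#' @export
print.dlm_fit <- function(x, ...) {
  cat("DLM fit (", nrow(x$draws), " kept draws; phi acceptance ",
      sprintf("%.2f", x$phi_accept_rate), ")\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Causally filter every series of a cohort
#'
#' Applies [kalman_filter()] to each (patient, marker) series with
#' per-marker (or shared) posterior-mean parameters, returning one long
#' data frame aligned to the observation grid.
#'
#' @param cohort An `exalert_cohort` (or its long `series` data frame).
#' @param params A single [dlm_params()] applied to every series, or a named
#'   list of `dlm_params` keyed by marker name.
#' @param component Passed to [kalman_filter()]; `"fluct"` yields
#'   personalised-baseline-corrected values.
#' @return Long data frame `(patient_id, day, marker, filtered_value,
#'   filtered_sd, observed)`.
#' @export
filter_cohort <- function(cohort, params,
                          component = c("level_fluct", "fluct", "level",
                                        "all")) {
  component <- match.arg(component)
  series <- if (inherits(cohort, "exalert_cohort")) cohort$series else cohort
  stopifnot(is.data.frame(series),
            all(c("patient_id", "day", "marker", "log_value", "batch_id")
                %in% names(series)))
  get_params <- function(mk) {
    if (inherits(params, "dlm_params")) return(params)
    p <- params[[mk]]
    if (is.null(p)) stop("no parameters supplied for marker '", mk, "'",
                         call. = FALSE)
    p
  }
  out <- list()
  for (pid in unique(series$patient_id)) {
    for (mk in unique(series$marker)) {
      ss <- series[series$patient_id == pid & series$marker == mk, ]
      if (!nrow(ss)) next
      fs <- kalman_filter(ss, get_params(mk), component = component)
      out[[length(out) + 1L]] <- cbind(patient_id = pid, marker = mk,
                                       as.data.frame(fs))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("patient_id", "day", "marker", "filtered_value", "filtered_sd",
        "observed")]
}
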