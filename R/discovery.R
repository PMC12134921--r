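#' Screen biomarkers on paired stable/exacerbation samples
#'
#' For each marker: a two-sided paired t-test on log10 concentrations and
#' the ROC AUC of exacerbation versus stable values. A marker is selected
#' when (AUC >= 0.59 or AUC <= 0.41) and p < 0.05.
#'
#' Markers with all-missing values are skipped with a warning; zero-variance
#' paired differences are reported with p = 1 and a warning (and are never
#' selected).
#'
#' @param pairs A `paired_samples` data frame (see
#'   [generate_paired_samples()]): columns `patient_id`, `state`, then one
#'   column per marker with linear-scale concentrations.
#' @param auc_hi,auc_lo,alpha Selection rule constants (defaults 0.59, 0.41,
#'   0.05).
#' @return Data frame of class `screen_result`: `marker`, `auc`, `p_value`,
#'   `mean_log_diff`, `selected`.
#' @export
screen_biomarkers <- function(pairs, auc_hi = 0.59, auc_lo = 0.41,
                              alpha = 0.05) {
  stopifnot(is.data.frame(pairs), all(c("patient_id", "state") %in%
                                        names(pairs)))
  mks <- setdiff(names(pairs), c("patient_id", "state"))
  st <- pairs[pairs$state == "stable", ]
  ex <- pairs[pairs$state == "exacerbation", ]
  ex <- ex[match(st$patient_id, ex$patient_id), ]
  if (anyNA(ex$patient_id)) stop("unpaired patients in input", call. = FALSE)

  rows <- lapply(mks, function(mk) {
    xs <- log10(st[[mk]])
    xe <- log10(ex[[mk]])
    ok <- is.finite(xs) & is.finite(xe)
    if (!any(ok)) {
      warning("marker '", mk, "' has no complete pairs; skipped")
      return(NULL)
    }
    if (sum(ok) < 2) {
      warning("marker '", mk, "' has < 2 complete pairs; skipped")
      return(NULL)
    }
    xs <- xs[ok]
    xe <- xe[ok]
    d <- xe - xs
    p <- if (sd(d) == 0) NULL else
      tryCatch(t.test(xe, xs, paired = TRUE)$p.value,
               error = function(e) NULL)  # "essentially constant" d
    if (is.null(p)) {
      warning("marker '", mk, "' has zero-variance differences; p set to 1")
      p <- 1
    }
    auc <- auc_rank(c(xs, xe), c(rep(FALSE, length(xs)), rep(TRUE, length(xe))))
    data.frame(marker = mk, auc = auc, p_value = p, mean_log_diff = mean(d),
               selected = (auc >= auc_hi || auc <= auc_lo) && p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Fit the biomarker panel by backward stepwise logistic regression
#'
#' Starts from all candidate markers (log10 concentrations) in a logistic
#' regression of exacerbation state, then repeatedly refits and drops the
#' covariate with the largest Wald p-value above `alpha`, stopping when all
#' retained covariates have p <= `alpha` or one covariate remains. Ties
#' between equally insignificant covariates are broken by dropping the
#' lexicographically later marker name, so the elimination path is
#' deterministic and invariant to candidate order.
#'
#' @param data Data frame with a `state` column (`"stable"`/
#'   `"exacerbation"`) and one column per marker (linear concentrations).
#' @param candidates Character vector of marker columns to start from
#'   (>= 2).
#' @param alpha Retention threshold on Wald p-values (default 0.05).
#' @return Object of class `panel_model`: `intercept`, `coefficients`
#'   (named, log10 scale), `retained_markers`, `path` (data frame of drops).
#' @export
fit_panel <- function(data, candidates, alpha = 0.05) {
  stopifnot(is.data.frame(data), "state" %in% names(data),
            length(candidates) >= 2, all(candidates %in% names(data)))
  y <- data$state == "exacerbation"
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  X <- as.data.frame(lapply(data[candidates], log10))
  names(X) <- candidates

  retained <- sort(candidates)
  path <- list()
  repeat {
    df <- cbind(y = y, X[retained])
    fit <- withCallingHandlers(
      glm(y ~ ., data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          stop("perfect separation detected; refusing to return unstable ",
               "coefficients", call. = FALSE)
        invokeRestart("muffleWarning")
      })
    if (any(abs(coef(fit)[-1]) > 50) ||
        any(fitted(fit) < 1e-10 | fitted(fit) > 1 - 1e-10))
      stop("perfect separation detected; refusing to return unstable ",
           "coefficients", call. = FALSE)
    sm <- summary(fit)$coefficients
    pv <- sm[match(make.names(retained), rownames(sm)), 4]
    names(pv) <- retained
    pv[is.na(pv)] <- 1  # aliased/collinear covariates are dropped first
    if (all(pv <= alpha) || length(retained) == 1) {
      return(structure(list(
        intercept = unname(coef(fit)[1]),
        coefficients = setNames(unname(coef(fit)[-1]), retained),
        retained_markers = retained,
        path = if (length(path)) do.call(rbind, path) else
          data.frame(dropped = character(0), p_value = numeric(0)),
        alpha = alpha), class = "panel_model"))
    }
    worst <- max(pv)
    cand_drop <- names(pv)[pv == worst]
    drop_mk <- sort(cand_drop, decreasing = TRUE)[1]  # lexicographically later
    path[[length(path) + 1L]] <- data.frame(dropped = drop_mk,
                                            p_value = worst,
                                            stringsAsFactors = FALSE)
    retained <- setdiff(retained, drop_mk)
  }
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Logistic biomarker panel:", length(x$retained_markers),
      "markers retained\n")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Panel probability score for a sample
#'
#' Inverse-logit of the panel's linear predictor on log10 concentrations.
#'
#' @param model A [fit_panel()] result.
#' @param sample Named numeric vector (or one-row data frame) of linear
#'   concentrations covering all retained markers.
#' @return Probability in (0, 1).
#' @export
panel_score <- function(model, sample) {
  stopifnot(inherits(model, "panel_model"))
  if (is.data.frame(sample)) sample <- unlist(sample[1, , drop = TRUE])
  missing_mk <- setdiff(model$retained_markers, names(sample))
  if (length(missing_mk))
    stop("sample lacks retained marker(s): ",
         paste(missing_mk, collapse = ", "), call. = FALSE)
  eta <- model$intercept +
    sum(model$coefficients * log10(sample[model$retained_markers]))
  plogis(eta)
}

#' Prevalence-adjusted predictive values
#'
#' PPV and NPV at an assumed prevalence from a test's sensitivity and
#' specificity:
#' PPV = 100 se pi / (se pi + (1 - sp)(1 - pi)),
#' NPV = 100 sp (1 - pi) / (sp (1 - pi) + (1 - se) pi).
#'
#' @param sensitivity,specificity In percent (0-100).
#' @param prevalence Proportion in (0, 1).
#' @return Named list `ppv`, `npv` in percent (unrounded).
#' @export
prevalence_adjusted_pv <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100,
            prevalence >= 0, prevalence <= 1)
  se <- sensitivity / 100
  sp <- specificity / 100
  pi_ <- prevalence
  dp <- se * pi_ + (1 - sp) * (1 - pi_)
  dn <- sp * (1 - pi_) + (1 - se) * pi_
  if (dp == 0 || dn == 0)
    stop("predictive value undefined (zero denominator)", call. = FALSE)
  list(ppv = 100 * se * pi_ / dp, npv = 100 * sp * (1 - pi_) / dn)
}

#' Confusion summary of panel scores at a probability cutoff
#'
#' @param scores Probability scores.
#' @param labels Logical, `TRUE` = exacerbation.
#' @param cutoff Probability cutoff (default 0.39, the panel's reported
#'   operating point); a score >= cutoff calls exacerbation.
#' @return Named list `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`
#'   (percent), `cutoff`.
#' @export
confusion_summary <- function(scores, labels, cutoff = 0.39) {
  labels <- as.logical(labels)
  call_pos <- scores >= cutoff
  tp <- sum(call_pos & labels)
  fp <- sum(call_pos & !labels)
  fn <- sum(!call_pos & labels)
  tn <- sum(!call_pos & !labels)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       cutoff = cutoff)
}
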