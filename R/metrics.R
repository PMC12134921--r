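#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a randomly chosen positive scores higher than
#' a randomly chosen negative, with ties counted one half — computed from
#' midranks. The optional confidence interval is a seeded stratified
#' bootstrap (positives and negatives resampled separately).
#'
#' @param scores Numeric scores; higher means more positive.
#' @param labels Logical/0-1 vector, `TRUE` = positive class.
#' @param ci Compute a bootstrap confidence interval?
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return Object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, and a `cutoffs` data frame with per-cutoff
#'   sensitivity and specificity (positive call: `score > cutoff`).
#' @export
roc_auc <- function(scores, labels, ci = TRUE, conf_level = 0.95,
                    n_boot = 2000L, seed = 1L) {
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)

  auc <- auc_rank(scores, labels)

  thr <- sort(unique(scores))
  # positive call if score > cutoff; add a cutoff below all scores
  cut_grid <- c(min(scores) - 1, thr)
  sens <- vapply(cut_grid, function(ct) sum(scores > ct & labels) / n_pos,
                 numeric(1))
  spec <- vapply(cut_grid, function(ct) sum(scores <= ct & !labels) / n_neg,
                 numeric(1))
  cutoffs <- data.frame(cutoff = cut_grid, sensitivity = sens,
                        specificity = spec)

  ci_low <- ci_high <- NA_real_
  if (isTRUE(ci)) {
    set.seed(seed)
    pos <- scores[labels]
    neg <- scores[!labels]
    boots <- vapply(seq_len(n_boot), function(b) {
      sp <- sample(pos, n_pos, replace = TRUE)
      sn <- sample(neg, n_neg, replace = TRUE)
      auc_rank(c(sp, sn), c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    ci_low <- qs[1]
    ci_high <- qs[2]
  }
  structure(list(auc = auc, ci_low = ci_low, ci_high = ci_high,
                 n_pos = n_pos, n_neg = n_neg, cutoffs = cutoffs),
            class = "roc_result")
}

auc_rank <- function(scores, labels) {
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  r <- rank(scores)  # midranks: ties count one half
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f", x$auc))
  if (is.finite(x$ci_low))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high))
  cat(sprintf(" [%d positives, %d negatives]\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Cutoff maximising Youden's J
#'
#' Returns the cutoff from a [roc_auc()] result maximising
#' sensitivity + specificity - 1; ties resolved to the lower cutoff.
#'
#' @param roc A `roc_result`.
#' @return Named list `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  tab <- roc$cutoffs
  j <- tab$sensitivity + tab$specificity - 1
  best <- which(j == max(j))
  best <- best[which.min(tab$cutoff[best])]
  list(cutoff = tab$cutoff[best], j = j[best],
       sensitivity = tab$sensitivity[best],
       specificity = tab$specificity[best])
}

#' Two-sided paired t-test on log concentrations
#'
#' Thin wrapper around [stats::t.test()] with explicit conventions for
#' degenerate differences: identical vectors give `t = 0`, `p = 1`;
#' zero-variance nonzero differences give `t = +/-Inf`, `p = 0` (the limit),
#' each with a warning.
#'
#' @param x_stable,x_exac Equal-length numeric vectors (paired by position).
#' @return Named list `t`, `p`, `df`, `mean_diff` (exacerbation - stable).
#' @export
paired_t_test <- function(x_stable, x_exac) {
  stopifnot(length(x_stable) == length(x_exac), length(x_stable) >= 2)
  d <- x_exac - x_stable
  degenerate <- function() {
    if (mean(d) == 0) {
      warning("zero-variance, zero-mean differences: t = 0, p = 1")
      list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0)
    } else {
      warning("zero-variance differences: |t| = Inf, p = 0 (limit)")
      list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
           mean_diff = mean(d))
    }
  }
  if (sd(d) == 0) return(degenerate())
  # t.test itself rejects essentially-constant differences (floating-point
  # remnants of an exactly constant shift); apply the same convention
  tt <- tryCatch(t.test(x_exac, x_stable, paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) return(degenerate())
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' Daily-testing compliance summary
#'
#' Percentage of expected tests done, and of done tests that were valid
#' (e.g. showed a positive control line).
#'
#' @param n_expected,n_done,n_valid Counts with
#'   `n_valid <= n_done <= n_expected`.
#' @param digits_done,digits_valid Rounding (defaults: one decimal for
#'   \% done, integer for \% valid-of-done, matching common reporting).
#' @return Named list `pct_done`, `pct_valid_of_done`.
#' @export
compliance_summary <- function(n_expected, n_done, n_valid,
                               digits_done = 1, digits_valid = 0) {
  if (!(n_valid <= n_done && n_done <= n_expected))
    stop("require n_valid <= n_done <= n_expected", call. = FALSE)
  pct_done <- round(100 * n_done / n_expected, digits_done)
  if (n_done == 0) {
    warning("no tests done: % valid-of-done undefined, reported as 0")
    pct_valid <- 0
  } else {
    pct_valid <- round(100 * n_valid / n_done, digits_valid)
  }
  list(pct_done = pct_done, pct_valid_of_done = pct_valid)
}
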