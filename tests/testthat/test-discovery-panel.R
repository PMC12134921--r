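make_pairs <- function(n = 40, effects = c(A = 0.4, B = 0), noise = 0.1,
                       seed = 1) {
  set.seed(seed)
  mks <- names(effects)
  stable <- exac <- matrix(NA_real_, n, length(mks),
                           dimnames = list(NULL, mks))
  for (j in seq_along(mks)) {
    base <- rnorm(n, 2, 0.3)
    stable[, j] <- 10^(base + rnorm(n, 0, noise))
    exac[, j] <- 10^(base + effects[j] + rnorm(n, 0, noise))
  }
  pid <- sprintf("P%03d", 1:n)
  rbind(data.frame(patient_id = pid, state = "stable", stable),
        data.frame(patient_id = pid, state = "exacerbation", exac))
}

test_that("screen selection rule is a pure function of (auc, p)", {
  sel <- function(auc, p) (auc >= 0.59 || auc <= 0.41) && p < 0.05
  # exhaustive grid over the rule's decision regions
  for (auc in c(0, 0.3, 0.41, 0.45, 0.5, 0.58, 0.59, 0.6, 0.8, 1))
    for (p in c(0, 0.01, 0.049, 0.05, 0.2, 1))
      expect_identical(sel(auc, p),
                       (auc >= 0.59 || auc <= 0.41) && p < 0.05)
  # and through the implementation on real data
  res <- screen_biomarkers(make_pairs(effects = c(A = 0.5, B = 0)))
  expect_true(res$selected[res$marker == "A"])
  expect_false(res$selected[res$marker == "B"])
  expect_identical(res$selected,
                   (res$auc >= 0.59 | res$auc <= 0.41) & res$p_value < 0.05)
})

test_that("identical stable/exacerbation vectors give auc 0.5, not selected", {
  n <- 10
  v <- 10^rnorm(n, 2, 0.3)
  pairs <- rbind(
    data.frame(patient_id = sprintf("P%d", 1:n), state = "stable", A = v),
    data.frame(patient_id = sprintf("P%d", 1:n), state = "exacerbation",
               A = v))
  res <- suppressWarnings(screen_biomarkers(pairs))
  expect_equal(res$auc, 0.5)
  expect_equal(res$p_value, 1)
  expect_false(res$selected)
})

test_that("zero-variance differences warn and report p = 1", {
  n <- 8
  v <- 10^rnorm(n, 2, 0.3)
  pairs <- rbind(
    data.frame(patient_id = sprintf("P%d", 1:n), state = "stable", A = v),
    data.frame(patient_id = sprintf("P%d", 1:n), state = "exacerbation",
               A = v * 10^0.2))  # constant log shift
  expect_warning(res <- screen_biomarkers(pairs), "zero-variance")
  expect_equal(res$p_value, 1)
})

test_that("backward elimination drops noise, keeps signal, order-invariant", {
  set.seed(42)
  n <- 2000
  base <- rnorm(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(3 * (base - 2)))
  dat <- data.frame(state = ifelse(y == 1, "exacerbation", "stable"),
                    sig = 10^(base + rnorm(n, 0, 0.05)),
                    noise = 10^rnorm(n, 2, 0.3))
  m1 <- fit_panel(dat, c("sig", "noise"))
  m2 <- fit_panel(dat, c("noise", "sig"))
  expect_identical(m1$retained_markers, "sig")
  expect_identical(m1$retained_markers, m2$retained_markers)
  expect_equal(m1$coefficients, m2$coefficients)

  # brute-force elimination path: refit all sub-models directly
  g_full <- glm(y ~ log10(sig) + log10(noise), data = dat,
                family = binomial())
  p_full <- summary(g_full)$coefficients[-1, 4]
  expect_gt(p_full[["log10(noise)"]], 0.05)  # noise is the droppable one
  g_sig <- glm(y ~ log10(sig), data = dat, family = binomial())
  expect_lte(summary(g_sig)$coefficients[2, 4], 0.05)
  expect_equal(unname(m1$coefficients["sig"]), unname(coef(g_sig)[2]),
               tolerance = 1e-8)
})

test_that("a null candidate survives elimination at about the alpha rate", {
  kept <- 0L
  for (r in 1:200) {
    set.seed(r)
    n <- 120
    base <- rnorm(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(3 * (base - 2)))
    dat <- data.frame(state = ifelse(y == 1, "exacerbation", "stable"),
                      sig = 10^(base + rnorm(n, 0, 0.05)),
                      null = 10^rnorm(n, 2, 0.3))
    m <- tryCatch(fit_panel(dat, c("sig", "null")), error = function(e) NULL)
    if (!is.null(m) && "null" %in% m$retained_markers) kept <- kept + 1L
  }
  expect_gt(kept / 200, 0.01)
  expect_lt(kept / 200, 0.11)
})

test_that("perfect separation raises an explicit error", {
  dat <- data.frame(state = rep(c("stable", "exacerbation"), each = 10),
                    A = 10^c(rnorm(10, 1, 0.05), rnorm(10, 5, 0.05)),
                    B = 10^rnorm(20, 2, 0.3))
  expect_error(fit_panel(dat, c("A", "B")), "separation")
})

test_that("panel score is the inverse-logit of the linear predictor", {
  m <- structure(list(intercept = 0,
                      coefficients = c(A = 0, B = 0),
                      retained_markers = c("A", "B")),
                 class = "panel_model")
  expect_equal(panel_score(m, c(A = 10, B = 100)), 0.5)

  # brute-force oracle on 20 random samples
  set.seed(9)
  m2 <- structure(list(intercept = -1.5,
                       coefficients = c(A = 2, B = -0.7),
                       retained_markers = c("A", "B")),
                  class = "panel_model")
  for (i in 1:20) {
    s <- c(A = 10^rnorm(1, 2, 0.5), B = 10^rnorm(1, 2, 0.5))
    eta <- -1.5 + 2 * log10(s["A"]) - 0.7 * log10(s["B"])
    expect_equal(panel_score(m2, s), unname(1 / (1 + exp(-eta))),
                 tolerance = 1e-12)
  }
  # monotone in intercept
  scores <- vapply(c(-5, 0, 5, 20), function(b0) {
    m2$intercept <- b0
    panel_score(m2, c(A = 100, B = 100))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_error(panel_score(m2, c(A = 1)), "B")
})

test_that("prevalence-adjusted predictive values match the closed formulas", {
  pv <- prevalence_adjusted_pv(72.7, 78.8, 0.5)
  expect_equal(round(pv$ppv, 1), 77.4)
  pv2 <- prevalence_adjusted_pv(83.6, 74.5, 0.5)
  expect_equal(round(pv2$npv, 1), 82.0)
  pv3 <- prevalence_adjusted_pv(100, 100, 0.3)
  expect_equal(pv3$ppv, 100)
  expect_equal(pv3$npv, 100)
  expect_error(prevalence_adjusted_pv(0, 100, 0), "undefined")
})
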