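# Build a feature_db directly from a feature matrix (bypasses the rolling
# windows: the selection/training machinery only needs the frame layout).
db_from_matrix <- function(X, tte, patient_id) {
  dev <- cbind(data.frame(patient_id = patient_id,
                          anchor_day = seq_along(tte), tte = tte),
               as.data.frame(X))
  structure(list(development = dev, production = dev[0, ],
                 manifest = list(markers = colnames(X))),
            class = "feature_db")
}

make_planted_db <- function(n = 240, p = 8, seed = 1, noise_sd = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("M", seq_len(p), ".value.1")))
  tte <- pmin(pmax(100 + 40 * X[, 3] + rnorm(n, 0, noise_sd), 0), 200)
  pid <- sprintf("P%03d", rep(seq_len(12), length.out = n))
  db_from_matrix(X, tte, pid)
}

test_that("stepwise selection finds a planted noiseless signal at step 1", {
  db <- make_planted_db(seed = 3)
  cfg <- ann_config(max_steps = 1, n_mc_splits = 1, size = 2, maxit = 200,
                    seed = 11)
  tr <- stepwise_select(db, cfg)
  expect_identical(tr$selected_inputs, "M3.value.1")
  expect_identical(nrow(tr$steps), 1L)
  # greedy optimality: the recorded choice has the lowest recorded test MSE
  expect_identical(tr$steps$chosen[1], "M3.value.1")
})

test_that("selection trace is fully reproducible with a fixed seed", {
  db <- make_planted_db(seed = 5, noise_sd = 20)
  cfg <- ann_config(max_steps = 2, n_mc_splits = 1, size = 2, maxit = 80,
                    seed = 4)
  t1 <- stepwise_select(db, cfg)
  t2 <- stepwise_select(db, cfg)
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$selected_inputs, t2$selected_inputs)
})

test_that("pure-noise features do not yield spuriously high test r-squared", {
  set.seed(8)
  r2 <- numeric(20)
  for (r in 1:20) {
    n <- 150
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("N", 1:4, ".value.1")))
    tte <- sample(c(rep(200, n / 2), runif(n / 2, 0, 200)))
    pid <- sprintf("P%03d", rep(1:10, length.out = n))
    db <- db_from_matrix(X, tte, pid)
    cfg <- ann_config(max_steps = 1, n_mc_splits = 1, size = 2, maxit = 60,
                      seed = 100 + r)
    tr <- tryCatch(stepwise_select(db, cfg), error = function(e) NULL)
    if (is.null(tr)) { r2[r] <- 0; next }
    m <- train_final(db, tr$selected_inputs,
                     ann_config(hidden_nodes_grid = 2, n_mc_splits = 1,
                                maxit = 60, seed = 100 + r))
    te <- m$split == "test"
    pred <- predict_risk(m, db$development[te, ])
    r2[r] <- if (sd(pred) == 0) 0 else
      cor(pred, pmin(db$development$tte[te], 200))^2
  }
  # held-out r2 on pure noise stays near zero on average
  expect_lt(mean(r2), 0.15)
})

test_that("degenerate targets are rejected", {
  db <- make_planted_db()
  db$development$tte <- 200
  expect_error(stepwise_select(db, ann_config()), "degenerate")
})

test_that("final training recovers a constant target and a linear signal", {
  # constant target: predictions within 1 of 200
  set.seed(2)
  X <- matrix(rnorm(300), 100, 3,
              dimnames = list(NULL, paste0("M", 1:3, ".value.1")))
  db <- db_from_matrix(X, rep(200, 100), sprintf("P%03d", rep(1:10, 10)))
  m <- train_final(db, "M1.value.1",
                   ann_config(hidden_nodes_grid = 2, n_mc_splits = 1,
                              maxit = 200, seed = 3))
  expect_true(all(abs(predict_risk(m, db$development) - 200) < 1))

  # planted linear signal, zero noise: held-out r2 >= 0.95
  db2 <- make_planted_db(seed = 6)
  m2 <- train_final(db2, "M3.value.1",
                    ann_config(hidden_nodes_grid = c(2, 4), n_mc_splits = 2,
                               maxit = 300, seed = 5))
  te <- m2$split == "test"
  pred <- predict_risk(m2, db2$development[te, ])
  expect_gte(cor(pred, pmin(db2$development$tte[te], 200))^2, 0.95)

  # degenerate grid: a single size is fit and reported
  m3 <- train_final(db2, "M3.value.1",
                    ann_config(hidden_nodes_grid = 3, n_mc_splits = 1,
                               maxit = 50, seed = 9))
  expect_identical(m3$hidden, 3L)
  expect_length(m3$performance, 1)
})

test_that("standardisation constants come from the training split only", {
  db <- make_planted_db(seed = 10, noise_sd = 10)
  cfg <- ann_config(hidden_nodes_grid = 2, n_mc_splits = 1, maxit = 50,
                    seed = 2)
  m1 <- train_final(db, "M3.value.1", cfg)
  # perturb only non-training rows: constants must not move
  db2 <- db
  not_tr <- m1$split != "train"
  db2$development[not_tr, "M3.value.1"] <-
    db2$development[not_tr, "M3.value.1"] + 100
  m2 <- train_final(db2, "M3.value.1", cfg)
  expect_identical(m1$center, m2$center)
  expect_identical(m1$scale, m2$scale)
})

test_that("forward pass matches hand-computed matrix algebra", {
  set.seed(14)
  p <- 3
  h <- 4
  model <- structure(list(
    inputs = c("a", "b", "c"),
    center = setNames(rnorm(p), c("a", "b", "c")),
    scale = setNames(runif(p, 0.5, 2), c("a", "b", "c")),
    W1 = matrix(rnorm(h * p), h, p), b1 = rnorm(h),
    w2 = rnorm(h), b2 = rnorm(1), w_skip = rnorm(p),
    hidden = h, horizon = 200), class = "ann_model")
  for (i in 1:10) {
    x <- setNames(rnorm(p), c("a", "b", "c"))
    z <- (x - model$center) / model$scale
    hid <- 1 / (1 + exp(-(model$W1 %*% z + model$b1)))
    expected <- model$b2 + sum(model$w2 * hid) + sum(model$w_skip * z)
    expect_equal(predict_risk(model, x), as.numeric(expected),
                 tolerance = 1e-10)
  }
  # all-zero weights: score = output bias
  model0 <- model
  model0$W1[] <- 0
  model0$b1[] <- 0
  model0$w2[] <- 0
  model0$w_skip[] <- 0
  model0$b2 <- 57.5
  expect_equal(predict_risk(model0, c(a = 1, b = 2, c = 3)), 57.5)
  expect_error(predict_risk(model, c(a = 1, b = 2)), "c")
})

test_that("rendered formula and JSON round trip reproduce predictions", {
  db <- make_planted_db(seed = 20, noise_sd = 15)
  m <- train_final(db, c("M3.value.1", "M1.value.1"),
                   ann_config(hidden_nodes_grid = 2, n_mc_splits = 1,
                              maxit = 60, seed = 6))
  expr <- parse(text = render_formula(m))
  set.seed(30)
  for (i in 1:100) {
    env <- list2env(list(M3.value.1 = rnorm(1), M1.value.1 = rnorm(1)))
    direct <- predict_risk(m, c(M3.value.1 = get("M3.value.1", env),
                                M1.value.1 = get("M1.value.1", env)))
    expect_equal(eval(expr, env), direct, tolerance = 1e-9)
  }
  path <- tempfile(fileext = ".json")
  write_ann_json(m, path)
  m2 <- read_ann_json(path)
  X <- db$development[1:25, ]
  expect_equal(predict_risk(m2, X), predict_risk(m, X), tolerance = 1e-12)
})

test_that("per-split r-squared follows the Pearson conventions", {
  x <- c(3, 8, 1, 9, 4, 7)
  expect_equal(unname(evaluate_regression(x, x)), 1)
  expect_equal(unname(evaluate_regression(-x, x)), 1)  # squared correlation
  set.seed(44)
  a <- rnorm(1000)
  b <- rnorm(1000)
  expect_lt(unname(evaluate_regression(a, b)), 0.01)
  expect_warning(r0 <- evaluate_regression(rep(1, 5), rnorm(5)),
                 "zero-variance")
  expect_equal(unname(r0), 0)
  expect_error(evaluate_regression(1:2, 1:2), "3 points")
})
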