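#' Configuration for stepwise neural-network risk modelling
#'
#' @param max_steps Maximum number of forward-selection steps (default 20).
#' @param split_ratios Train/validation/test proportions (default 60:20:20).
#' @param n_mc_splits Number of Monte Carlo cross-validation splits.
#' @param hidden_nodes_grid Hidden-layer sizes tried when tuning the final
#'   model (default 2..10).
#' @param size Hidden nodes used during stepwise selection (default 2).
#' @param maxit Optimiser iterations per incremental (warm-started) fit;
#'   cold fits get a larger budget internally.
#' @param decay Weight-decay regularisation (default 1e-3 on standardised
#'   inputs and a unit-scaled target).
#' @param horizon Cap on the time-to-exacerbation target (default 200 days).
#' @param seed Root seed; split and weight-initialisation seeds derive from
#'   it.
#' @return Object of class `ann_config`.
#' @export
ann_config <- function(max_steps = 20L, split_ratios = c(0.6, 0.2, 0.2),
                       n_mc_splits = 5L, hidden_nodes_grid = 2:10,
                       size = 2L, maxit = 60L, decay = 1e-3,
                       horizon = 200, seed = 1L) {
  stopifnot(max_steps >= 1, length(split_ratios) == 3,
            abs(sum(split_ratios) - 1) < 1e-8, all(split_ratios > 0),
            n_mc_splits >= 1, all(hidden_nodes_grid >= 1))
  structure(list(max_steps = as.integer(max_steps),
                 split_ratios = split_ratios,
                 n_mc_splits = as.integer(n_mc_splits),
                 hidden_nodes_grid = as.integer(hidden_nodes_grid),
                 size = as.integer(size), maxit = as.integer(maxit),
                 decay = decay, horizon = horizon, seed = as.integer(seed)),
            class = "ann_config")
}

# Patient-stratified 60:20:20 split: all windows of a patient land in one
# partition, preventing leakage of a patient's profile across partitions.
mc_split <- function(patient_ids, ratios, seed) {
  pats <- sort(unique(patient_ids))
  set.seed(seed)
  pats <- sample(pats)
  n <- length(pats)
  n_tr <- max(1L, round(ratios[1] * n))
  n_va <- max(1L, round(ratios[2] * n))
  if (n_tr + n_va >= n) {
    n_tr <- max(1L, n - 2L)
    n_va <- 1L
  }
  grp <- rep("test", n)
  grp[seq_len(n_tr)] <- "train"
  grp[n_tr + seq_len(n_va)] <- "validation"
  setNames(grp, pats)[as.character(patient_ids)]
}

# standardisation constants from the training rows only (no leakage)
train_standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

# one network fit on standardised inputs; target scaled to [0,1] internally;
# Wts warm-starts from a previous fit when supplied
fit_net <- function(Xs, y, size, config, seed = NULL, maxit = config$maxit,
                    Wts = NULL) {
  if (!is.null(seed)) set.seed(seed)
  args <- list(x = Xs, y = y / config$horizon, size = size, linout = TRUE,
               skip = TRUE, decay = config$decay, maxit = maxit,
               trace = FALSE)
  if (!is.null(Wts)) args$Wts <- Wts
  do.call(nnet::nnet, args)
}

net_mse <- function(net, Xs, y, horizon) {
  pred <- as.numeric(predict(net, Xs)) * horizon
  mean((pred - y)^2)
}

# Grow an nnet weight vector from p to p + 1 inputs (skip-layer layout):
# each hidden unit and the skip layer gain one connection, initialised with
# the supplied small perturbations `eps` (length size + 1).
expand_wts <- function(wts, p, size, eps) {
  out <- numeric(0)
  idx <- 1L
  for (j in seq_len(size)) {
    out <- c(out, wts[idx:(idx + p)], eps[j])
    idx <- idx + p + 1L
  }
  c(out, wts[idx:(idx + size)],
    if (p > 0) wts[(idx + size + 1):(idx + size + p)],
    eps[size + 1])
}

#' Forward stepwise selection of temporal-biomarker inputs
#'
#' At each step, every unused candidate feature is tried alongside the
#' current inputs: the step's network is warm-started from the previous
#' step's fitted weights (new connections initialised near zero), retrained
#' on the training partition, and scored on the unseen test partition,
#' averaged over `n_mc_splits` patient-stratified Monte Carlo 60:20:20
#' splits (validation-partition error is recorded alongside). The candidate
#' with the lowest mean test MSE is appended and the walk continues to
#' `max_steps`; the selected panel is the path prefix with the best mean
#' unseen-test error.
#'
#' @param db A [build_database()] result (development set is used).
#' @param config An [ann_config()].
#' @param candidates Optional subset of feature columns to search over.
#' @return Object of class `selection_trace`: `steps` (data frame: step,
#'   chosen, mean test/validation MSE), `selected_inputs` (best prefix),
#'   `best_step`, `per_split_best` (best candidate per split per step, for
#'   panel-stability tallies), `marker_tally`, `split_seeds`, and the
#'   per-split warm weights at the best prefix (used by [train_final()]).
#' @export
stepwise_select <- function(db, config = ann_config(), candidates = NULL) {
  stopifnot(inherits(db, "feature_db"), inherits(config, "ann_config"))
  dev <- db$development
  if (!nrow(dev)) stop("development set is empty", call. = FALSE)
  y <- pmin(dev$tte, config$horizon)
  if (length(unique(y)) < 2)
    stop("degenerate target: all time-to-exacerbation labels identical",
         call. = FALSE)
  feats <- feature_columns(db)
  if (!is.null(candidates)) {
    stopifnot(all(candidates %in% feats))
    feats <- candidates
  }
  X <- as.matrix(dev[feats])

  split_seeds <- config$seed + seq_len(config$n_mc_splits) * 131L
  splits <- lapply(split_seeds, function(s)
    mc_split(dev$patient_id, config$split_ratios, s))
  n_s <- length(splits)

  selected <- character(0)
  warm <- vector("list", n_s)          # current weights per split
  warm_path <- list()                  # per step: list of per-split weights
  steps <- list()
  per_split_best <- list()

  for (step in seq_len(config$max_steps)) {
    remaining <- setdiff(feats, selected)
    if (!length(remaining)) break
    test_mse <- matrix(NA_real_, length(remaining), n_s,
                       dimnames = list(remaining, NULL))
    val_mse <- test_mse
    cand_wts <- vector("list", n_s)
    for (si in seq_len(n_s)) {
      grp <- splits[[si]]
      tr <- grp == "train"
      va <- grp == "validation"
      te <- grp == "test"
      seed_si <- config$seed + 7919L * step + si
      set.seed(seed_si)
      eps <- rnorm(config$size + 1, 0, 0.05)
      cand_wts[[si]] <- list()
      for (cand in remaining) {
        cols <- c(selected, cand)
        std <- train_standardizer(X[tr, cols, drop = FALSE])
        Xs <- apply_standardizer(X[, cols, drop = FALSE], std)
        net <- if (is.null(warm[[si]]))
          fit_net(Xs[tr, , drop = FALSE], y[tr], config$size, config,
                  seed = seed_si, maxit = max(3L * config$maxit, 150L))
        else
          fit_net(Xs[tr, , drop = FALSE], y[tr], config$size, config,
                  maxit = config$maxit,
                  Wts = expand_wts(warm[[si]], length(selected),
                                   config$size, eps))
        val_mse[cand, si] <- net_mse(net, Xs[va, , drop = FALSE], y[va],
                                     config$horizon)
        test_mse[cand, si] <- net_mse(net, Xs[te, , drop = FALSE], y[te],
                                      config$horizon)
        cand_wts[[si]][[cand]] <- net$wts
      }
    }
    mean_test <- rowMeans(test_mse)
    chosen <- names(which.min(mean_test))
    per_split_best[[step]] <- rownames(test_mse)[apply(test_mse, 2,
                                                       which.min)]
    for (si in seq_len(n_s)) warm[[si]] <- cand_wts[[si]][[chosen]]
    warm_path[[step]] <- warm
    selected <- c(selected, chosen)
    steps[[step]] <- data.frame(step = step, chosen = chosen,
                                mean_test_mse = mean_test[chosen],
                                mean_val_mse = rowMeans(val_mse)[chosen],
                                stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL
  best_step <- which.min(steps$mean_test_mse)
  tally <- table(sub("\\..*$", "", unlist(per_split_best)))
  structure(list(steps = steps,
                 selected_inputs = steps$chosen[seq_len(best_step)],
                 best_step = best_step,
                 per_split_best = per_split_best,
                 marker_tally = tally,
                 split_seeds = split_seeds,
                 splits = splits,
                 warm_weights = warm_path[[best_step]],
                 config = config),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Stepwise input selection:", length(x$selected_inputs),
      "inputs (best of a", nrow(x$steps), "step path)\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Train the final risk network over a hidden-node grid
#'
#' For each hidden-layer size in the grid, trains a network per Monte Carlo
#' split on the training partition and scores the unseen test partition;
#' the size with the lowest mean test MSE wins. When a [stepwise_select()]
#' trace is supplied, fits at the selection's hidden size continue from the
#' warm path weights (the same incremental-training trajectory that scored
#' the panel); other sizes are fit cold with an enlarged iteration budget.
#' The returned model embeds the first split's training-partition
#' standardisation constants and, by default, is polished on the full
#' development set from the warm weights (the test partition never
#' influences selection or tuning).
#'
#' @param db A [build_database()] result.
#' @param inputs A `selection_trace`, or a character vector of feature
#'   names (cold training).
#' @param config An [ann_config()]; ignored in favour of the trace's config
#'   when a trace is supplied.
#' @param refit `"development"` (default) polishes the final weights on all
#'   development windows; `"train"` keeps the model trained on the first
#'   split's training partition only.
#' @return Object of class `ann_model`: `inputs`, `center`, `scale`, `W1`
#'   (hidden x p), `b1`, `w2`, `b2`, `w_skip`, `hidden`, `performance`
#'   (per-size mean test MSE), `split` (the canonical split).
#' @export
train_final <- function(db, inputs, config = ann_config(),
                        refit = c("development", "train")) {
  stopifnot(inherits(db, "feature_db"))
  refit <- match.arg(refit)
  trace <- NULL
  if (inherits(inputs, "selection_trace")) {
    trace <- inputs
    config <- trace$config
    inputs <- trace$selected_inputs
  }
  stopifnot(length(inputs) >= 1, all(inputs %in% feature_columns(db)))
  dev <- db$development
  y <- pmin(dev$tte, config$horizon)
  X <- as.matrix(dev[inputs])

  if (!is.null(trace)) {
    splits <- trace$splits
  } else {
    split_seeds <- config$seed + seq_len(config$n_mc_splits) * 131L
    splits <- lapply(split_seeds, function(s)
      mc_split(dev$patient_id, config$split_ratios, s))
  }
  cold_maxit <- max(5L * config$maxit, 300L)

  fit_one <- function(si, h) {
    grp <- splits[[si]]
    tr <- grp == "train"
    std <- train_standardizer(X[tr, , drop = FALSE])
    Xs <- apply_standardizer(X, std)
    warm_ok <- !is.null(trace) && h == config$size
    net <- if (warm_ok)
      fit_net(Xs[tr, , drop = FALSE], y[tr], h, config,
              maxit = 2L * config$maxit, Wts = trace$warm_weights[[si]])
    else
      fit_net(Xs[tr, , drop = FALSE], y[tr], h, config,
              seed = config$seed + 7717L * h + si, maxit = cold_maxit)
    if (!is.finite(net$value))
      stop("network training did not converge (non-finite loss)",
           call. = FALSE)
    list(net = net, std = std,
         mse = net_mse(net, Xs[grp == "test", , drop = FALSE],
                       y[grp == "test"], config$horizon))
  }

  grid <- config$hidden_nodes_grid
  perf <- setNames(numeric(length(grid)), grid)
  keep_first <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    fits <- lapply(seq_along(splits), function(si) fit_one(si, grid[gi]))
    perf[gi] <- mean(vapply(fits, `[[`, numeric(1), "mse"))
    keep_first[[gi]] <- fits[[1]]
  }
  best_gi <- which.min(perf)
  best_h <- grid[best_gi]
  final <- keep_first[[best_gi]]
  net <- final$net
  std <- final$std

  if (refit == "development") {
    Xs <- apply_standardizer(X, std)
    net <- fit_net(Xs, y, best_h, config, maxit = cold_maxit, Wts = net$wts)
    if (!is.finite(net$value))
      stop("network training did not converge (non-finite loss)",
           call. = FALSE)
  }

  model <- nnet_to_model(net, inputs, std, best_h, config$horizon)
  model$performance <- perf
  model$split <- splits[[1]]
  model
}

# unpack nnet's weight vector (skip-layer, linear output) and fold the
# target scaling into the output layer so predictions are in days
nnet_to_model <- function(net, inputs, std, hidden, horizon) {
  p <- length(inputs)
  wts <- net$wts
  W1 <- matrix(NA_real_, hidden, p)
  b1 <- numeric(hidden)
  idx <- 1L
  for (j in seq_len(hidden)) {
    b1[j] <- wts[idx]
    W1[j, ] <- wts[idx + seq_len(p)]
    idx <- idx + p + 1L
  }
  b2 <- wts[idx]
  w2 <- wts[idx + seq_len(hidden)]
  idx <- idx + hidden
  w_skip <- wts[idx + seq_len(p)]
  structure(list(inputs = inputs, center = std$center, scale = std$scale,
                 W1 = W1, b1 = b1,
                 w2 = horizon * w2, b2 = horizon * b2,
                 w_skip = horizon * w_skip, hidden = hidden,
                 horizon = horizon),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat("Risk network:", length(x$inputs), "inputs,", x$hidden,
      "hidden nodes (sigmoid), linear output in days\n")
  cat("Inputs:", paste(x$inputs, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the time-to-exacerbation risk score
#'
#' Deterministic forward pass: inputs are standardised with the model's
#' training constants, passed through the sigmoid hidden layer, and combined
#' linearly (including skip-layer terms). The output is an unbounded real
#' interpreted as predicted days to exacerbation — lower means higher risk.
#'
#' @param model An [train_final()] result.
#' @param newdata Named numeric vector, matrix, or data frame covering all
#'   model inputs.
#' @return Numeric vector of risk scores (days).
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "ann_model"))
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.data.frame(newdata)
  miss <- setdiff(model$inputs, names(newdata))
  if (length(miss))
    stop("missing model input(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  Z <- apply_standardizer(as.matrix(newdata[model$inputs]),
                          list(center = model$center, scale = model$scale))
  H <- plogis(Z %*% t(model$W1) + matrix(model$b1, nrow(Z), model$hidden,
                                         byrow = TRUE))
  as.numeric(model$b2 + H %*% model$w2 + Z %*% model$w_skip)
}

#' Render the trained network as an explicit formula
#'
#' Produces a self-contained R expression (as text) computing the risk
#' score from the raw input features — the "mathematical formula" form of
#' the model. Evaluating it in an environment holding the input variables
#' reproduces [predict_risk()].
#'
#' @param model An `ann_model`.
#' @param digits Significant digits in the rendered constants (default 17,
#'   i.e. exact double round-trip).
#' @return A single character string.
#' @export
render_formula <- function(model, digits = 17) {
  stopifnot(inherits(model, "ann_model"))
  num <- function(x) formatC(x, digits = digits, format = "g")
  z <- vapply(seq_along(model$inputs), function(i)
    sprintf("((%s - %s) / %s)", model$inputs[i], num(model$center[i]),
            num(model$scale[i])), character(1))
  hid <- vapply(seq_len(model$hidden), function(j) {
    lin <- paste(c(num(model$b1[j]),
                   vapply(seq_along(z), function(i)
                     sprintf("%s * %s", num(model$W1[j, i]), z[i]),
                     character(1))), collapse = " + ")
    sprintf("%s / (1 + exp(-(%s)))", num(model$w2[j]), lin)
  }, character(1))
  skip <- vapply(seq_along(z), function(i)
    sprintf("%s * %s", num(model$w_skip[i]), z[i]), character(1))
  paste(c(num(model$b2), hid, skip), collapse = " + ")
}

#' Export / import the risk model as JSON
#'
#' The JSON file carries the selected inputs, standardisation constants,
#' all weights, and the rendered formula string; a read/write round trip
#' preserves predictions to full double precision.
#'
#' @param model An `ann_model`.
#' @param path File path.
#' @return `write_ann_json` returns `path` invisibly; `read_ann_json`
#'   returns the `ann_model`.
#' @export
write_ann_json <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(inputs = model$inputs,
              center = unname(model$center), scale = unname(model$scale),
              W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
              w_skip = model$w_skip, hidden = model$hidden,
              horizon = model$horizon,
              formula = render_formula(model))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ann_json
#' @export
read_ann_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(inputs = obj$inputs,
                 center = setNames(obj$center, obj$inputs),
                 scale = setNames(obj$scale, obj$inputs),
                 W1 = matrix(obj$W1, nrow = obj$hidden),
                 b1 = obj$b1, w2 = obj$w2, b2 = obj$b2,
                 w_skip = obj$w_skip, hidden = obj$hidden,
                 horizon = obj$horizon),
            class = "ann_model")
}

#' Squared Pearson correlation of predicted vs actual tte per split
#'
#' @param predictions,actual Numeric vectors.
#' @param splits Factor/character of the same length assigning rows to
#'   splits (e.g. train/validation/test); `NULL` = one split.
#' @return Named numeric vector of r-squared values.
#' @export
evaluate_regression <- function(predictions, actual, splits = NULL) {
  stopifnot(length(predictions) == length(actual))
  if (is.null(splits)) splits <- rep("all", length(actual))
  vapply(split(seq_along(actual), splits), function(idx) {
    if (length(idx) < 3)
      stop("need at least 3 points per split", call. = FALSE)
    if (sd(predictions[idx]) == 0) {
      warning("zero-variance predictions: r-squared reported as 0")
      return(0)
    }
    stats::cor(predictions[idx], actual[idx])^2
  }, numeric(1))
}
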