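# Independent oracles used across the suite.  These never call the code
# paths they check: the filter oracle conditions the joint multivariate
# normal of (states, observations) directly; the AUC oracle enumerates all
# positive-negative pairs; the forward-pass oracle is plain matrix algebra.

# Brute-force causal filter: for each day t, E[mu_t + s_t | y_{1:t}] by
# direct conditioning of the joint Gaussian built from the state recursion
# x_t = G x_{t-1} + w_t, y_t = F x_t + eps_t.
brute_force_filter <- function(y, batch, par, m0, C0mu) {
  T <- length(y)
  G <- diag(c(1, par$phi, 1))
  C0 <- diag(c(C0mu, if (par$W_s > 0) par$W_s / (1 - par$phi^2) else 0, 0))
  D <- matrix(0, 3 + 3 * T, 3 + 3 * T)
  D[1:3, 1:3] <- C0
  for (t in 1:T) {
    Wt <- diag(c(par$W_mu, par$W_s,
                 if (t > 1 && batch[t] != batch[t - 1]) par$W_b else 0))
    D[3 * t + (1:3), 3 * t + (1:3)] <- Wt
  }
  B <- matrix(0, 3 * T, 3 + 3 * T)
  prev <- cbind(diag(3), matrix(0, 3, 3 * T))
  for (t in 1:T) {
    cur <- G %*% prev
    cur[, 3 * t + (1:3)] <- cur[, 3 * t + (1:3)] + diag(3)
    B[3 * (t - 1) + (1:3), ] <- cur
    prev <- cur
  }
  mean_states <- B %*% c(m0, 0, 0, rep(0, 3 * T))
  S <- B %*% D %*% t(B)
  F_ <- matrix(0, T, 3 * T)
  for (t in 1:T) F_[t, 3 * (t - 1) + (1:3)] <- 1
  mu_y <- F_ %*% mean_states
  Syy <- F_ %*% S %*% t(F_) + par$V * diag(T)
  Sxy <- S %*% t(F_)
  out <- rep(NA_real_, T)
  for (t in 1:T) {
    obs <- which(!is.na(y) & seq_len(T) <= t)
    L <- matrix(0, 1, 3 * T)
    L[1, 3 * (t - 1) + 1] <- 1
    L[1, 3 * (t - 1) + 2] <- 1
    if (!length(obs)) {
      out[t] <- L %*% mean_states
      next
    }
    out[t] <- L %*% mean_states +
      (L %*% Sxy[, obs, drop = FALSE]) %*%
      solve(Syy[obs, obs, drop = FALSE], y[obs] - mu_y[obs])
  }
  out
}

# Joint-Gaussian log density of the observed y under the model (oracle for
# the prediction-error-decomposition log-likelihood).
brute_force_loglik <- function(y, batch, par, m0, C0mu) {
  T <- length(y)
  G <- diag(c(1, par$phi, 1))
  C0 <- diag(c(C0mu, if (par$W_s > 0) par$W_s / (1 - par$phi^2) else 0, 0))
  D <- matrix(0, 3 + 3 * T, 3 + 3 * T)
  D[1:3, 1:3] <- C0
  for (t in 1:T)
    D[3 * t + (1:3), 3 * t + (1:3)] <-
      diag(c(par$W_mu, par$W_s,
             if (t > 1 && batch[t] != batch[t - 1]) par$W_b else 0))
  B <- matrix(0, 3 * T, 3 + 3 * T)
  prev <- cbind(diag(3), matrix(0, 3, 3 * T))
  for (t in 1:T) {
    cur <- G %*% prev
    cur[, 3 * t + (1:3)] <- cur[, 3 * t + (1:3)] + diag(3)
    B[3 * (t - 1) + (1:3), ] <- cur
    prev <- cur
  }
  F_ <- matrix(0, T, 3 * T)
  for (t in 1:T) F_[t, 3 * (t - 1) + (1:3)] <- 1
  mu_y <- F_ %*% B %*% c(m0, 0, 0, rep(0, 3 * T))
  Syy <- F_ %*% B %*% D %*% t(B) %*% t(F_) + par$V * diag(T)
  obs <- which(!is.na(y))
  S <- Syy[obs, obs, drop = FALSE]
  r <- y[obs] - mu_y[obs]
  ch <- chol(S)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# Exhaustive pairwise AUC: wins + half-ties over all pos x neg pairs.
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Simulate one series from the DLM generative model.
sim_dlm_series <- function(T, par, batch_len = 28, seed = 1, miss = 0.1,
                           m0 = 2) {
  set.seed(seed)
  batch <- (seq_len(T) - 1) %/% batch_len + 1
  mu <- cumsum(c(m0, rnorm(T - 1, 0, sqrt(par$W_mu))))
  s <- numeric(T)
  sp <- rnorm(1, 0, sqrt(par$W_s / (1 - par$phi^2)))
  for (t in 1:T) {
    sp <- par$phi * sp + rnorm(1, 0, sqrt(par$W_s))
    s[t] <- sp
  }
  b <- 0
  bo <- numeric(T)
  for (t in 1:T) {
    if (t > 1 && batch[t] != batch[t - 1]) b <- b + rnorm(1, 0, sqrt(par$W_b))
    bo[t] <- b
  }
  y <- mu + s + bo + rnorm(T, 0, sqrt(par$V))
  if (miss > 0) y[runif(T) < miss] <- NA
  data.frame(day = seq_len(T), log_value = y, batch_id = batch)
}

# Small filtered data frame for feature tests: deterministic values.
toy_filtered <- function(days = 1:60, markers = c("A", "B"),
                         fun = function(d, mk) 1 + 0 * d) {
  do.call(rbind, lapply(markers, function(mk)
    data.frame(patient_id = "P001", day = days, marker = mk,
               filtered_value = fun(days, mk))))
}

# Reference red-day rule: day t is red iff >= `need` of the trailing `span`
# days (inclusive, truncated at the series start) are amber.
brute_force_reds <- function(amber, need = 6, span = 7) {
  vapply(seq_along(amber), function(t)
    sum(amber[max(1, t - span + 1):t]) >= need, logical(1))
}
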