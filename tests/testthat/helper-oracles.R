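# Independent oracles used across tests.

# Brute-force joint-Gaussian evaluation of the scalar-state LDS: builds the
# full covariance of (x_1..x_n, y_1..y_n) by recursion and conditions x on the
# observed y. Independent of the Kalman recursions in the package.
lds_joint_oracle <- function(params, y, inputs) {
  n <- length(y)
  terms <- srtbind:::lds_terms(params, inputs)
  mx <- numeric(n)
  Sxx <- matrix(0, n, n)
  mx[1] <- params$x1_mean
  Sxx[1, 1] <- params$x1_var
  for (t in seq_len(n - 1)) {
    mx[t + 1] <- params$A * mx[t] + terms$u[t]
    Sxx[t + 1, 1:t] <- params$A * Sxx[t, 1:t]
    Sxx[1:t, t + 1] <- Sxx[t + 1, 1:t]
    Sxx[t + 1, t + 1] <- params$A^2 * Sxx[t, t] + params$Q
  }
  my <- mx + terms$o
  Syy <- Sxx + diag(params$R, n)
  obs <- which(!is.na(y))
  So <- Syy[obs, obs, drop = FALSE]
  resid <- y[obs] - my[obs]
  W <- solve(So)
  cond_mean <- mx + Sxx[, obs, drop = FALSE] %*% W %*% resid
  cond_cov <- Sxx - Sxx[, obs, drop = FALSE] %*% W %*% Sxx[obs, , drop = FALSE]
  L <- chol(So)
  ll <- -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(L))) +
                  sum(resid * (W %*% resid)))
  list(means = as.numeric(cond_mean), vars = diag(cond_cov),
       cov = cond_cov, loglik = as.numeric(ll))
}

# Double-loop autocovariance oracle (biased 1/n normalization).
acf_bruteforce <- function(x, n_lags) {
  n <- length(x)
  x <- x - mean(x)
  c0 <- 0
  for (t in 1:n) c0 <- c0 + x[t]^2
  c0 <- c0 / n
  rho <- numeric(n_lags)
  for (l in 1:n_lags) {
    s <- 0
    for (t in 1:(n - l)) s <- s + x[t] * x[t + l]
    rho[l] <- (s / n) / c0
  }
  rho
}

# Coarse-binned plug-in mutual information estimate between two vectors.
mutual_information <- function(a, b, bins = 8) {
  qa <- cut(a, stats::quantile(a, probs = seq(0, 1, length.out = bins + 1)),
            include.lowest = TRUE)
  qb <- cut(b, stats::quantile(b, probs = seq(0, 1, length.out = bins + 1)),
            include.lowest = TRUE)
  pj <- table(qa, qb) / length(a)
  pa <- rowSums(pj); pb <- colSums(pj)
  sum(pj[pj > 0] * log(pj[pj > 0] / outer(pa, pb)[pj > 0]))
}

# Small fast subject config for generator-based tests.
quick_config <- function(seed = 1L, ...) {
  subject_config(seed = seed, ...)
}
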