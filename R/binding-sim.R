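#' Configuration for the response-binding toy model
#'
#' A minimal generative model of response chunking: on each trial the internal
#' response plan follows a stationary AR(1) around `mu_p_ms`,
#' `x_t = mu_p + alpha * (x_{t-1} - mu_p) + N(0, sigma_p^2)`, and the motor
#' output adds independent execution noise, `y_t = x_t + N(0, sigma_e^2)`.
#' The coupling `alpha` spans statistically independent plans (0) to strongly
#' bound plans (e.g. 0.75). The canonical simulation uses mu_p = 200 ms,
#' sigma_p = sigma_e = 10 ms and 100 blocks of 1000 trials.
#'
#' @param alpha Inter-plan binding coefficient in \[0, 1).
#' @param mu_p_ms Mean plan latency (ms).
#' @param sigma_p_ms Plan innovation SD (ms).
#' @param sigma_e_ms Execution noise SD (ms).
#' @param n_blocks,n_trials Simulation size.
#' @param seed Integer seed.
#' @return An object of class `binding_config`.
#' @export
binding_config <- function(alpha = 0, mu_p_ms = 200, sigma_p_ms = 10,
                           sigma_e_ms = 10, n_blocks = 100L,
                           n_trials = 1000L, seed = 1L) {
  if (alpha < 0 || alpha >= 1)
    stop("binding_config: alpha must be in [0, 1) for stationarity")
  stopifnot(sigma_p_ms >= 0, sigma_e_ms >= 0, n_blocks >= 1, n_trials >= 2)
  structure(list(alpha = alpha, mu_p_ms = mu_p_ms, sigma_p_ms = sigma_p_ms,
                 sigma_e_ms = sigma_e_ms, n_blocks = as.integer(n_blocks),
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "binding_config")
}

#' Simulate the response-binding model
#'
#' Draws `n_blocks` independent blocks of `n_trials` responses from the
#' AR(1)-plus-execution-noise model of [binding_config()]. The first plan of
#' each block is drawn from the stationary distribution, so block-level
#' autocorrelation is unbiased without burn-in. Deterministic given the seed.
#'
#' @param config A [binding_config()].
#' @return Numeric matrix `n_blocks x n_trials` of simulated responses y (ms).
#' @export
simulate_binding <- function(config) {
  stopifnot(inherits(config, "binding_config"))
  set.seed(config$seed)
  nb <- config$n_blocks; nt <- config$n_trials
  a <- config$alpha
  sd_x <- if (a > 0) config$sigma_p_ms / sqrt(1 - a^2) else config$sigma_p_ms
  y <- matrix(0, nb, nt)
  for (b in seq_len(nb)) {
    innov <- stats::rnorm(nt, 0, config$sigma_p_ms)
    dev <- if (a > 0)
      as.numeric(stats::filter(innov, a, method = "recursive",
                               init = stats::rnorm(1, 0, sd_x)))
    else innov
    y[b, ] <- config$mu_p_ms + dev + stats::rnorm(nt, 0, config$sigma_e_ms)
  }
  y
}

#' Closed-form autocorrelation of the binding model
#'
#' The analytic ACF of the observed responses:
#' `rho(lag) = alpha^lag * sigma_x^2 / (sigma_x^2 + sigma_e^2)` with
#' stationary plan variance `sigma_x^2 = sigma_p^2 / (1 - alpha^2)`. Serves as
#' the oracle against which simulated profiles are checked, and as the
#' calibration tool for planting a known binding span.
#'
#' @param alpha Binding coefficient in \[0, 1).
#' @param sigma_p Plan innovation SD.
#' @param sigma_e Execution noise SD.
#' @param lag Lag(s), integer >= 1 (vectorized).
#' @return Theoretical autocorrelation value(s).
#' @examples
#' theoretical_acf(0.75, 10, 10, 1)   # 0.5217
#' theoretical_acf(0.9, 10, 0, 3)     # 0.9^3: no observation noise
#' @export
theoretical_acf <- function(alpha, sigma_p, sigma_e, lag) {
  if (any(alpha < 0) || any(alpha >= 1))
    stop("theoretical_acf: alpha must be in [0, 1)")
  if (any(lag < 1)) stop("theoretical_acf: lag must be >= 1")
  if (sigma_p == 0 && sigma_e == 0) stop("theoretical_acf: degenerate (no variance)")
  var_x <- sigma_p^2 / (1 - alpha^2)
  alpha^lag * var_x / (var_x + sigma_e^2)
}

#' Mean empirical ACF across simulated blocks
#'
#' Per-block autocorrelation (biased 1/n estimator, block mean removed),
#' averaged across blocks; the Monte-Carlo summary used to compare simulation
#' with [theoretical_acf()].
#'
#' @param y Matrix `n_blocks x n_trials` from [simulate_binding()].
#' @param n_lags Number of lags (default 31).
#' @return List with `mean_rho`, `sd_rho` (across blocks), `se_rho`
#'   (`sd / sqrt(n_blocks)`), and `n_blocks`.
#' @export
binding_acf <- function(y, n_lags = 31L) {
  per_block <- apply(y, 1, function(row) acf31(row - mean(row), n_lags)$rho)
  per_block <- if (is.null(dim(per_block))) matrix(per_block, ncol = 1)
  else t(per_block)
  list(mean_rho = colMeans(per_block),
       sd_rho = apply(per_block, 2, stats::sd),
       se_rho = apply(per_block, 2, stats::sd) / sqrt(nrow(y)),
       n_blocks = nrow(y))
}
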