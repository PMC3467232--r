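#' Parameters of the response-preparedness state-space model
#'
#' The trial-by-trial model of response preparedness is a scalar-state linear
#' dynamical system in reaction-time units (ms):
#'
#' \deqn{x_{t+1} = A x_t + B \cdot Y_t + F e_t + q_t, \quad q_t \sim N(0, Q)}
#' \deqn{y_t = x_t + D \cdot K_t + r_t, \quad r_t \sim N(0, R)}
#'
#' where \eqn{K_t} is the one-hot cue vector, \eqn{Y_t} the one-hot vector of
#' the key pressed on trial t (regardless of accuracy), and \eqn{e_t} the
#' binary error flag of trial t. The latent state \eqn{x_t} shifts the next
#' reaction time: negative values are prepared (fast) trials, positive values
#' hesitations. A is the state memory, B the per-key response prediction, D
#' the per-key response bias, F the error correction (post-error state delay),
#' Q and R the state and motor noise variances.
#'
#' @param A State memory (dimensionless retention coefficient).
#' @param B Length-8 response-prediction weights (ms).
#' @param D Length-8 response-bias weights (ms).
#' @param F_err Error-correction weight F (ms; named `F_err` to avoid R's
#'   `F`/`FALSE` pun, reported as `F`).
#' @param Q State noise variance (ms^2).
#' @param R Motor noise variance (ms^2).
#' @param x1_mean,x1_var Prior mean and variance of the initial state.
#' @return An object of class `lds_params`.
#' @export
lds_params <- function(A = 0.5, B = rep(0, 8), D = rep(0, 8), F_err = 0,
                       Q = 25, R = 100, x1_mean = 0, x1_var = 10 * Q) {
  stopifnot(length(B) == 8, length(D) == 8, Q >= 0, R >= 0, x1_var >= 0)
  structure(list(A = A, B = as.numeric(B), D = as.numeric(D), F_err = F_err,
                 Q = Q, R = R, x1_mean = x1_mean, x1_var = x1_var),
            class = "lds_params")
}

#' @export
print.lds_params <- function(x, ...) {
  cat("Response-preparedness LDS parameters (ms units)\n")
  cat(sprintf("  A (state memory)     : %.4f\n", x$A))
  cat(sprintf("  F (error correction) : %.3f ms\n", x$F_err))
  cat(sprintf("  Q (state noise)      : %.3f ms^2\n", x$Q))
  cat(sprintf("  R (motor noise)      : %.3f ms^2\n", x$R))
  cat("  B (response prediction, per key):\n   ")
  cat(sprintf(" %.2f", x$B), "\n")
  cat("  D (response bias, per key):\n   ")
  cat(sprintf(" %.2f", x$D), "\n")
  invisible(x)
}

#' Per-trial inputs for the state-space model
#'
#' Builds the deterministic input structure from a block's cue, press and
#' error records: the one-hot cue index for the output equation, and the
#' previous trial's press one-hot and error flag for the state update (the
#' update into trial t uses what happened on trial t-1).
#'
#' @param cue_key Integer 1-8 cue per trial.
#' @param pressed_key Integer 1-8 key pressed per trial (NA for omissions; an
#'   omitted press contributes a zero one-hot).
#' @param is_error Logical error flag per trial.
#' @param block Optional block/segment id per trial; state information does
#'   not flow across segments.
#' @return A list of class `lds_inputs` with `cue`, `press`, `error`, `block`.
#' @export
lds_inputs <- function(cue_key, pressed_key = cue_key,
                       is_error = rep(FALSE, length(cue_key)),
                       block = rep(1L, length(cue_key))) {
  n <- length(cue_key)
  stopifnot(length(pressed_key) == n, length(is_error) == n,
            length(block) == n)
  if (!all(cue_key %in% 1:8)) stop("lds_inputs: cue_key must be in 1..8")
  if (!all(is.na(pressed_key) | pressed_key %in% 1:8))
    stop("lds_inputs: pressed_key must be in 1..8 or NA")
  structure(list(cue = as.integer(cue_key),
                 press = as.integer(pressed_key),
                 error = as.logical(is_error),
                 block = as.integer(block)),
            class = "lds_inputs")
}

# Deterministic per-trial terms: observation offset o_t = D.K_t and state
# input u_t = B.Y_t + F e_t (u_t feeds the transition t -> t+1).
lds_terms <- function(params, inputs) {
  o <- params$D[inputs$cue]
  b_term <- ifelse(is.na(inputs$press), 0, params$B[ifelse(is.na(inputs$press),
                                                           1L, inputs$press)])
  u <- b_term + params$F_err * as.numeric(inputs$error)
  list(o = o, u = u)
}

#' One-step prediction and observation means
#'
#' The deterministic skeleton of the model: given the current state and trial
#' inputs, returns the mean observation for this trial and the mean next
#' state. Noise (Q, R) enters only in sampling and likelihood.
#'
#' @param params [lds_params()].
#' @param x_t Current state (ms).
#' @param cue_key Cue on this trial (1-8).
#' @param pressed_key Key pressed on this trial (1-8 or NA).
#' @param is_error Was this trial an error?
#' @return List with `y_mean` and `x_next_mean`.
#' @export
lds_predict_observe <- function(params, x_t, cue_key, pressed_key = cue_key,
                                is_error = FALSE) {
  y_mean <- x_t + params$D[cue_key]
  b <- if (is.na(pressed_key)) 0 else params$B[pressed_key]
  x_next <- params$A * x_t + b + params$F_err * as.numeric(is_error)
  list(y_mean = y_mean, x_next_mean = x_next)
}

#' Exact Kalman filter and RTS smoother
#'
#' Runs the exact forward filter and Rauch-Tung-Striebel smoother for the
#' scalar-state model, returning smoothed state means/variances, the lag-one
#' smoothed covariances needed by EM, and the exact Gaussian marginal
#' log-likelihood. Missing observations (`NA` in `y`) are treated as
#' unobserved: the filter propagates without an update.
#'
#' @param params [lds_params()].
#' @param y Observed RTs (ms), NA = missing.
#' @param inputs [lds_inputs()] of the same length.
#' @return An object of class `state_trajectory`: list with `smoothed_means`,
#'   `smoothed_vars`, `lag1_cov`, `filtered_means`, `filtered_vars`,
#'   `pred_means`, `pred_vars`, `loglik`.
#' @export
kalman_smooth <- function(params, y, inputs) {
  n <- length(y)
  stopifnot(length(inputs$cue) == n)
  terms <- lds_terms(params, inputs)
  obs <- !is.na(y)
  y0 <- ifelse(obs, y, 0)
  res <- lds_estep_cpp(y0, obs, terms$o, terms$u, inputs$block,
                       params$A, params$Q, params$R,
                       params$x1_mean, params$x1_var)
  structure(list(smoothed_means = res$xs, smoothed_vars = res$Ps,
                 lag1_cov = res$C, filtered_means = res$xf,
                 filtered_vars = res$Pf, pred_means = res$xp,
                 pred_vars = res$Pp, loglik = res$loglik),
            class = "state_trajectory")
}

#' Simulate the state-space model
#'
#' Samples a trial series from the generative model given a cue sequence and
#' an exogenous error sequence. Deterministic given the seed.
#'
#' @param params [lds_params()].
#' @param cue_sequence Integer cues 1-8.
#' @param error_sequence Binary/logical error flags, same length (errors are
#'   exogenous here; pressed key is taken to be the cue).
#' @param seed Integer seed.
#' @param block Optional segment ids (state restarts at each segment).
#' @return List with `y` (simulated RTs), `x` (latent states), and `inputs`.
#' @export
simulate_lds <- function(params, cue_sequence, error_sequence, seed = 1L,
                         block = rep(1L, length(cue_sequence))) {
  n <- length(cue_sequence)
  stopifnot(length(error_sequence) == n)
  set.seed(seed)
  inputs <- lds_inputs(cue_sequence, cue_sequence,
                       as.logical(error_sequence), block)
  terms <- lds_terms(params, inputs)
  x <- numeric(n); y <- numeric(n)
  sq <- sqrt(params$Q); sr <- sqrt(params$R); s1 <- sqrt(params$x1_var)
  for (t in seq_len(n)) {
    x[t] <- if (t == 1 || block[t] != block[t - 1])
      params$x1_mean + stats::rnorm(1, 0, s1)
    else params$A * x[t - 1] + terms$u[t - 1] + stats::rnorm(1, 0, sq)
    y[t] <- x[t] + terms$o[t] + stats::rnorm(1, 0, sr)
  }
  list(y = y, x = x, inputs = inputs)
}

# Expected sufficient statistics and closed-form M-step.
# State regression: x_{t+1} on z_t = (x_t, Y_t one-hot, e_t); D and R from the
# output equation. Predictor columns that never occur (keys never pressed, no
# errors) are dropped and their coefficients held at zero.
lds_mstep <- function(y, inputs, traj, est_B = TRUE, est_F = TRUE) {
  n <- length(y)
  xs <- traj$smoothed_means; Ps <- traj$smoothed_vars; C <- traj$lag1_cov
  within <- which(!is.na(C))       # transitions t -> t+1 inside a segment
  t0 <- within; t1 <- within + 1L

  press <- inputs$press; err <- as.numeric(inputs$error)
  # design for the state equation at transition t -> t+1
  Z_cols <- list(x = NULL)         # handled via moments
  press_mat <- matrix(0, length(t0), 8)
  okp <- !is.na(press[t0])
  press_mat[cbind(which(okp), press[t0][okp])] <- 1
  e_col <- err[t0]

  keep_B <- if (est_B) which(colSums(press_mat) > 0) else integer(0)
  keep_F <- est_F && sum(e_col) > 0
  Zdet <- cbind(press_mat[, keep_B, drop = FALSE],
                if (keep_F) e_col else NULL)
  p_det <- ncol(Zdet)

  Ex0 <- xs[t0]; Ex1 <- xs[t1]
  Ex0x0 <- xs[t0]^2 + Ps[t0]
  Ex0x1 <- xs[t0] * xs[t1] + C[t0]
  Ex1x1 <- xs[t1]^2 + Ps[t1]

  # normal equations for theta = (A, coef(Zdet))
  p <- 1L + p_det
  S_zz <- matrix(0, p, p); S_zx <- numeric(p)
  S_zz[1, 1] <- sum(Ex0x0)
  S_zx[1] <- sum(Ex0x1)
  if (p_det > 0) {
    S_zz[1, -1] <- S_zz[-1, 1] <- as.numeric(crossprod(Zdet, Ex0))
    S_zz[-1, -1] <- crossprod(Zdet)
    S_zx[-1] <- as.numeric(crossprod(Zdet, Ex1))
  }
  theta <- tryCatch(solve(S_zz, S_zx),
                    error = function(e) solve(S_zz + diag(1e-8, p), S_zx))
  A_new <- theta[1]
  B_new <- rep(0, 8)
  if (length(keep_B)) B_new[keep_B] <- theta[1 + seq_along(keep_B)]
  F_new <- if (keep_F) theta[p] else 0

  # Q: expected residual variance of the state equation
  fit_det <- if (p_det > 0) as.numeric(Zdet %*% theta[-1]) else 0
  Q_new <- sum(Ex1x1 - 2 * A_new * Ex0x1 - 2 * fit_det * Ex1 +
                 A_new^2 * Ex0x0 + 2 * A_new * fit_det * Ex0 + fit_det^2) /
    length(t0)

  # D and R from observed trials: D_k = mean(y - E[x]) over trials cued k
  obs <- which(!is.na(y))
  resid <- y[obs] - xs[obs]
  D_new <- rep(0, 8)
  for (k in 1:8) {
    idx <- obs[inputs$cue[obs] == k]
    if (length(idx)) D_new[k] <- mean(y[idx] - xs[idx])
  }
  R_new <- mean((y[obs] - xs[obs] - D_new[inputs$cue[obs]])^2 + Ps[obs])

  list(A = A_new, B = B_new, D = D_new, F_err = F_new,
       Q = max(Q_new, 1e-10), R = max(R_new, 1e-10))
}

#' Fit the response-preparedness state-space model by EM
#'
#' Estimates the free parameters A, B, D, F, Q, R of the scalar-state linear
#' dynamical system (see [lds_params()]) from a reaction-time series by
#' expectation-maximization: the E-step is the exact Kalman
#' filter/RTS smoother ([kalman_smooth()]), the M-step solves closed-form
#' regression updates from the expected sufficient statistics (A, B, F
#' jointly from the state equation; D and R from the output equation). The
#' log-likelihood is non-decreasing across iterations.
#'
#' Identifiability: the state mean trades off against D, so `y` is centered
#' (per segment) before fitting and D is reported as per-key deviations plus
#' the segment mean. The initial state prior is fixed at mean 0 and variance
#' `10 * Q0` and is not estimated. Missing RTs are treated as unobserved by
#' default (`missing = "skip"`); `missing = "mean"` instead imputes the
#' segment mean before fitting.
#'
#' @param y Reaction-time series (ms), NA = missing.
#' @param inputs [lds_inputs()] for the same trials.
#' @param init Optional initial [lds_params()]; defaults to A = 0.5, B = 0,
#'   F = 0, D = per-key mean RT, Q = R = half the residual variance.
#' @param max_iter Maximum EM iterations (default 200).
#' @param rel_tol Relative log-likelihood improvement at which to stop
#'   (default 1e-6).
#' @param est_B,est_F Estimate B / F (fix at 0 when FALSE).
#' @param missing `"skip"` (default) or `"mean"`.
#' @param center Center y before fitting (default TRUE; see Details).
#' @return An object of class `lds_fit`: the fitted `params`, the smoothed
#'   `trajectory` at the optimum, `loglik`, `loglik_path`, `iterations`,
#'   `converged`, plus the data and metadata needed by the methods
#'   (`print`, `summary`, `coef`, `logLik`, `fitted`, `residuals`,
#'   `predict`, `simulate`, `plot`).
#' @examples
#' sq <- canonical_sequence()
#' cues <- rep(sq$items, 4)
#' sim <- simulate_lds(lds_params(A = 0.6, F_err = 12, D = rep(300, 8)),
#'                     cues, rbinom(length(cues), 1, 0.1), seed = 2)
#' fit <- fit_lds(sim$y, sim$inputs, est_B = FALSE)
#' coef(fit)["A"]
#' @export
fit_lds <- function(y, inputs, init = NULL, max_iter = 200L, rel_tol = 1e-6,
                    est_B = TRUE, est_F = TRUE,
                    missing = c("skip", "mean"), center = TRUE) {
  missing <- match.arg(missing)
  n <- length(y)
  stopifnot(length(inputs$cue) == n)
  if (n < 10) stop("fit_lds: need at least 10 trials")

  y_work <- y
  offsets <- rep(0, n)
  for (b in unique(inputs$block)) {
    idx <- which(inputs$block == b)
    m <- mean(y[idx], na.rm = TRUE)
    if (missing == "mean") y_work[idx][is.na(y_work[idx])] <- m
    if (center) {
      y_work[idx] <- y_work[idx] - m
      offsets[idx] <- m
    }
  }

  if (is.null(init)) {
    v <- stats::var(y_work, na.rm = TRUE)
    D0 <- vapply(1:8, function(k) {
      idx <- which(inputs$cue == k & !is.na(y_work))
      if (length(idx)) mean(y_work[idx]) else 0
    }, numeric(1))
    init <- lds_params(A = 0.5, B = rep(0, 8), D = D0, F_err = 0,
                       Q = v / 2, R = v / 2)
  }
  params <- init
  x1_var0 <- init$x1_var   # fixed prior, not estimated

  ll_path <- numeric(0)
  converged <- FALSE
  traj <- NULL
  for (it in seq_len(max_iter)) {
    traj <- kalman_smooth(params, y_work, inputs)
    if (!is.finite(traj$loglik))
      stop("fit_lds: non-finite log-likelihood at iteration ", it)
    ll_path <- c(ll_path, traj$loglik)
    if (it > 1) {
      prev <- ll_path[it - 1]
      if (abs(traj$loglik - prev) < rel_tol * max(1, abs(prev))) {
        converged <- TRUE
        break
      }
    }
    up <- lds_mstep(y_work, inputs, traj, est_B = est_B, est_F = est_F)
    if (any(!is.finite(c(up$A, up$B, up$D, up$F_err, up$Q, up$R))))
      stop("fit_lds: divergent M-step statistics at iteration ", it)
    params <- lds_params(A = up$A, B = up$B, D = up$D, F_err = up$F_err,
                         Q = up$Q, R = up$R,
                         x1_mean = 0, x1_var = x1_var0)
  }

  # report D on the original scale: deviations plus segment mean (single
  # segment) or the grand mean across segments
  D_report <- params$D + if (center) mean(offsets) else 0

  structure(list(
    params = params,
    D_reported = D_report,
    trajectory = traj,
    loglik = ll_path[length(ll_path)],
    loglik_path = ll_path,
    iterations = length(ll_path),
    converged = converged,
    y = y, y_centered = y_work, offsets = offsets, inputs = inputs,
    n = n, missing = missing, centered = center,
    est_B = est_B, est_F = est_F
  ), class = "lds_fit")
}

#' @export
print.lds_fit <- function(x, ...) {
  cat("Response-preparedness state-space model (EM fit)\n")
  cat(sprintf("  %d trials, %d EM iterations (%s), logLik = %.2f\n",
              x$n, x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              x$loglik))
  print(x$params)
  invisible(x)
}

#' @export
summary.lds_fit <- function(object, ...) {
  st <- object$trajectory$smoothed_means
  cat("Response-preparedness state-space model\n")
  cat(sprintf("  trials: %d (missing: %d)\n", object$n, sum(is.na(object$y))))
  cat(sprintf("  EM: %d iterations, converged = %s, logLik = %.2f\n",
              object$iterations, object$converged, object$loglik))
  cat(sprintf("  state memory A = %.4f, error correction F = %.3f ms\n",
              object$params$A, object$params$F_err))
  cat(sprintf("  noise: Q = %.2f ms^2, R = %.2f ms^2\n",
              object$params$Q, object$params$R))
  cat(sprintf("  smoothed state: mean %.2f ms, sd %.2f ms; %0.1f%% prepared (x < 0)\n",
              mean(st), stats::sd(st), 100 * mean(st < 0)))
  invisible(object)
}

#' @export
coef.lds_fit <- function(object, ...) {
  p <- object$params
  c(A = p$A, F = p$F_err, Q = p$Q, R = p$R,
    stats::setNames(p$B, paste0("B", 1:8)),
    stats::setNames(object$D_reported, paste0("D", 1:8)))
}

#' @export
logLik.lds_fit <- function(object, ...) {
  n_par <- 1 + 1 + 2 + 8 * (1 + object$est_B)  # A, F, Q, R, D (+B)
  structure(object$loglik, df = n_par, nobs = sum(!is.na(object$y)),
            class = "logLik")
}

#' @export
fitted.lds_fit <- function(object, ...) {
  object$trajectory$smoothed_means + object$params$D[object$inputs$cue] +
    object$offsets
}

#' @export
residuals.lds_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' One-step-ahead predictions from a fitted model
#'
#' @param object An `lds_fit`.
#' @param ... Unused.
#' @return Predicted observation means (original scale) from the filter's
#'   one-step-ahead state predictions.
#' @export
predict.lds_fit <- function(object, ...) {
  object$trajectory$pred_means + object$params$D[object$inputs$cue] +
    object$offsets
}

#' @export
simulate.lds_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  reps <- lapply(seq_len(nsim), function(i)
    simulate_lds(lds_params(A = p$A, B = p$B, D = object$D_reported,
                            F_err = p$F_err, Q = p$Q, R = p$R,
                            x1_mean = p$x1_mean, x1_var = p$x1_var),
                 object$inputs$cue, object$inputs$error,
                 seed = sample.int(.Machine$integer.max, 1),
                 block = object$inputs$block)$y)
  out <- as.data.frame(reps)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.lds_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  st <- x$trajectory$smoothed_means
  graphics::plot(st, type = "l", xlab = "trial",
                 ylab = "preparedness state (ms)",
                 main = "Smoothed response-preparedness state", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::plot(x$y, type = "p", pch = 16, cex = 0.4, xlab = "trial",
                 ylab = "RT (ms)", main = "Observed and fitted RTs")
  graphics::lines(fitted(x), col = 2)
}

#' Fit the state-space model to one probe block of a trial table
#'
#' Convenience wrapper: extracts a subject/day probe block and runs
#' [fit_lds()] on its RT series (errors = incorrect trials).
#'
#' @param trials Trial data.frame.
#' @param subject,day,block_type Block selector.
#' @param ... Passed to [fit_lds()].
#' @return An `lds_fit`.
#' @export
fit_lds_block <- function(trials, subject, day,
                          block_type = "sequence_probe", ...) {
  blk <- trials[trials$subject == subject & trials$day == day &
                  trials$block_type == block_type, ]
  if (!nrow(blk)) stop("fit_lds_block: no such block")
  inputs <- lds_inputs(blk$cue_key, blk$pressed_key, !blk$correct)
  fit_lds(blk$rt_ms, inputs, ...)
}
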