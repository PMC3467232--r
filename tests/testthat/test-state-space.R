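test_that("prediction/observation means follow the model equations", {
  p <- lds_params(A = 0, B = rep(0, 8), D = c(0, 0, 310, rep(0, 5)),
                  F_err = 0)
  expect_equal(lds_predict_observe(p, 0, cue_key = 3)$y_mean, 310)
  p2 <- lds_params(A = 0.8)
  expect_equal(lds_predict_observe(p2, -10, 1, pressed_key = NA)$x_next_mean, -8)
  # an error delays the next state by F
  p3 <- lds_params(A = 1, B = rep(0, 8), F_err = 15)
  expect_equal(lds_predict_observe(p3, 0, 1, pressed_key = NA,
                                   is_error = TRUE)$x_next_mean, 15)
  # B contribution keyed by the pressed key
  p4 <- lds_params(A = 0, B = c(rep(0, 4), 7, rep(0, 3)))
  expect_equal(lds_predict_observe(p4, 3, 1, pressed_key = 5)$x_next_mean, 7)
})

test_that("smoother equals the joint-Gaussian brute-force oracle", {
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(15:25, 1)
    p <- lds_params(A = runif(1, -0.5, 0.9), B = rnorm(8, 0, 3),
                    D = rnorm(8, 300, 20), F_err = rnorm(1, 10, 5),
                    Q = runif(1, 5, 50), R = runif(1, 20, 150),
                    x1_mean = rnorm(1), x1_var = runif(1, 10, 100))
    cues <- sample.int(8, n, replace = TRUE)
    err <- runif(n) < 0.2
    sim <- simulate_lds(p, cues, err, seed = rep)
    y <- sim$y
    if (rep >= 4) y[sample.int(n, 3)] <- NA   # missing handled as unobserved
    got <- kalman_smooth(p, y, sim$inputs)
    want <- lds_joint_oracle(p, y, sim$inputs)
    expect_equal(got$smoothed_means, want$means, tolerance = 1e-8)
    expect_equal(got$smoothed_vars, want$vars, tolerance = 1e-8)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-8)
    # lag-one smoothed covariances against the oracle's full covariance
    expect_equal(got$lag1_cov[1:(n - 1)],
                 want$cov[cbind(1:(n - 1), 2:n)], tolerance = 1e-8)
  }
})

test_that("noiseless limit reduces to the deterministic recursion", {
  p <- lds_params(A = 0.8, B = rep(0, 8), D = rep(0, 8), F_err = 0,
                  Q = 0, R = 1e-10, x1_mean = 20, x1_var = 0)
  n <- 10
  x_det <- 20 * 0.8^(0:(n - 1))
  inputs <- lds_inputs(rep(1L, n))
  got <- kalman_smooth(p, x_det, inputs)
  expect_equal(got$smoothed_means, x_det, tolerance = 1e-6)
})

test_that("simulate_lds is deterministic and collapses to the mean chain", {
  p <- lds_params(A = 0.7, B = rnorm(8), D = rnorm(8, 300, 10), F_err = 12,
                  Q = 0, R = 0, x1_var = 0, x1_mean = 5)
  cues <- sample.int(8, 40, replace = TRUE)
  err <- rbinom(40, 1, 0.2)
  s1 <- simulate_lds(p, cues, err, seed = 7)
  s2 <- simulate_lds(p, cues, err, seed = 7)
  expect_identical(s1, s2)
  # chained deterministic means
  x <- 5
  for (t in 1:40) {
    expect_equal(s1$y[t], x + p$D[cues[t]], tolerance = 1e-10)
    x <- p$A * x + p$B[cues[t]] + p$F_err * err[t]
  }
})

test_that("EM log-likelihood is non-decreasing on varied datasets", {
  set.seed(2)
  sq <- canonical_sequence()
  for (rep in 1:3) {
    cues <- rep(sq$items, 4)
    err <- rbinom(length(cues), 1, 0.1)
    p <- lds_params(A = runif(1, 0, 0.8), D = rnorm(8, 300, 15),
                    F_err = runif(1, 0, 20), Q = 25, R = 100)
    sim <- simulate_lds(p, cues, err, seed = 40 + rep)
    fit <- fit_lds(sim$y, sim$inputs, max_iter = 60)
    expect_true(all(diff(fit$loglik_path) > -1e-8))
  }
})

test_that("EM recovers A and F from pooled blocks at study scale", {
  set.seed(3)
  sq <- canonical_sequence()
  ests <- sapply(1:6, function(s) {
    nb <- 30
    cues <- rep(rep(sq$items, 8), nb)
    blk <- rep(seq_len(nb), each = 256)
    err <- rbinom(length(cues), 1, 0.1)
    p <- lds_params(A = 0.5, B = rep(0, 8), D = rnorm(8, 300, 20),
                    F_err = 15, Q = 25, R = 100)
    sim <- simulate_lds(p, cues, err, seed = 50 + s, block = blk)
    fit <- fit_lds(sim$y, sim$inputs, est_B = FALSE, max_iter = 150)
    c(A = fit$params$A, F = fit$params$F_err,
      Dcor = cor(fit$D_reported, p$D))
  })
  expect_lt(abs(median(ests["A", ]) - 0.5), 0.1)
  expect_lt(abs(median(ests["F", ]) - 15), 5)
  expect_true(all(ests["F", ] > 0))            # sign of F recovered
  expect_true(all(ests["Dcor", ] > 0.95))      # key ordering of D recovered
})

test_that("null dynamics shrink A toward zero", {
  set.seed(4)
  sq <- canonical_sequence()
  a_hat <- sapply(1:10, function(s) {
    cues <- rep(rep(sq$items, 8), 4)
    blk <- rep(1:4, each = 256)
    err <- rbinom(length(cues), 1, 0.1)
    p <- lds_params(A = 0, B = rep(0, 8), D = rnorm(8, 300, 20),
                    F_err = 0, Q = 25, R = 100)
    sim <- simulate_lds(p, cues, err, seed = 80 + s, block = blk)
    fit_lds(sim$y, sim$inputs, est_B = FALSE, max_iter = 100)$params$A
  })
  expect_gte(mean(abs(a_hat) < 0.1), 0.9)
})

test_that("smoothed state tracks the true latent state", {
  set.seed(5)
  sq <- canonical_sequence()
  rs <- sapply(1:6, function(s) {
    cues <- rep(sq$items, 7)   # 224 trials
    err <- rbinom(length(cues), 1, 0.1)
    p <- lds_params(A = 0.6, D = rnorm(8, 300, 15), F_err = 10,
                    Q = 50, R = 50)  # Q/R = 1
    sim <- simulate_lds(p, cues, err, seed = 60 + s)
    tr <- kalman_smooth(p, sim$y, sim$inputs)
    cor(tr$smoothed_means, sim$x)
  })
  expect_true(all(rs > 0.7))
})

test_that("fitted-model simulation preserves the source block's variance", {
  tr <- simulate_subject(quick_config(seed = 14), days = 10)
  sp <- probe_block(tr, "S01", 10, "sequence_probe")
  fit <- fit_lds_block(tr, "S01", 10)
  y_sim <- simulate(fit, nsim = 5, seed = 1)
  v_src <- var(sp$rt_ms, na.rm = TRUE)
  v_sim <- mean(apply(y_sim, 2, var))
  expect_lt(abs(v_sim - v_src) / v_src, 0.2)
})

test_that("lds_fit methods are coherent", {
  tr <- simulate_subject(quick_config(seed = 15), days = 5)
  fit <- fit_lds_block(tr, "S01", 5)
  expect_s3_class(fit, "lds_fit")
  co <- coef(fit)
  expect_true(all(c("A", "F", "Q", "R") %in% names(co)))
  expect_equal(length(co), 4 + 16)
  obs <- !is.na(fit$y)
  expect_equal(fitted(fit)[obs] + residuals(fit)[obs], fit$y[obs])
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_length(predict(fit), fit$n)
  expect_output(print(fit), "state-space")
  expect_output(summary(fit), "prepared")
})
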