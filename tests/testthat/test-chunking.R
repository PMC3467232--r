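test_that("preprocessing drops the first cycle, detrends and zero-means", {
  # a pure line is removed entirely
  x <- 5 + 0.3 * (1:200)
  out <- preprocess_probe(x)
  expect_length(out, 168)
  expect_true(all(abs(out) < 1e-9))
  # a constant plus spike: spike survives, mean is zero
  x2 <- rep(400, 200); x2[100] <- 480
  out2 <- preprocess_probe(x2)
  expect_lt(abs(mean(out2)), 1e-9)
  expect_gt(max(out2), 70)
  # generator fixture: exact zero mean, length n - 32
  tr <- simulate_subject(quick_config(seed = 12), days = 5)
  rts <- probe_block(tr, "S01", 5, "sequence_probe")$rt_ms
  out3 <- preprocess_probe(rts)
  expect_length(out3, length(rts) - 32)
  expect_lt(abs(mean(out3)), 1e-9)
})

test_that("preprocessing imputes missing values and flags heavy missingness", {
  x <- rnorm(200, 400, 20)
  x[c(50, 90, 130)] <- NA
  out <- preprocess_probe(x)
  expect_false(any(is.na(out)))
  expect_equal(attr(out, "prop_missing"), 3 / 168)
  x2 <- x; x2[40:160] <- NA
  expect_warning(preprocess_probe(x2), "50%")
})

test_that("acf31 equals the brute-force double-loop oracle", {
  set.seed(1)
  for (n in c(80, 257, 500)) {
    x <- rnorm(n)
    x <- x - mean(x)
    expect_equal(acf31(x)$rho, acf_bruteforce(x, 31), tolerance = 1e-12)
  }
})

test_that("acf31 matches the AR(1) closed form and sign patterns", {
  y <- as.numeric(simulate_binding(
    binding_config(0.75, sigma_p_ms = 10, sigma_e_ms = 10,
                   n_blocks = 1, n_trials = 1e5, seed = 2)))
  prof <- acf31(y - mean(y))
  # 3 Monte-Carlo SEs at n = 1e5 is ~0.013
  expect_lt(abs(prof$rho[1] - 0.5217), 0.015)
  expect_lt(abs(prof$rho[2] - 0.3913), 0.015)
  # white noise: all small
  z <- rnorm(1e4)
  expect_true(all(abs(acf31(z - mean(z))$rho) < 0.05))
  # alternating series: negative odd lags, positive even lags
  alt <- rep(c(-1, 1), 100) + rnorm(200, 0, 0.01)
  pa <- acf31(alt - mean(alt))$rho
  expect_lt(pa[1], 0)
  expect_gt(pa[2], 0)
  expect_error(acf31(rep(0, 100)), "zero-variance")
})

test_that("build_null takes across-subject mean and SD per lag", {
  p1 <- structure(list(rho = rep(0.1, 31), n_trials_used = 224, n_lags = 31L),
                  class = "acf_profile")
  p2 <- structure(list(rho = rep(0.3, 31), n_trials_used = 224, n_lags = 31L),
                  class = "acf_profile")
  null <- build_null(list(p1, p2))
  expect_equal(null$mu, rep(0.2, 31))
  expect_equal(null$sigma, rep(sd(c(0.1, 0.3)), 31), tolerance = 1e-12)
  expect_equal(null$n_subjects, 2L)
  expect_warning(build_null(list(p1, p1)), "degenerate")
  expect_error(build_null(list(p1)), ">= 2")
  # 23 unbound synthetic subjects: null mean ~ 0 at every lag
  set.seed(3)
  profs <- lapply(1:23, function(i) { x <- rnorm(224); acf31(x - mean(x)) })
  n23 <- build_null(profs)
  expect_true(all(abs(n23$mu) < 3 * n23$sigma / sqrt(23)))
})

test_that("chunk size counts consecutive significant positive lags from lag 1", {
  null <- structure(list(mu = rep(0, 31), sigma = rep(0.05, 31),
                         n_subjects = 23L), class = "acf_null")
  mk <- function(rho) structure(list(rho = rho, n_trials_used = 224,
                                     n_lags = 31L), class = "acf_profile")
  # rho == mu: size 0
  expect_equal(chunk_size(mk(rep(0, 31)), null)$size, 0L)
  # strong first 4 lags then nothing
  rho <- rep(0, 31); rho[1:4] <- c(0.5, 0.4, 0.3, 0.25)
  expect_equal(chunk_size(mk(rho), null)$size, 4L)
  # a gap breaks the run even if later lags are significant
  rho2 <- rho; rho2[3] <- 0; rho2[5] <- 0.5
  expect_equal(chunk_size(mk(rho2), null)$size, 2L)
  # negative autocorrelation is not binding, however extreme
  rho3 <- rep(0, 31); rho3[1] <- -0.9
  expect_equal(chunk_size(mk(rho3), null)$size, 0L)
  # monotone in effect size: inflating every rho never shrinks the estimate
  set.seed(4)
  base <- pmax(rnorm(31, 0.1, 0.1), 0)
  s1 <- chunk_size(mk(base), null)$size
  s2 <- chunk_size(mk(base + 0.1), null)$size
  expect_gte(s2, s1)
  # degenerate null
  null0 <- structure(list(mu = rep(0, 31), sigma = rep(0, 31),
                          n_subjects = 23L), class = "acf_null")
  expect_error(chunk_size(mk(rho), null0), "degenerate")
})

test_that("family-wise false-positive rate under the exchangeable null <= alpha", {
  set.seed(5)
  hits <- replicate(200, {
    profs <- lapply(1:24, function(i) { x <- rnorm(224); acf31(x - mean(x)) })
    null <- build_null(profs[1:23])
    chunk_size(profs[[24]], null)$size >= 1
  })
  expect_lte(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("day-1 generator profiles give chunk size 0 almost always", {
  set.seed(6)
  # day 1 has binding alpha ~ 0; null from the same cohort's random probes
  cfgs <- lapply(1:12, function(i)
    subject_config(subject = sprintf("S%02d", i), seed = 700 + i))
  tr <- simulate_cohort(cfgs, days = 1)
  ct <- chunk_table(tr)
  expect_gte(mean(ct$chunks$chunk_size == 0), 0.9)
})

test_that("a planted binding span is recovered as the modal estimate", {
  # choose alpha from the closed form so the theoretical ACF crosses the
  # Bonferroni-corrected threshold between lag 7 and lag 8
  nt <- 1000L; ns <- 23L
  thr <- qt(1 - 0.05 / 31 / 2, ns - 1) / sqrt(nt)
  alpha_pl <- exp(log(thr) / 7.5)
  expect_gt(theoretical_acf(alpha_pl, 10, 0, 7), thr)
  expect_lt(theoretical_acf(alpha_pl, 10, 0, 8), thr)
  sizes <- sapply(1:20, function(s) {
    nulls <- lapply(1:ns, function(i) {
      y <- as.numeric(simulate_binding(binding_config(
        0, sigma_e_ms = 10, n_blocks = 1, n_trials = nt, seed = s * 1000 + i)))
      acf31(y - mean(y))
    })
    pr <- binding_acf(simulate_binding(binding_config(
      alpha_pl, sigma_e_ms = 0, n_blocks = 100, n_trials = nt, seed = s)))
    prof <- structure(list(rho = pr$mean_rho, n_trials_used = nt,
                           n_lags = 31L), class = "acf_profile")
    chunk_size(prof, build_null(nulls))$size
  })
  tab <- table(sizes)
  expect_equal(as.integer(names(tab)[which.max(tab)]), 7L)
})
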