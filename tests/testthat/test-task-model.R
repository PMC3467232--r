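test_that("canonical sequence has the fixed 32-item structure", {
  sq <- canonical_sequence()
  expect_length(sq$items, 32)
  expect_identical(sq$items[1], 6L)
  expect_identical(sq$items[32], 7L)
  expect_true(all(sq$items %in% 1:8))
  expect_true(all(table(sq$items) == 4))   # every key four times per cycle
  expect_identical(sq$repeats_per_block, 8L)
})

test_that("adaptive window follows mu + sd with 200 ms and accuracy resets", {
  expect_equal(adaptive_window(300, 50, 0.90), 350)
  expect_equal(adaptive_window(150, 40, 0.90), 600)   # 190 < 200 ms
  expect_equal(adaptive_window(300, 50, 0.70), 600)   # accuracy < 75%
  expect_equal(adaptive_window(160, 40, 0.90), 200)   # exactly at the floor: no reset
  expect_error(adaptive_window(NA, 10, 0.9), "finite")
  expect_error(adaptive_window(300, 50, 1.2), "accuracy")
})

test_that("session schedule is 2 random, 5 adaptive sequence, 2 fixed probes", {
  s <- build_session(1)
  expect_equal(nrow(s), 9)
  expect_equal(s$block_type,
               c(rep("random_train", 2), rep("sequence_train", 5),
                 "random_probe", "sequence_probe"))
  expect_true(all(s$n_trials == 256))
  expect_equal(s$window_policy[s$block_type == "sequence_train"],
               rep("adaptive", 5))
  expect_equal(s$window_policy[8:9], rep("fixed_600", 2))
  expect_error(build_session(11))
})

test_that("sequence blocks are circular rotations of the canonical sequence", {
  sq <- canonical_sequence()
  set.seed(5)
  for (i in 1:5) {
    cues <- srtbind:::sequence_cues()
    expect_length(cues, 256)
    # every aligned 32-trial window is some rotation of the sequence
    first <- cues[1:32]
    rotations <- sapply(1:32, function(o)
      all(first == sq$items[((1:32 + o - 2) %% 32) + 1]))
    expect_equal(sum(rotations), 1)
    expect_identical(cues, rep(first, 8))
  }
})

test_that("questionnaire scoring follows the four-question decision tree", {
  expect_identical(score_questionnaire(FALSE), 0L)
  expect_identical(score_questionnaire(TRUE, c("weird", "colors")), 1L)
  expect_identical(score_questionnaire(TRUE, "pattern", q3_always_present = TRUE), 2L)
  expect_identical(score_questionnaire(TRUE, "order", q3_always_present = FALSE,
                                       q4_reproduced_4_items = TRUE), 3L)
  expect_identical(score_questionnaire(TRUE, "Sequence", q3_always_present = FALSE,
                                       q4_reproduced_4_items = FALSE), 2L)
})

test_that("generator is deterministic given the seed", {
  cfg <- quick_config(seed = 11)
  t1 <- simulate_subject(cfg, days = 3)
  t2 <- simulate_subject(cfg, days = 3)
  expect_identical(t1, t2)
})

test_that("generator censors RTs at the block response window", {
  tr <- simulate_subject(quick_config(seed = 2), days = c(1, 5))
  ok <- !is.na(tr$rt_ms)
  expect_true(all(tr$rt_ms[ok] <= tr$response_window_ms[ok]))
  expect_true(all(!tr$correct[!ok]))   # missing RT is never correct
  expect_true(all(tr$pressed_key[tr$correct] == tr$cue_key[tr$correct]))
})

test_that("noiseless, unbound generator reproduces the mean structure exactly", {
  cfg <- subject_config(base_rt_ms = 400, rt_learning_slope_ms_per_day = 9,
                        key_bias_ms = seq(-14, 14, by = 4),
                        binding_alpha_by_day = rep(0, 10),
                        binding_sd_ms = 0, motor_sd_ms = 0,
                        pes_state_delay_ms = 0,
                        error_rate_by_day = rep(0, 10), seed = 3)
  tr <- simulate_subject(cfg, days = 4)
  sp <- tr[tr$block_type == "sequence_probe", ]
  expect_equal(sp$rt_ms, 400 - 9 * 4 + cfg$key_bias_ms[sp$cue_key],
               tolerance = 1e-12)
  rp <- tr[tr$block_type == "random_probe", ]
  expect_equal(rp$rt_ms, 400 + cfg$key_bias_ms[rp$cue_key], tolerance = 1e-12)
})

test_that("unbound subject shows no lag-1 autocorrelation; bound subject does", {
  cfg0 <- subject_config(binding_alpha_by_day = rep(0, 10),
                         pes_state_delay_ms = 0,
                         error_rate_by_day = rep(0.05, 10), seed = 21)
  tr0 <- simulate_subject(cfg0, days = 10)
  x0 <- preprocess_probe(probe_block(tr0, "S01", 10, "sequence_probe")$rt_ms)
  r0 <- acf31(x0)$rho[1]
  expect_lt(abs(r0), 3 / sqrt(length(x0)))

  # day-10 binding at 0.75 lifts lag-1 autocorrelation well above day 1
  lag1 <- sapply(1:12, function(s) {
    cfg <- subject_config(binding_alpha_by_day = c(0, rep(0.75, 9)), seed = 300 + s)
    tr <- simulate_subject(cfg, days = c(1, 10))
    c(d1 = acf31(preprocess_probe(probe_block(tr, "S01", 1, "sequence_probe")$rt_ms))$rho[1],
      d10 = acf31(preprocess_probe(probe_block(tr, "S01", 10, "sequence_probe")$rt_ms))$rho[1])
  })
  expect_gt(mean(lag1["d10", ] - lag1["d1", ]), 0.2)
  expect_true(t.test(lag1["d10", ], lag1["d1", ], paired = TRUE)$p.value < 0.01)
})

test_that("trial tables round-trip losslessly through the writer/reader", {
  tr <- simulate_subject(quick_config(seed = 4), days = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  rownames(tr) <- rownames(back) <- NULL
  expect_equal(back, tr, tolerance = 1e-12)
  expect_true(any(is.na(back$rt_ms)) == any(is.na(tr$rt_ms)))
})
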