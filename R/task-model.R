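#' Canonical 32-item bimanual SRT sequence
#'
#' The fixed cue sequence used in the multi-day bimanual serial reaction time
#' task. Keys are numbered 1-8 from left pinky (1) to right pinky (8), thumbs
#' excluded. Each of the eight keys occurs exactly four times per cycle, and a
#' sequence training block cycles the list eight times (256 trials).
#'
#' @return An object of class `sequence_spec`: a list with `items` (integer
#'   vector of length 32, values 1-8) and `repeats_per_block` (8).
#' @examples
#' sq <- canonical_sequence()
#' length(sq$items)          # 32
#' table(sq$items)           # each key four times
#' @export
canonical_sequence <- function() {
  items <- c(6L, 8L, 5L, 6L, 3L, 5L, 4L, 1L, 3L, 6L, 8L, 4L, 1L, 2L, 7L, 3L,
             1L, 8L, 2L, 7L, 5L, 2L, 4L, 5L, 7L, 3L, 1L, 6L, 8L, 2L, 4L, 7L)
  structure(list(items = items, repeats_per_block = 8L),
            class = "sequence_spec")
}

#' Adaptive maximum response window
#'
#' During the five training sequence blocks the maximum response time for a
#' block is set from the previous block's performance as `mu + sd`. If that
#' value falls below 200 ms, or the previous block's accuracy falls below 75%
#' correct, the window is reset to the 600 ms default.
#'
#' @param prev_mean_rt_ms Mean reaction time of the previous block (ms).
#' @param prev_sd_rt_ms Standard deviation of previous-block RTs (ms, >= 0).
#' @param prev_accuracy Proportion correct on the previous block, in \[0, 1\].
#' @return The maximum response window for the next block, in ms.
#' @examples
#' adaptive_window(300, 50, 0.90)  # 350
#' adaptive_window(150, 40, 0.90)  # 600 (190 < 200 ms floor)
#' adaptive_window(300, 50, 0.70)  # 600 (accuracy below 75%)
#' @export
adaptive_window <- function(prev_mean_rt_ms, prev_sd_rt_ms, prev_accuracy) {
  if (!all(is.finite(c(prev_mean_rt_ms, prev_sd_rt_ms, prev_accuracy))))
    stop("adaptive_window: inputs must be finite")
  if (prev_sd_rt_ms < 0) stop("adaptive_window: sd must be >= 0")
  if (prev_accuracy < 0 || prev_accuracy > 1)
    stop("adaptive_window: accuracy must be in [0, 1]")
  w <- prev_mean_rt_ms + prev_sd_rt_ms
  if (w < 200 || prev_accuracy < 0.75) 600 else w
}

#' Daily session schedule
#'
#' One training day comprises nine 256-trial blocks in fixed order: two random
#' training blocks, five adaptive sequence training blocks, then a random probe
#' and a sequence probe, both at the fixed 600 ms window. All analyses restrict
#' to the two probe blocks.
#'
#' @param day Training day, 1-10 (recorded in the schedule; the block layout is
#'   identical on every day).
#' @return A data.frame with one row per block: `block_index`, `block_type`
#'   (`random_train`, `sequence_train`, `random_probe`, `sequence_probe`),
#'   `n_trials`, and `window_policy` (`fixed_600` or `adaptive`).
#' @export
build_session <- function(day) {
  if (!(is.numeric(day) && length(day) == 1L && day >= 1 && day <= 10))
    stop("build_session: day must be a single value in 1..10")
  types <- c(rep("random_train", 2), rep("sequence_train", 5),
             "random_probe", "sequence_probe")
  data.frame(
    day = as.integer(day),
    block_index = 1:9,
    block_type = types,
    n_trials = 256L,
    window_policy = ifelse(types == "sequence_train", "adaptive", "fixed_600"),
    stringsAsFactors = FALSE
  )
}

#' Post-session awareness questionnaire score
#'
#' Scores the four-question verbal questionnaire given after each training day
#' to probe explicit awareness of the sequence. Score 0: subject noticed
#' nothing different about the stimuli. Score 1: noticed something but did not
#' describe it with any of the keywords "pattern", "sequence", "sequential",
#' "order", "ordering". Score 2: used a keyword and reported the pattern as
#' always present (the implicit-to-explicit threshold). Score 3: used a
#' keyword, reported the pattern as only occasionally present, and could
#' reproduce at least four consecutive sequence items.
#'
#' @param q1_different Did any stimuli appear different? (logical)
#' @param q2_keywords Character vector of words the subject used to describe
#'   the difference.
#' @param q3_always_present Was the pattern reported as always present?
#' @param q4_reproduced_4_items Could the subject reproduce 4 consecutive
#'   items?
#' @return Integer score 0-3.
#' @export
score_questionnaire <- function(q1_different, q2_keywords = character(),
                                q3_always_present = FALSE,
                                q4_reproduced_4_items = FALSE) {
  if (!isTRUE(q1_different)) return(0L)
  keywords <- c("pattern", "sequence", "sequential", "order", "ordering")
  if (!any(tolower(q2_keywords) %in% keywords)) return(1L)
  if (isTRUE(q3_always_present)) return(2L)
  if (isTRUE(q4_reproduced_4_items)) 3L else 2L
}

#' Generative parameters for one synthetic subject
#'
#' Bundles the per-subject parameters of the synthetic cohort generator. The
#' generator is a stand-in for raw data: it reproduces the statistical
#' structure the analysis stages assume (day-linear sequence-specific RT
#' improvement, quadratic-saturating accuracy, growing AR(1) response binding,
#' post-error slowing, per-key biases, response-window censoring), not any real
#' subject.
#'
#' @param base_rt_ms Mean RT at day 0, before sequence learning (ms).
#' @param rt_learning_slope_ms_per_day Sequence-specific improvement per day
#'   (ms/day); applied to sequence blocks only, so random-probe RTs stay flat.
#' @param key_bias_ms Length-8 vector of per-key RT offsets (ms).
#' @param binding_alpha_by_day Length-10 vector in \[0, 1): AR(1) coupling of
#'   successive response plans in sequence blocks on each day (0 in random
#'   blocks). Non-decreasing for a learner.
#' @param binding_sd_ms Innovation SD of the latent plan process (ms).
#' @param motor_sd_ms SD of trial-wise motor/execution noise (ms).
#' @param pes_state_delay_ms Post-error slowing injected into the latent state
#'   at the end of training (ms at lag 1 on day 10); ramps linearly with day
#'   and applies in sequence blocks only.
#' @param pes_decay_lags Number of post-error trials over which the injected
#'   delay decays geometrically (factor 1/2 per lag).
#' @param error_rate_by_day Length-10 vector of per-trial error probabilities,
#'   non-increasing (quadratic-saturating decline by default).
#' @param seed Integer seed making the subject's simulation deterministic.
#' @return An object of class `subject_config` (a validated list).
#' @export
subject_config <- function(base_rt_ms = 400,
                           rt_learning_slope_ms_per_day = 9,
                           key_bias_ms = rep(0, 8),
                           binding_alpha_by_day = 0.75 * (1 - exp(-(0:9) / 2.2)),
                           binding_sd_ms = 15,
                           motor_sd_ms = 20,
                           pes_state_delay_ms = 15,
                           pes_decay_lags = 4L,
                           error_rate_by_day = 0.045 + 0.28 * ((10 - (1:10)) / 9)^2,
                           seed = 1L,
                           subject = "S01") {
  cfg <- list(subject = as.character(subject),
              base_rt_ms = base_rt_ms,
              rt_learning_slope_ms_per_day = rt_learning_slope_ms_per_day,
              key_bias_ms = as.numeric(key_bias_ms),
              binding_alpha_by_day = as.numeric(binding_alpha_by_day),
              binding_sd_ms = binding_sd_ms,
              motor_sd_ms = motor_sd_ms,
              pes_state_delay_ms = pes_state_delay_ms,
              pes_decay_lags = as.integer(pes_decay_lags),
              error_rate_by_day = as.numeric(error_rate_by_day),
              seed = as.integer(seed))
  validate_subject_config(cfg)
  structure(cfg, class = "subject_config")
}

validate_subject_config <- function(cfg) {
  stopifnot(length(cfg$key_bias_ms) == 8,
            length(cfg$binding_alpha_by_day) == 10,
            length(cfg$error_rate_by_day) == 10,
            all(cfg$binding_alpha_by_day >= 0),
            all(cfg$binding_alpha_by_day < 1),
            all(cfg$error_rate_by_day >= 0),
            all(cfg$error_rate_by_day <= 1),
            cfg$binding_sd_ms >= 0, cfg$motor_sd_ms >= 0,
            cfg$pes_decay_lags >= 0)
  if (any(diff(cfg$error_rate_by_day) > 1e-12))
    stop("subject_config: error_rate_by_day must be non-increasing")
  invisible(cfg)
}

# Pseudo-random cue stream with no immediate repeats, mimicking the task's
# random condition.
random_cues <- function(n) {
  cues <- integer(n)
  cues[1] <- sample.int(8L, 1L)
  for (t in 2:n) cues[t] <- sample((1:8)[-cues[t - 1]], 1L)
  cues
}

# Cue stream for a sequence block: circular rotation from a random start
# offset, cycled repeats_per_block times. The sequence itself is never
# re-ordered.
sequence_cues <- function(spec = canonical_sequence(), offset = NULL) {
  k <- length(spec$items)
  if (is.null(offset)) offset <- sample.int(k, 1L)
  rotated <- spec$items[((seq_len(k) + offset - 2L) %% k) + 1L]
  rep(rotated, spec$repeats_per_block)
}

# Simulate one block. Latent plan = day/key-dependent mean + AR(1) deviation
# (stationary init) + post-error delay; observed RT = plan + motor noise,
# censored to missing above the response window.
simulate_block <- function(cfg, day, block_type, window_ms, n_trials = 256L) {
  is_seq <- block_type %in% c("sequence_train", "sequence_probe")
  cues <- if (is_seq) sequence_cues() else random_cues(n_trials)
  n <- length(cues)

  alpha <- if (is_seq) cfg$binding_alpha_by_day[day] else 0
  day_mean <- if (is_seq)
    cfg$base_rt_ms - cfg$rt_learning_slope_ms_per_day * day
  else cfg$base_rt_ms
  mu <- day_mean + cfg$key_bias_ms[cues]

  innov <- stats::rnorm(n, 0, cfg$binding_sd_ms)
  if (alpha > 0) {
    dev <- as.numeric(stats::filter(innov, alpha, method = "recursive",
                                    init = stats::rnorm(1, 0, cfg$binding_sd_ms /
                                                          sqrt(1 - alpha^2))))
  } else {
    dev <- innov
  }

  err <- stats::rbinom(n, 1L, cfg$error_rate_by_day[day]) == 1L

  # post-error slowing: delay injected into the latent plan of the following
  # pes_decay_lags trials, halving per lag; sequence blocks only, amplitude
  # ramping linearly across days up to pes_state_delay_ms on the final day
  pes <- numeric(n)
  pes_amp <- if (is_seq) cfg$pes_state_delay_ms * day / 10 else 0
  if (pes_amp != 0 && cfg$pes_decay_lags > 0 && any(err)) {
    for (lag in seq_len(cfg$pes_decay_lags)) {
      idx <- which(err) + lag
      idx <- idx[idx <= n]
      pes[idx] <- pes[idx] + pes_amp * 0.5^(lag - 1)
    }
  }

  latent <- mu + dev + pes
  y <- latent + stats::rnorm(n, 0, cfg$motor_sd_ms)
  censored <- y > window_ms

  pressed <- cues
  if (any(err)) {
    pressed[err] <- vapply(cues[err],
                           function(k) sample((1:8)[-k], 1L), integer(1))
  }
  rt <- ifelse(censored, NA_real_, y)
  correct <- !err & !censored

  data.frame(
    subject = cfg$subject,
    day = as.integer(day),
    block_type = block_type,
    trial_index = seq_len(n),
    cue_key = cues,
    pressed_key = pressed,
    rt_ms = rt,
    correct = correct,
    response_window_ms = window_ms,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full 10-day synthetic subject
#'
#' Runs one subject through the canonical schedule (nine 256-trial blocks per
#' day for 10 days), with adaptive response windows on the five sequence
#' training blocks and fixed 600 ms windows elsewhere. Deterministic given the
#' config seed.
#'
#' @param cfg A [subject_config()].
#' @param days Days to simulate (default 1:10).
#' @return A data.frame of trials with columns `subject`, `day`, `block_index`,
#'   `block_type`, `trial_index`, `cue_key`, `pressed_key`, `rt_ms` (NA when
#'   the response exceeded the window), `correct`, `response_window_ms`.
#' @seealso [simulate_cohort()], [build_session()]
#' @export
simulate_subject <- function(cfg, days = 1:10) {
  validate_subject_config(cfg)
  set.seed(cfg$seed)
  out <- vector("list", length(days) * 9L)
  i <- 0L
  for (day in days) {
    sched <- build_session(day)
    prev <- NULL   # previous block's rt stats for the adaptive window
    for (b in seq_len(nrow(sched))) {
      wp <- sched$window_policy[b]
      window <- if (wp == "adaptive" && !is.null(prev))
        adaptive_window(prev$mean, prev$sd, prev$acc) else 600
      blk <- simulate_block(cfg, day, sched$block_type[b], window,
                            sched$n_trials[b])
      blk$block_index <- sched$block_index[b]
      ok <- !is.na(blk$rt_ms)
      prev <- list(mean = if (any(ok)) mean(blk$rt_ms[ok]) else 600,
                   sd = if (sum(ok) > 1) stats::sd(blk$rt_ms[ok]) else 0,
                   acc = mean(blk$correct))
      i <- i + 1L
      out[[i]] <- blk
    }
  }
  res <- do.call(rbind, out)
  res[, c("subject", "day", "block_index", "block_type", "trial_index",
          "cue_key", "pressed_key", "rt_ms", "correct", "response_window_ms")]
}

#' Generate a default synthetic cohort configuration
#'
#' Draws per-subject generative parameters around the cohort-level defaults of
#' [subject_config()]: baseline RT, learning slope, key biases and noise SDs
#' vary across subjects; binding and error-rate schedules keep their canonical
#' shapes. 23 subjects matches the study-scale cohort.
#'
#' @param n_subjects Number of subjects (default 23).
#' @param seed Cohort-level seed; per-subject seeds are derived from it.
#' @return A list of `subject_config` objects.
#' @export
cohort_config <- function(n_subjects = 23L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    subject_config(
      subject = sprintf("S%02d", i),
      base_rt_ms = stats::rnorm(1, 400, 25),
      rt_learning_slope_ms_per_day = pmax(stats::rnorm(1, 9, 2.5), 1),
      key_bias_ms = stats::rnorm(8, 0, 8),
      binding_sd_ms = stats::runif(1, 12, 18),
      motor_sd_ms = stats::runif(1, 16, 24),
      pes_state_delay_ms = pmax(stats::rnorm(1, 15, 3), 2),
      seed = (seed * 1000L + i) %% .Machine$integer.max
    )
  })
}

#' Simulate a cohort of synthetic subjects
#'
#' @param configs List of [subject_config()] objects, e.g. from
#'   [cohort_config()].
#' @param days Days to simulate (default 1:10).
#' @return A single trial data.frame (rbind of [simulate_subject()] outputs).
#' @export
simulate_cohort <- function(configs, days = 1:10) {
  do.call(rbind, lapply(configs, simulate_subject, days = days))
}
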