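#' Read and write trial tables
#'
#' Trial tables are plain CSV, one row per cued keypress, with columns
#' `subject`, `day`, `block_index`, `block_type`, `trial_index`, `cue_key`,
#' `pressed_key`, `rt_ms`, `correct`, `response_window_ms`. Missing reaction
#' times (responses outside the window) are written as empty fields; trial
#' indices are 1-based within block. `read_trials()` validates every row and
#' reports offending row numbers.
#'
#' @param path File path.
#' @return `read_trials()` returns the validated trial data.frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject = "character"))
  needed <- c("subject", "day", "block_index", "block_type", "trial_index",
              "cue_key", "pressed_key", "rt_ms", "correct",
              "response_window_ms")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("read_trials: missing columns: ", paste(missing_cols, collapse = ", "))
  df$rt_ms <- as.numeric(df$rt_ms)
  df$correct <- as.logical(df$correct)
  df$pressed_key <- as.integer(df$pressed_key)
  validate_trials(df)
  df[, needed]
}

#' @rdname read_trials
#' @param trials Trial data.frame (as produced by [simulate_subject()] or
#'   [simulate_cohort()]).
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

block_types <- c("random_train", "sequence_train", "random_probe",
                 "sequence_probe")

validate_trials <- function(df) {
  bad_row <- function(cond, msg) {
    if (any(cond, na.rm = TRUE))
      stop("trial table validation: ", msg, " (rows ",
           paste(utils::head(which(cond), 5), collapse = ", "), ")")
  }
  bad_row(!(df$block_type %in% block_types), "unknown block_type")
  bad_row(!(df$cue_key %in% 1:8), "cue_key out of range 1..8")
  bad_row(!(is.na(df$pressed_key) | df$pressed_key %in% 1:8),
          "pressed_key out of range 1..8")
  bad_row(!is.na(df$rt_ms) & df$rt_ms <= 0, "non-positive rt_ms")
  bad_row(is.na(df$rt_ms) & df$correct, "missing rt_ms on a correct trial")
  bad_row(!is.na(df$rt_ms) & df$rt_ms > df$response_window_ms & df$correct,
          "rt_ms above response window on a correct trial")
  bad_row(df$correct & df$pressed_key != df$cue_key,
          "correct trial with pressed_key != cue_key")
  invisible(df)
}

#' Extract one probe block from a trial table
#'
#' All analyses restrict to the two daily probe blocks; this selects one of
#' them for a given subject and day.
#'
#' @param trials Trial data.frame.
#' @param subject Subject identifier.
#' @param day Training day.
#' @param type `"sequence_probe"` (default) or `"random_probe"`.
#' @return The block's rows of `trials`.
#' @export
probe_block <- function(trials, subject, day,
                        type = c("sequence_probe", "random_probe")) {
  type <- match.arg(type)
  trials[trials$subject == subject & trials$day == day &
           trials$block_type == type, , drop = FALSE]
}
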