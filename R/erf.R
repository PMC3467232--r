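#' Error response function (post-error slowing profile)
#'
#' Measures how an error on one trial perturbs the following responses: for
#' every error at position t, trials t+1 .. t+`n_lags` contribute their RT
#' deviation from the block mean to the corresponding lag; the ERF is the
#' per-lag mean over all contributions. Windows are truncated at the block
#' end. Every error opens its own window, so a trial may contribute to several
#' windows at different lags. Trials that are themselves errors still open
#' windows but contribute no RT value at any lag (their RTs reflect a
#' different event class), and missing RTs contribute nothing.
#'
#' @param rts RT vector (ms), NA = missing.
#' @param is_error Logical vector, same length, TRUE on error trials.
#' @param block_mean_ms Block mean RT used as the deviation baseline (default:
#'   mean of the non-missing, non-error RTs).
#' @param n_lags Number of post-error lags (default 6).
#' @return An object of class `erf` (list with `lag_means_ms`, `n_contributions`,
#'   `n_errors_used`, `block_mean_ms`), or `NULL` when the block contains no
#'   errors (an absent ERF, not a zero one).
#' @export
error_response_function <- function(rts, is_error,
                                    block_mean_ms = NULL, n_lags = 6L) {
  if (length(rts) != length(is_error))
    stop("error_response_function: rts and is_error differ in length")
  if (n_lags < 1) stop("error_response_function: n_lags must be >= 1")
  err_idx <- which(is_error)
  if (!length(err_idx)) return(NULL)
  if (is.null(block_mean_ms)) {
    usable <- !is.na(rts) & !is_error
    if (!any(usable)) stop("error_response_function: no usable RTs for block mean")
    block_mean_ms <- mean(rts[usable])
  }
  n <- length(rts)
  sums <- numeric(n_lags)
  counts <- integer(n_lags)
  for (lag in seq_len(n_lags)) {
    idx <- err_idx + lag
    idx <- idx[idx <= n]
    idx <- idx[!is_error[idx] & !is.na(rts[idx])]
    counts[lag] <- length(idx)
    sums[lag] <- sum(rts[idx] - block_mean_ms)
  }
  lag_means <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(lag_means_ms = lag_means, n_contributions = counts,
                 n_errors_used = length(err_idx),
                 block_mean_ms = block_mean_ms),
            class = "erf")
}

#' Post-error slowing magnitude
#'
#' The lag-1 value of the error response function: the mean RT deviation on
#' the trial immediately after an error.
#'
#' @param erf An `erf` object from [error_response_function()].
#' @return PES magnitude in ms.
#' @export
pes_magnitude <- function(erf) {
  if (is.null(erf)) stop("pes_magnitude: ERF is absent (no errors in block)")
  if (is.na(erf$lag_means_ms[1]))
    stop("pes_magnitude: ERF undefined at lag 1")
  erf$lag_means_ms[1]
}

#' @export
print.erf <- function(x, ...) {
  cat("Error response function (", x$n_errors_used, " errors)\n", sep = "")
  print(round(stats::setNames(x$lag_means_ms,
                              paste0("lag", seq_along(x$lag_means_ms))), 2))
  invisible(x)
}

#' Per subject/day/block-type ERF table
#'
#' Applies [error_response_function()] to each probe block of a trial table.
#'
#' @param trials Trial data.frame.
#' @param n_lags Post-error lags (default 6).
#' @return Long data.frame: `subject`, `day`, `block_type`, `lag`, `mean_ms`,
#'   `n_contributions`, `n_errors`. Blocks without errors are omitted.
#' @export
erf_table <- function(trials, n_lags = 6L) {
  probes <- trials[trials$block_type %in% c("random_probe", "sequence_probe"), ]
  keys <- unique(probes[, c("subject", "day", "block_type")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    blk <- probes[probes$subject == keys$subject[i] &
                    probes$day == keys$day[i] &
                    probes$block_type == keys$block_type[i], ]
    e <- error_response_function(blk$rt_ms, !blk$correct, n_lags = n_lags)
    if (is.null(e)) return(NULL)
    data.frame(subject = keys$subject[i], day = keys$day[i],
               block_type = keys$block_type[i], lag = seq_len(n_lags),
               mean_ms = e$lag_means_ms, n_contributions = e$n_contributions,
               n_errors = e$n_errors_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
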