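#' Preprocess a probe-block RT series for autocorrelation analysis
#'
#' Drops the first 32 trials (the first sequence cycle, which often shows an
#' exponential warm-up on later days), replaces missing RTs with the mean of
#' the retained non-missing trials, removes the linear trend over trial index
#' by OLS, and zero-means the result.
#'
#' @param rts RT vector (ms); NA marks a missing (censored) response.
#' @param missing_mask Optional logical vector marking missing trials
#'   (defaults to `is.na(rts)`).
#' @param n_warmup Leading trials to drop (default 32, one sequence cycle).
#' @return Zero-mean detrended numeric vector of length `length(rts) - n_warmup`,
#'   with attribute `prop_missing`. Warns (and proceeds) when more than half
#'   of the retained trials are missing.
#' @export
preprocess_probe <- function(rts, missing_mask = is.na(rts), n_warmup = 32L) {
  if (length(rts) != length(missing_mask))
    stop("preprocess_probe: rts and missing_mask differ in length")
  if (length(rts) < 2 * n_warmup)
    stop("preprocess_probe: need at least ", 2 * n_warmup, " trials")
  x <- rts[-seq_len(n_warmup)]
  miss <- missing_mask[-seq_len(n_warmup)] | is.na(x)
  prop_missing <- mean(miss)
  if (prop_missing > 0.5)
    warning("preprocess_probe: more than 50% of retained trials missing")
  if (all(miss)) stop("preprocess_probe: all retained trials missing")
  x[miss] <- mean(x[!miss])
  t_idx <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, t_idx), x)
  out <- as.numeric(fit$residuals)   # OLS residuals are exactly zero-mean
  attr(out, "prop_missing") <- prop_missing
  out
}

#' Inter-trial autocorrelation at lags 1-31
#'
#' Autocorrelation of a detrended, zero-mean probe series across one full
#' sequence length (31 lags), using the biased (1/n) autocovariance estimator,
#' which guarantees |rho| <= 1.
#'
#' @param detrended Zero-mean numeric vector (from [preprocess_probe()]).
#' @param n_lags Number of lags (default 31, the sequence length minus one).
#' @return An object of class `acf_profile`: list with `rho` (length
#'   `n_lags`), `n_trials_used`, `n_lags`.
#' @export
acf31 <- function(detrended, n_lags = 31L) {
  n <- length(detrended)
  if (n <= 2 * n_lags)
    stop("acf31: series too short for ", n_lags, " lags")
  x <- detrended - mean(detrended)
  c0 <- sum(x^2) / n
  if (c0 == 0) stop("acf31: zero-variance series")
  rho <- vapply(seq_len(n_lags), function(l)
    sum(x[1:(n - l)] * x[(1 + l):n]) / n / c0, numeric(1))
  structure(list(rho = rho, n_trials_used = n, n_lags = as.integer(n_lags)),
            class = "acf_profile")
}

#' @export
print.acf_profile <- function(x, ...) {
  cat("Inter-trial autocorrelation (", x$n_lags, " lags, n = ",
      x$n_trials_used, ")\n", sep = "")
  print(round(stats::setNames(x$rho, paste0("lag", seq_len(x$n_lags))), 3))
  invisible(x)
}

#' @export
plot.acf_profile <- function(x, ...) {
  graphics::plot(seq_len(x$n_lags), x$rho, type = "h", xlab = "lag",
                 ylab = expression(rho), ...)
  graphics::abline(h = 0, lty = 2)
}

#' Cross-subject random-probe null for the chunk estimator
#'
#' The null distribution for the chunk-size test is built, per day, from the
#' random-probe autocorrelation profiles of all subjects: the across-subject
#' mean `mu(l)` and sample SD `sigma(l)` at each lag.
#'
#' @param random_probe_acfs List of `acf_profile` objects (one per subject,
#'   same day, random probe block).
#' @return An object of class `acf_null`: list with `mu`, `sigma` (length 31
#'   vectors) and `n_subjects`.
#' @export
build_null <- function(random_probe_acfs) {
  if (length(random_probe_acfs) < 2)
    stop("build_null: need >= 2 subjects")
  mat <- do.call(rbind, lapply(random_probe_acfs, function(a) a$rho))
  null <- structure(list(mu = colMeans(mat),
                         sigma = apply(mat, 2, stats::sd),
                         n_subjects = nrow(mat)),
                    class = "acf_null")
  if (any(null$sigma == 0))
    warning("build_null: zero across-subject SD at some lag (degenerate null)")
  null
}

#' Chunk-size estimate from an autocorrelation profile
#'
#' Tests the subject's sequence-probe autocorrelation at each lag against the
#' cross-subject random-probe null with a one-sample t statistic
#' `t(l) = (rho(l) - mu(l)) / sigma(l)` on `n_subjects - 1` degrees of
#' freedom, two-sided, Bonferroni-corrected for `n_comparisons` lags. The
#' chunk size is the number of consecutive significant lags starting at lag 1,
#' additionally requiring `rho(l) > mu(l)` (a negative autocorrelation is not
#' binding).
#'
#' @param seq_acf `acf_profile` of the subject's sequence probe.
#' @param null `acf_null` from [build_null()].
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_comparisons Bonferroni correction count (default 31 lags).
#' @param reference `"t"` (default; df = n_subjects - 1) or `"z"` for a
#'   normal reference.
#' @return An object of class `chunk_estimate`: list with `size`, `t_stats`,
#'   `significant` (logical vector), `alpha_corrected`, `reference`.
#' @export
chunk_size <- function(seq_acf, null, alpha = 0.05,
                       n_comparisons = seq_acf$n_lags,
                       reference = c("t", "z")) {
  reference <- match.arg(reference)
  if (null$n_subjects < 2) stop("chunk_size: null needs >= 2 subjects")
  if (any(null$sigma == 0)) stop("chunk_size: degenerate null (sigma = 0)")
  a_corr <- alpha / n_comparisons
  t_stats <- (seq_acf$rho - null$mu) / null$sigma
  p <- if (reference == "t")
    2 * stats::pt(-abs(t_stats), df = null$n_subjects - 1)
  else 2 * stats::pnorm(-abs(t_stats))
  sig <- (p < a_corr) & (seq_acf$rho > null$mu)
  size <- if (sig[1]) {
    runs <- rle(sig)
    runs$lengths[1]
  } else 0L
  structure(list(size = as.integer(size), t_stats = t_stats,
                 significant = sig, alpha_corrected = a_corr,
                 reference = reference),
            class = "chunk_estimate")
}

#' @export
print.chunk_estimate <- function(x, ...) {
  cat("Estimated chunk size:", x$size, "bound responses\n")
  cat(sprintf("  (%s reference, corrected alpha = %.3g)\n",
              x$reference, x$alpha_corrected))
  invisible(x)
}

#' Per subject/day autocorrelation and chunk-size tables
#'
#' Runs the full chunk-estimation pipeline on a trial table: per subject/day,
#' preprocess both probe blocks, compute 31-lag ACFs, build the day's
#' cross-subject random-probe null, and count consecutive significant lags in
#' each subject's sequence-probe profile.
#'
#' @param trials Trial data.frame (cohort).
#' @param alpha,n_comparisons,reference Passed to [chunk_size()].
#' @return List with `acf` (long data.frame: subject, day, block_type, lag,
#'   rho) and `chunks` (data.frame: subject, day, chunk_size).
#' @export
chunk_table <- function(trials, alpha = 0.05, n_comparisons = 31L,
                        reference = "t") {
  subjects <- unique(trials$subject)
  days <- sort(unique(trials$day))
  acf_rows <- list(); chunk_rows <- list()
  for (d in days) {
    profs <- lapply(subjects, function(s) {
      list(
        rand = acf31(preprocess_probe(probe_block(trials, s, d, "random_probe")$rt_ms)),
        seq = acf31(preprocess_probe(probe_block(trials, s, d, "sequence_probe")$rt_ms))
      )
    })
    null <- build_null(lapply(profs, `[[`, "rand"))
    for (i in seq_along(subjects)) {
      est <- chunk_size(profs[[i]]$seq, null, alpha = alpha,
                        n_comparisons = n_comparisons, reference = reference)
      chunk_rows[[length(chunk_rows) + 1L]] <-
        data.frame(subject = subjects[i], day = d, chunk_size = est$size,
                   stringsAsFactors = FALSE)
      for (bt in c("random_probe", "sequence_probe")) {
        rho <- if (bt == "random_probe") profs[[i]]$rand$rho else profs[[i]]$seq$rho
        acf_rows[[length(acf_rows) + 1L]] <-
          data.frame(subject = subjects[i], day = d, block_type = bt,
                     lag = seq_along(rho), rho = rho, stringsAsFactors = FALSE)
      }
    }
  }
  list(acf = do.call(rbind, acf_rows), chunks = do.call(rbind, chunk_rows))
}
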