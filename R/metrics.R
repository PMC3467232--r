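#' Sequence-specific response time (z units)
#'
#' Expresses sequence-probe speed relative to the same day's random-probe RT
#' distribution, controlling for generic (non-sequence-specific) speedup:
#' `(mean(random) - mean(sequence)) / sd(random)`. Positive values mean faster
#' responses in the sequence condition. Missing RTs are excluded from the
#' means and SD (no imputation here).
#'
#' @param random_probe_rts RTs from the random probe block (ms, NA = missing).
#' @param sequence_probe_rts RTs from the sequence probe block (ms).
#' @return Sequence-specific RT score in z units.
#' @export
sequence_specific_rt <- function(random_probe_rts, sequence_probe_rts) {
  r <- random_probe_rts[!is.na(random_probe_rts)]
  s <- sequence_probe_rts[!is.na(sequence_probe_rts)]
  if (length(r) < 2 || length(s) < 2)
    stop("sequence_specific_rt: need >= 2 non-missing RTs per block")
  sd_r <- stats::sd(r)
  if (sd_r == 0) stop("sequence_specific_rt: random-probe SD is zero")
  (mean(r) - mean(s)) / sd_r
}

#' Response time variability of a probe block
#'
#' Sample standard deviation of the non-missing probe RTs.
#'
#' @param probe_rts RTs (ms), NA = missing.
#' @return SD in ms.
#' @export
rt_variability <- function(probe_rts) {
  x <- probe_rts[!is.na(probe_rts)]
  if (length(x) < 2) stop("rt_variability: need >= 2 non-missing RTs")
  stats::sd(x)
}

#' Across-day learning rate with linear/quadratic model selection
#'
#' Fits `value ~ day` and `value ~ day + day^2` by OLS on the raw (1..10,
#' non-orthogonal) day basis and selects the quadratic model when a likelihood
#' ratio test (2 * (ll_quad - ll_lin) against chi-square, df = 1) is
#' significant at `alpha`. The learning-rate summary is `lambda = b` for the
#' linear model and `lambda = b + c` (linear plus quadratic coefficient) for
#' the quadratic model, so saturating learners are summarized by their net
#' coefficient sum.
#'
#' @param values Numeric vector, one value per day.
#' @param days Day codes (default `seq_along(values)`).
#' @param alpha Significance level of the likelihood-ratio test (per subject,
#'   uncorrected).
#' @return An object of class `learning_rate`: list with `lambda`, `model`
#'   (`"linear"` or `"quadratic"`), `beta_linear`, `beta_quadratic` (NA for
#'   the linear model), `lr_stat`, `lr_test_p`, and the two `lm` fits.
#' @examples
#' fit_learning_rate(0.1 + 0.5 * (1:10))           # linear, lambda = 0.5
#' @export
fit_learning_rate <- function(values, days = seq_along(values), alpha = 0.05) {
  if (length(values) < 4) stop("fit_learning_rate: need >= 4 days")
  if (length(values) != length(days)) stop("values and days differ in length")
  d <- data.frame(value = values, day = days)
  fit_lin <- stats::lm(value ~ day, data = d)
  fit_quad <- stats::lm(value ~ day + I(day^2), data = d)
  ll_lin <- as.numeric(stats::logLik(fit_lin))
  ll_quad <- as.numeric(stats::logLik(fit_quad))
  lr <- max(0, 2 * (ll_quad - ll_lin))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  # a (numerically) perfect linear fit cannot be improved: the LR statistic is
  # meaningless when the linear residuals are at machine-zero scale
  lin_perfect <- sum(stats::residuals(fit_lin)^2) <=
    1e-10 * max(1, sum(values^2))
  if (!lin_perfect && is.finite(p) && p < alpha) {
    model <- "quadratic"
    b <- unname(stats::coef(fit_quad)["day"])
    c2 <- unname(stats::coef(fit_quad)["I(day^2)"])
    lambda <- b + c2
  } else {
    model <- "linear"
    b <- unname(stats::coef(fit_lin)["day"])
    if (is.na(b)) b <- 0   # constant series: zero slope
    c2 <- NA_real_
    lambda <- b
  }
  structure(list(lambda = lambda, model = model, beta_linear = b,
                 beta_quadratic = c2, lr_stat = lr, lr_test_p = p,
                 fit_linear = fit_lin, fit_quadratic = fit_quad),
            class = "learning_rate")
}

#' @export
print.learning_rate <- function(x, ...) {
  cat("Across-day learning rate\n")
  cat(sprintf("  model: %s (LR test p = %.4g)\n", x$model, x$lr_test_p))
  cat(sprintf("  lambda = %.4g  (beta_linear = %.4g, beta_quadratic = %s)\n",
              x$lambda, x$beta_linear,
              ifelse(is.na(x$beta_quadratic), "-",
                     sprintf("%.4g", x$beta_quadratic))))
  invisible(x)
}

#' @export
coef.learning_rate <- function(object, ...) {
  c(lambda = object$lambda, beta_linear = object$beta_linear,
    beta_quadratic = object$beta_quadratic)
}

#' Median split of learning rates
#'
#' Labels subjects `"high"` when strictly above the median and `"low"`
#' otherwise (values at the median join the low group, so the split is
#' deterministic for odd n and ties).
#'
#' @param lambdas Numeric vector of per-subject learning rates.
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
median_split <- function(lambdas) {
  if (length(lambdas) < 2) stop("median_split: need >= 2 subjects")
  ifelse(lambdas > stats::median(lambdas), "high", "low")
}

#' Bootstrap correlation between daily RT variability and learning rate
#'
#' For each training day, correlates subjects' probe-block RT variability with
#' their across-day learning rates. Uncertainty comes from resampling subjects
#' with replacement `n_boot` times (the bootstrap SD is the error bar on r);
#' the significance flag tests r against 0 with the exact correlation t
#' reference (df = n - 2), Bonferroni-corrected for `n_comparisons` days, so
#' the family-wise false-positive rate stays at `alpha` under the null.
#'
#' @param per_day_sd Matrix, subjects x days, of probe RT variability (ms).
#' @param lambdas Per-subject learning rates (length = nrow(per_day_sd)).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param n_comparisons Number of days corrected for (default `ncol`).
#' @param method Correlation inside the bootstrap: `"pearson"` (default) or
#'   `"spearman"`.
#' @param alpha Family-wise significance level before correction.
#' @return A data.frame with one row per day: `day`, `r` (full-sample
#'   correlation), `boot_sd`, `t`, `p`, `significant` (at
#'   `alpha / n_comparisons`), `defined` (FALSE for zero-variance days).
#' @export
bootstrap_day_correlation <- function(per_day_sd, lambdas, n_boot = 1000,
                                      n_comparisons = ncol(per_day_sd),
                                      method = c("pearson", "spearman"),
                                      alpha = 0.05) {
  method <- match.arg(method)
  n_sub <- nrow(per_day_sd)
  if (n_sub < 5) stop("bootstrap_day_correlation: need >= 5 subjects")
  if (length(lambdas) != n_sub) stop("lambdas must match nrow(per_day_sd)")
  out <- lapply(seq_len(ncol(per_day_sd)), function(d) {
    x <- per_day_sd[, d]
    if (stats::sd(x) == 0 || stats::sd(lambdas) == 0)
      return(data.frame(day = d, r = NA_real_, boot_sd = NA_real_,
                        t = NA_real_, p = NA_real_, significant = FALSE,
                        defined = FALSE))
    r <- stats::cor(x, lambdas, method = method)
    boot <- replicate(n_boot, {
      idx <- sample.int(n_sub, n_sub, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(lambdas[idx]) == 0) NA_real_
      else stats::cor(x[idx], lambdas[idx], method = method)
    })
    boot <- boot[!is.na(boot)]
    # boot_sd is the error-bar estimate of r's sampling SD; the significance
    # flag uses the exact-null t reference for a correlation coefficient
    # (t = r sqrt((n-2)/(1-r^2)), df = n-2), which keeps the family-wise
    # false-positive rate at alpha under an exchangeable null
    bsd <- stats::sd(boot)
    tt <- r * sqrt((n_sub - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n_sub - 2)
    data.frame(day = d, r = r, boot_sd = bsd, t = tt, p = p,
               significant = p < alpha / n_comparisons, defined = TRUE)
  })
  do.call(rbind, out)
}

#' Per-subject, per-day probe metrics
#'
#' Computes the standard per-day metric table from a trial table: the
#' sequence-specific RT z-score, sequence-probe accuracy (% correct), and RT
#' variability of both probe blocks.
#'
#' @param trials Trial data.frame (dialect of [simulate_subject()]).
#' @return A data.frame with columns `subject`, `day`, `seq_rt_z`,
#'   `accuracy_pct`, `rt_sd_seq`, `rt_sd_rand`.
#' @export
probe_metrics <- function(trials) {
  keys <- unique(trials[, c("subject", "day")])
  keys <- keys[order(keys$subject, keys$day), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- keys$subject[i]; d <- keys$day[i]
    rp <- probe_block(trials, s, d, "random_probe")
    sp <- probe_block(trials, s, d, "sequence_probe")
    data.frame(
      subject = s, day = d,
      seq_rt_z = sequence_specific_rt(rp$rt_ms, sp$rt_ms),
      accuracy_pct = 100 * mean(sp$correct),
      rt_sd_seq = rt_variability(sp$rt_ms),
      rt_sd_rand = rt_variability(rp$rt_ms),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
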