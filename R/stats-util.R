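#' One-sample t-test
#'
#' Classical one-sample t statistic `(mean(x) - mu0) / (sd(x)/sqrt(n))` with a
#' two-sided p-value on n - 1 degrees of freedom. Implemented directly so the
#' same statistic backs the chunk-estimator lag tests and the bootstrap
#' significance tests.
#'
#' @param values Numeric vector (n >= 2).
#' @param mu0 Null mean (default 0).
#' @return List with `t`, `df`, `p`, `mean`, `se`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2) stop("one_sample_t: need n >= 2")
  s <- stats::sd(x)
  if (s == 0) stop("one_sample_t: zero variance")
  se <- s / sqrt(n)
  t <- (mean(x) - mu0) / se
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), df = n - 1),
       mean = mean(x), se = se)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-corrected), with the t-approximation
#' p-value `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman: need n >= 4")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("spearman: constant input")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Bonferroni correction
#'
#' Either divides an alpha level by the number of comparisons (threshold
#' form) or multiplies p-values, capped at 1 (adjusted-p form).
#'
#' @param p Vector of p-values (adjusted-p form); supply either `p` or
#'   `alpha`.
#' @param alpha Family-wise alpha (threshold form).
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-values, or the corrected threshold.
#' @export
bonferroni <- function(p = NULL, alpha = NULL, m) {
  if (m < 1) stop("bonferroni: m must be >= 1")
  if (!is.null(alpha)) return(alpha / m)
  if (is.null(p)) stop("bonferroni: supply p or alpha")
  pmin(1, p * m)
}

#' Repeated-measures ANOVA (within-subject)
#'
#' Standard within-subject sums-of-squares decomposition for complete,
#' balanced designs. One-way: a subjects x conditions matrix; the condition
#' effect is tested against the subject-by-condition interaction. Two-way: a
#' subjects x factorA x factorB array; each main effect is tested against its
#' subject-by-factor interaction and the A:B interaction against the
#' subject-by-A-by-B term. No sphericity correction is applied (a
#' Greenhouse-Geisser epsilon is reported when `gg = TRUE`, scaling the dfs of
#' each effect).
#'
#' @param data Matrix (one-way) or 3-d array (two-way), subjects on the first
#'   dimension; no missing cells.
#' @param gg Apply Greenhouse-Geisser df correction (default FALSE).
#' @return A data.frame with one row per effect: `effect`, `F`, `df_num`,
#'   `df_den`, `p` (and `epsilon` when `gg = TRUE`).
#' @export
rm_anova <- function(data, gg = FALSE) {
  if (any(is.na(data))) stop("rm_anova: unbalanced design (missing cells)")
  if (is.matrix(data)) rm_anova_oneway(data, gg)
  else if (is.array(data) && length(dim(data)) == 3) rm_anova_twoway(data, gg)
  else stop("rm_anova: data must be a matrix or a 3-d array")
}

gg_epsilon <- function(mat) {
  # Greenhouse-Geisser epsilon from the double-centered covariance of the
  # subject x condition matrix
  S <- stats::cov(mat)
  k <- ncol(S)
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

rm_anova_oneway <- function(mat, gg = FALSE) {
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("rm_anova: need >= 2 subjects and >= 2 conditions")
  grand <- mean(mat)
  subj <- rowMeans(mat); cond <- colMeans(mat)
  ss_cond <- n * sum((cond - grand)^2)
  resid <- mat - outer(subj, rep(1, k)) - outer(rep(1, n), cond) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  eps <- if (gg) gg_epsilon(mat) else 1
  out <- data.frame(effect = "condition", F = Fv,
                    df_num = df1, df_den = df2,
                    p = stats::pf(Fv, df1 * eps, df2 * eps,
                                  lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  if (gg) out$epsilon <- eps
  out
}

rm_anova_twoway <- function(arr, gg = FALSE) {
  dd <- dim(arr)
  n <- dd[1]; a <- dd[2]; b <- dd[3]
  if (n < 2 || a < 2 || b < 2)
    stop("rm_anova: need >= 2 levels on every dimension")
  grand <- mean(arr)
  m_s <- apply(arr, 1, mean)
  m_a <- apply(arr, 2, mean)
  m_b <- apply(arr, 3, mean)
  m_sa <- apply(arr, c(1, 2), mean)
  m_sb <- apply(arr, c(1, 3), mean)
  m_ab <- apply(arr, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  full <- arr
  for (i in seq_len(n)) for (j in seq_len(a)) for (l in seq_len(b))
    full[i, j, l] <- arr[i, j, l] - m_sa[i, j] - m_sb[i, l] - m_ab[j, l] +
      m_s[i] + m_a[j] + m_b[l] - grand
  ss_sab <- sum(full^2)

  eff <- function(name, ss, df1, ss_err, df_err, eps = 1) {
    Fv <- (ss / df1) / (ss_err / df_err)
    data.frame(effect = name, F = Fv, df_num = df1, df_den = df_err,
               p = stats::pf(Fv, df1 * eps, df_err * eps, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  eps_a <- if (gg) gg_epsilon(m_sa) else 1
  eps_b <- if (gg) gg_epsilon(m_sb) else 1
  out <- rbind(
    eff("A", ss_a, a - 1L, ss_sa, (n - 1L) * (a - 1L), eps_a),
    eff("B", ss_b, b - 1L, ss_sb, (n - 1L) * (b - 1L), eps_b),
    eff("A:B", ss_ab, (a - 1L) * (b - 1L), ss_sab,
        (n - 1L) * (a - 1L) * (b - 1L))
  )
  if (gg) out$epsilon <- c(eps_a, eps_b, NA)
  out
}

#' Chi-square tail probability for nested-model likelihood-ratio tests
#'
#' @param lr_stat Likelihood-ratio statistic 2 * (ll_full - ll_reduced).
#' @param df Degrees-of-freedom difference.
#' @return Upper-tail p-value.
#' @export
lr_test_p <- function(lr_stat, df = 1) {
  stats::pchisq(max(0, lr_stat), df = df, lower.tail = FALSE)
}
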