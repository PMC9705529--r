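#' Two-tailed paired t test
#'
#' Classical paired t on the condition differences, two-tailed p from the
#' t distribution with n - 1 degrees of freedom.
#'
#' @param x1,x2 Equal-length numeric vectors (n >= 3) of the same metric
#'   from two conditions.
#' @return List with `t`, `df`, `p`, `n`, `mean_diff`.
#' @export
paired_t <- function(x1, x2) {
  d <- check_paired(x1, x2)
  tt <- t.test(x1, x2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = length(d), mean_diff = mean(d))
}

check_paired <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("paired samples must have equal length")
  if (length(x1) < 3L) stop("paired test needs n >= 3")
  if (!all(is.finite(x1)) || !all(is.finite(x2)))
    stop("non-finite values in paired sample")
  d <- x1 - x2
  if (sd(d) == 0) stop("degenerate sample: zero-variance differences")
  d
}

#' Cohen's dz paired effect size
#'
#' Mean of the condition differences over their sample standard deviation
#' (n - 1 denominator): `dz = mean(X1 - X2) / sd(X1 - X2)`.
#'
#' @param x1 First condition values, or the differences themselves when
#'   `x2` is `NULL`.
#' @param x2 Second condition values (optional).
#' @return Scalar dz.
#' @export
cohens_dz <- function(x1, x2 = NULL) {
  d <- if (is.null(x2)) x1 else x1 - x2
  if (length(d) < 2L) stop("need at least 2 differences")
  s <- sd(d)
  if (s == 0) stop("zero standard deviation of differences")
  mean(d) / s
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR over one family of p-values: q-values via the BH
#' adjustment, rejection where q <= alpha.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `q` and logical `reject`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Anderson-Darling test of normality
#'
#' Case-3 (estimated mean and variance) Anderson-Darling test with the
#' small-sample correction, via `nortest::ad.test`.
#'
#' @param x Numeric vector, n >= 8, not constant.
#' @return List with `A` (the A-squared statistic) and `p`.
#' @export
normality_ad <- function(x) {
  if (length(x) < 8L) stop("Anderson-Darling test needs n >= 8")
  if (sd(x) == 0) stop("constant vector")
  r <- nortest::ad.test(x)
  list(A = unname(r$statistic), p = r$p.value)
}

#' Correlation between effect magnitude and stimulation experience
#'
#' Pearson correlation between per-trial metric-change magnitudes and an
#' ordinal experience code (experienced = 1, rudimentary = 2, naive = 3),
#' with the two-tailed p and the 95 % Fisher-z confidence interval.
#'
#' @param magnitudes Numeric vector (e.g. percent-change magnitudes).
#' @param codes Ordinal experience codes, same length, >= 2 distinct
#'   values.
#' @return List with `r`, `p`, `ci` (length-2 vector).
#' @export
experience_correlation <- function(magnitudes, codes) {
  if (length(magnitudes) != length(codes)) stop("unequal lengths")
  if (length(magnitudes) < 3L) stop("need at least 3 points")
  if (sd(magnitudes) == 0 || length(unique(codes)) < 2L)
    stop("constant input: correlation undefined")
  r <- cor.test(as.numeric(codes), magnitudes, method = "pearson")
  list(r = unname(r$estimate), p = r$p.value,
       ci = as.numeric(r$conf.int))
}

#' Achieved power of a two-tailed paired t test
#'
#' Analytic power at effect size dz with n pairs: noncentral t with
#' noncentrality `dz * sqrt(n)` and `n - 1` degrees of freedom against
#' the two-tailed critical value at `alpha`.
#'
#' @param dz Paired effect size (Cohen's dz).
#' @param n Number of pairs, >= 2.
#' @param alpha Significance level.
#' @return Power in `[0, 1]`.
#' @export
power_paired_t <- function(dz, n, alpha = 0.05) {
  if (n < 2L) stop("power needs n >= 2")
  if (!is.finite(dz)) stop("dz must be finite")
  df <- n - 1
  ncp <- dz * sqrt(n)
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp = ncp) + 1 - pt(tc, df, ncp = ncp)
}

#' Significance stars
#'
#' `***` p < 0.005, `**` p < 0.01, `*` p < 0.05, else empty.
#'
#' @param p Numeric vector of p- (or q-) values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.005, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare one metric between two conditions across units
#'
#' For every unit (system, system pair, or "overall") present for the
#' metric, runs the two-tailed paired t test over trials, computes
#' Cohen's dz and the achieved analytic power, and applies
#' Benjamini-Hochberg FDR across the units of this contrast (one family
#' per contrast). Trials are paired by index; `aggregate_by` optionally
#' pre-averages repeated trials sharing a grouping value before pairing.
#'
#' @param mf1,mf2 `metric_frame`s of the two conditions (equal trial
#'   counts after any aggregation).
#' @param metric Metric name to compare.
#' @param units Units to include (default: all shared units).
#' @param alpha FDR level.
#' @param aggregate_by Optional vector (one value per trial, same for both
#'   frames) whose groups are averaged before pairing.
#' @return Data.frame `unit, n, t, p, q, dz, power, stars` (stars from
#'   FDR-adjusted q).
#' @export
compare_conditions <- function(mf1, mf2, metric = "flexibility",
                               units = NULL, alpha = 0.05,
                               aggregate_by = NULL) {
  u1 <- unique(mf1$unit[mf1$metric == metric])
  u2 <- unique(mf2$unit[mf2$metric == metric])
  if (is.null(units)) units <- intersect(u1, u2)
  if (length(units) == 0L) stop("no shared units for metric ", metric)
  one <- function(u) {
    v1 <- metric_values(mf1, metric, u)
    v2 <- metric_values(mf2, metric, u)
    if (!is.null(aggregate_by)) {
      v1 <- tapply(v1, aggregate_by, mean)
      v2 <- tapply(v2, aggregate_by, mean)
    }
    tt <- paired_t(v1, v2)
    dz <- cohens_dz(v1, v2)
    data.frame(unit = u, n = tt$n, t = tt$t, p = tt$p, dz = dz,
               power = power_paired_t(dz, tt$n, alpha))
  }
  res <- do.call(rbind, lapply(units, one))
  fdr <- fdr_bh(res$p, alpha)
  res$q <- fdr$q
  res$stars <- significance_stars(res$q)
  rownames(res) <- NULL
  res[, c("unit", "n", "t", "p", "q", "dz", "power", "stars")]
}
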