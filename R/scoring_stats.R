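#' Score one cleaned cut-mark sample
#'
#' The cleaning experiments grade each cast against its untreated reference
#' on five microscopic criteria: coarse striations detectable, fine
#' striations detectable, complete mark detectable, no shine, no dots. Each
#' fulfilled criterion scores 1, an unfulfilled one 0; `no_dots` may
#' additionally score -1 when more dots occur than on the reference mark.
#' The total score TS therefore lies in `[-1, 5]`.
#'
#' @param coarse_striations,fine_striations,complete_mark,no_shine 0 or 1.
#' @param no_dots -1, 0 or 1.
#' @return An object of class `cleaning_score` with the five criteria and
#'   `total`.
#' @export
#' @examples
#' score_sample(1, 1, 1, 0, no_dots = -1)$total  # 2
score_sample <- function(coarse_striations, fine_striations, complete_mark,
                         no_shine, no_dots) {
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !v %in% c(0, 1))
      stop("'", nm, "' must be 0 or 1")
    v
  }
  coarse_striations <- chk01(coarse_striations, "coarse_striations")
  fine_striations <- chk01(fine_striations, "fine_striations")
  complete_mark <- chk01(complete_mark, "complete_mark")
  no_shine <- chk01(no_shine, "no_shine")
  if (!is.numeric(no_dots) || length(no_dots) != 1L ||
      !no_dots %in% c(-1, 0, 1))
    stop("'no_dots' must be -1, 0 or 1 (-1 = more dots than the reference)")
  total <- coarse_striations + fine_striations + complete_mark + no_shine +
    no_dots
  structure(list(coarse_striations = coarse_striations,
                 fine_striations = fine_striations,
                 complete_mark = complete_mark, no_shine = no_shine,
                 no_dots = no_dots, total = as.integer(total)),
            class = "cleaning_score")
}

#' Delta score between cleaned samples and their references
#'
#' The effect of a cleaning method is the difference between the total
#' scores of the cleaned samples and the untreated reference marks,
#' `DS = TS_sample - TS_reference`. Given raw per-sample scores of equal
#' length the per-pair differences are returned as well.
#'
#' @param ts_sample Numeric vector of sample total scores, or a single mean.
#' @param ts_reference Numeric vector of reference total scores, or a mean.
#' @return A list with `mean` (the DS mean) and `per_sample` (pairwise
#'   differences when both inputs are raw vectors of equal length, else
#'   `NULL`).
#' @export
#' @examples
#' delta_score(3.27, 1.67)$mean  # 1.60
delta_score <- function(ts_sample, ts_reference) {
  ts_sample <- as.numeric(ts_sample)
  ts_reference <- as.numeric(ts_reference)
  per <- NULL
  if (length(ts_sample) > 1L && length(ts_sample) == length(ts_reference))
    per <- ts_sample - ts_reference
  list(mean = mean(ts_sample) - mean(ts_reference), per_sample = per)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the independent-samples t-test directly from `(mean, sd, n)`
#' summaries, as needed when only printed summaries are available — e.g.
#' comparing the diameters of the grain-like dots on cartilage casts with
#' the chondrocyte diameters measured on stained sections. Both the Welch
#' (unequal variances, Welch-Satterthwaite df) and the pooled-variance
#' flavor are available; Welch is the default because it is safe under
#' unequal variances.
#'
#' @param mean_a,sd_a,n_a Summary of group A.
#' @param mean_b,sd_b,n_b Summary of group B.
#' @param flavor `"welch"` (default) or `"pooled"`.
#' @return A list with `t`, `df` and two-sided `p.value`.
#' @details Degenerate contract: with zero variance in both groups, equal
#'   means give `p = 1` and unequal means `p = 0`.
#' @export
#' @examples
#' ttest_from_summary(26.3, 5.1, 30, 29.2, 7.6, 40)$p.value  # > 0.05
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  for (v in list(sd_a, sd_b)) if (!is.finite(v) || v < 0)
    stop("standard deviations must be nonnegative")
  for (v in list(n_a, n_b)) if (!is.finite(v) || v < 2)
    stop("group sizes must be at least 2")
  if (flavor == "welch") {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se2 <- va + vb
    df <- if (se2 > 0) se2^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
          else n_a + n_b - 2
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se2 <- sp2 * (1 / n_a + 1 / n_b)
    df <- n_a + n_b - 2
  }
  if (se2 == 0) {
    if (mean_a == mean_b) return(list(t = 0, df = df, p.value = 1))
    return(list(t = sign(mean_a - mean_b) * Inf, df = df, p.value = 0))
  }
  t_stat <- (mean_a - mean_b) / sqrt(se2)
  list(t = t_stat, df = df, p.value = 2 * pt(-abs(t_stat), df))
}

#' Mann-Whitney U test for independent samples
#'
#' Two-sided rank-sum test reporting the U statistic. The exact null
#' distribution is used for combined sample sizes up to 25 without ties
#' (the usual group sizes in the scoring and comparison studies are 10-15);
#' larger or tied samples use the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y Numeric samples.
#' @return A list with `U` (the statistic for `x`), `p.value` and `exact`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 25L) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value, exact = exact)
}

#' Standard statistical tests behind one contract
#'
#' Thin wrappers over the established tests used throughout the scoring and
#' contrast analyses, all two-sided: Mann-Whitney U for independent samples,
#' Wilcoxon signed-rank for paired samples, Pearson correlation, and
#' normality checks (Kolmogorov-Smirnov with estimated parameters, i.e. the
#' Lilliefors correction, and Shapiro-Wilk). Significance is conventionally
#' judged against [SIGNIFICANCE_LEVEL].
#'
#' @param x Numeric sample (the only sample for normality tests).
#' @param y Second sample (required for two-sample and correlation tests;
#'   the Wilcoxon test pairs `x` and `y` elementwise).
#' @param test One of `"mann-whitney-u"`, `"wilcoxon-signed-rank"`,
#'   `"pearson"`, `"ks-normality"`, `"shapiro-normality"`.
#' @return A list with `statistic` and `p.value` (for `"pearson"` also
#'   `estimate`, the correlation coefficient r).
#' @export
test_battery <- function(x, y = NULL,
                         test = c("mann-whitney-u", "wilcoxon-signed-rank",
                                  "pearson", "ks-normality",
                                  "shapiro-normality")) {
  test <- match.arg(test)
  x <- as.numeric(x)
  switch(test,
    "mann-whitney-u" = {
      if (is.null(y)) stop("mann-whitney-u needs two samples")
      r <- mann_whitney_u(x, y)
      list(statistic = r$U, p.value = r$p.value)
    },
    "wilcoxon-signed-rank" = {
      if (is.null(y)) stop("the signed-rank test needs paired samples")
      y <- as.numeric(y)
      if (length(x) != length(y))
        stop("paired samples must have equal length")
      d <- x - y
      if (all(d == 0)) return(list(statistic = 0, p.value = 1))
      ties <- anyDuplicated(abs(d[d != 0])) > 0L
      wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                         exact = !ties && length(d) <= 25L))
      list(statistic = unname(wt$statistic), p.value = wt$p.value)
    },
    "pearson" = {
      if (is.null(y)) stop("pearson needs two samples")
      y <- as.numeric(y)
      if (length(x) != length(y) || length(x) < 3L)
        stop("pearson needs >= 3 paired points")
      if (sd(x) == 0 || sd(y) == 0)
        stop("degenerate (zero-variance) input for correlation")
      ct <- cor.test(x, y, method = "pearson")
      list(statistic = unname(ct$statistic), p.value = ct$p.value,
           estimate = unname(ct$estimate))
    },
    "ks-normality" = {
      if (length(x) < 5L) stop("ks-normality needs >= 5 values")
      if (sd(x) == 0) stop("degenerate (zero-variance) input")
      kt <- nortest::lillie.test(x)
      list(statistic = unname(kt$statistic), p.value = kt$p.value)
    },
    "shapiro-normality" = {
      if (length(x) < 3L) stop("shapiro-normality needs >= 3 values")
      if (sd(x) == 0) stop("degenerate (zero-variance) input")
      st <- shapiro.test(x)
      list(statistic = unname(st$statistic), p.value = st$p.value)
    })
}
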