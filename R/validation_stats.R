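#' Friedman's ANOVA with Kendall's W effect size
#'
#' Rank-based omnibus test for k related conditions (midrank ties, tie
#' correction), with concordance effect size W = chi2 / (n * (k - 1)).
#'
#' @param data An n-subjects x k-conditions numeric matrix or data frame
#'   (no missing cells, k >= 3).
#' @return A one-row tibble: `method`, `statistic` (chi-squared), `df`,
#'   `p.value`, `effect_name` (`"kendall_w"`), `effect`.
#' @export
friedman_kendall <- function(data) {
  m <- as.matrix(data)
  if (anyNA(m)) abort("No missing cells allowed.")
  n <- nrow(m)
  k <- ncol(m)
  if (k < 3) abort("Need at least 3 conditions.")
  if (n < 2) abort("Need at least 2 subjects.")
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    # every row fully tied: no concordance signal at all
    return(tibble::tibble(
      method = "Friedman rank sum test",
      statistic = 0, df = k - 1, p.value = 1,
      effect_name = "kendall_w", effect = 0
    ))
  }
  ft <- stats::friedman.test(m)
  chi2 <- unname(ft$statistic)
  tibble::tibble(
    method = "Friedman rank sum test",
    statistic = chi2,
    df = unname(ft$parameter),
    p.value = ft$p.value,
    effect_name = "kendall_w",
    effect = chi2 / (n * (k - 1))
  )
}

#' One-sample Wilcoxon signed-rank test with r effect size
#'
#' Compares the sample median to a hypothetical value using the signed-rank
#' statistic with midrank ties and the tie-corrected normal approximation
#' (no continuity correction). The effect size is r = Z / sqrt(N) with N the
#' full sample size.
#'
#' @param values Numeric sample.
#' @param hypothetical_median The comparison value.
#' @return A one-row tibble: `method`, `statistic` (Z), `df` (`NA`),
#'   `p.value`, `effect_name` (`"r"`), `effect`.
#' @export
wilcoxon_one_sample <- function(values, hypothetical_median) {
  n_total <- length(values)
  d <- values - hypothetical_median
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) abort("Need at least 5 non-zero differences.")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  e_w <- n * (n + 1) / 4
  ties <- table(r)
  var_w <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (w_pos - e_w) / sqrt(var_w)
  tibble::tibble(
    method = "Wilcoxon one-sample signed-rank test",
    statistic = z,
    df = NA_real_,
    p.value = 2 * stats::pnorm(-abs(z)),
    effect_name = "r",
    effect = z / sqrt(n_total)
  )
}

#' Effect size r from a Z statistic
#'
#' @param z Z statistic.
#' @param n Sample size.
#' @return r = z / sqrt(n).
#' @export
wilcoxon_r <- function(z, n) {
  z / sqrt(n)
}

#' Cohen's d from condition means and SDs (pooled-SD form)
#'
#' `d = (m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)`. This is the form that
#' reproduces printed effect sizes computed from per-condition summary
#' statistics (as opposed to the difference-score SD form).
#'
#' @param m1,sd1 Mean and SD of the first condition.
#' @param m2,sd2 Mean and SD of the second condition.
#' @return Cohen's d.
#' @export
cohens_d_pooled <- function(m1, sd1, m2, sd2) {
  (m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Paired-samples t-test with Cohen's d
#'
#' The t statistic uses the difference scores (`t = mean(x - y) /
#' (sd(x - y) / sqrt(n))`); Cohen's d uses the pooled per-condition SDs
#' (see [cohens_d_pooled()]). The confidence interval is on the mean
#' difference.
#'
#' @param x,y Paired numeric samples.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `method`, `statistic` (t), `df`, `p.value`,
#'   `effect_name` (`"cohens_d"`), `effect`, `conf.low`, `conf.high`.
#' @export
paired_t_cohend <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("Samples must be paired.")
  if (length(x) < 2) abort("Need at least 2 pairs.")
  d_sd <- stats::sd(x - y)
  if (d_sd < 1e-10 * max(1, abs(mean(x - y)), abs(mean(x)))) {
    if (abs(mean(x - y)) > 1e-10) abort("Zero-variance differences.")
    # identical samples: no effect by definition
    return(tibble::tibble(
      method = "Paired-samples t-test",
      statistic = 0, df = length(x) - 1, p.value = 1,
      effect_name = "cohens_d", effect = 0,
      conf.low = 0, conf.high = 0
    ))
  }
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
  tibble::tibble(
    method = "Paired-samples t-test",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    effect_name = "cohens_d",
    effect = cohens_d_pooled(mean(x), stats::sd(x), mean(y), stats::sd(y)),
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2]
  )
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Within-subject F test on an n x k matrix of condition values, effect size
#' partial eta^2 = SS_effect / (SS_effect + SS_error), and Benjamini-
#' Hochberg-controlled post-hoc paired t-tests for all condition pairs.
#' No sphericity correction is applied.
#'
#' @param data An n-subjects x k-conditions numeric matrix or data frame.
#' @return A one-row tibble: `method`, `statistic` (F), `df1`, `df2`,
#'   `p.value`, `effect_name` (`"partial_eta2"`), `effect`. Post-hoc
#'   comparisons are attached as attribute `"posthoc"` (tibble with
#'   `pair`, `statistic`, `df`, `p.value`, `p.adjusted`, `cohens_d`).
#' @export
rm_anova <- function(data) {
  m <- as.matrix(data)
  if (anyNA(m)) abort("No missing cells allowed.")
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) abort("Need at least 2 conditions.")
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  # identical condition profiles: no effect (and possibly no error) at all
  f <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  out <- tibble::tibble(
    method = "One-way repeated-measures ANOVA",
    statistic = f,
    df1 = df1,
    df2 = df2,
    p.value = stats::pf(f, df1, df2, lower.tail = FALSE),
    effect_name = "partial_eta2",
    effect = if (ss_cond == 0) 0 else ss_cond / (ss_cond + ss_err)
  )
  cols <- colnames(m) %||% paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  posthoc <- purrr::map_dfr(seq_len(ncol(pairs)), function(u) {
    i <- pairs[1, u]
    j <- pairs[2, u]
    res <- paired_t_cohend(m[, i], m[, j])
    tibble::tibble(
      pair = paste(cols[i], cols[j], sep = " vs "),
      statistic = res$statistic, df = res$df, p.value = res$p.value,
      cohens_d = res$effect
    )
  })
  posthoc$p.adjusted <- stats::p.adjust(posthoc$p.value, method = "BH")
  attr(out, "posthoc") <- posthoc
  out
}
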