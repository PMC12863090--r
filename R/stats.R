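group_comparison <- function(test, statistic, p_raw, effect, n1, n2 = NA_integer_,
                             ci = NULL, p_adjusted = NA_real_) {
  structure(list(test = test, statistic = unname(statistic), p_raw = unname(p_raw),
                 p_adjusted = p_adjusted, effect = effect, ci = ci,
                 n1 = n1, n2 = n2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  eff <- paste(names(x$effect), signif(unlist(x$effect), 4), sep = " = ",
               collapse = ", ")
  cat("<group_comparison> ", x$test, ": statistic = ", signif(x$statistic, 6),
      ", p = ", signif(x$p_raw, 4), ", ", eff, "\n", sep = "")
  if (!is.null(x$ci)) {
    cat("  ", format(100 * x$ci$level), "% CI [", signif(x$ci$low, 4), ", ",
        signif(x$ci$high, 4), "]\n", sep = "")
  }
  invisible(x)
}

tie_corrected_z <- function(u, n1, n2, pooled) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  (u - mu) / sqrt(sigma2)
}

#' Wilcoxon rank-sum (Mann-Whitney) test with rank-biserial effect size
#'
#' Two-sided rank-sum comparison of two independent groups. The p-value
#' is computed by exact enumeration when the combined sample is at most
#' 50 with no ties, and by the tie-corrected normal approximation with
#' continuity correction otherwise. Two effect sizes are reported: the
#' primary rank-biserial correlation `r = 1 − 2U/(n1·n2)`, and the
#' `z/sqrt(N)` variant some packages report, which differs from the
#' primary definition under ties.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_max Combined-sample threshold below which the exact
#'   distribution is used (default 50).
#' @return A `group_comparison` with `test = "rank_sum"`, statistic `U`
#'   (for `x`), and effects `rank_biserial`, `rank_biserial_z`.
#' @export
rank_sum_test <- function(x, y, exact_max = 50) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) stop("each group needs n >= 1", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    stop("degenerate data: all values identical across both groups", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(pooled) > 0
  exact <- (n1 + n2) <= exact_max && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  u <- unname(ht$statistic)
  r_rb <- 1 - 2 * u / (n1 * n2)
  z <- tie_corrected_z(u, n1, n2, pooled)
  group_comparison("rank_sum", u, ht$p.value,
                   effect = list(rank_biserial = r_rb,
                                 rank_biserial_z = -z / sqrt(n1 + n2)),
                   n1 = n1, n2 = n2)
}

#' Wilcoxon signed-rank test for paired deltas
#'
#' Two-sided signed-rank test of paired differences (e.g. original minus
#' shuffled per sequence). Exact for at most `exact_max` nonzero,
#' tie-free deltas; normal approximation with continuity and tie
#' correction otherwise. Zeros are dropped before ranking by default;
#' the Pratt variant (`zero_method = "pratt"`) ranks them first and then
#' discards their ranks. The matched rank-biserial correlation
#' `(W+ − W−) / (W+ + W−)` is reported.
#'
#' @param deltas Numeric vector of paired differences.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @param exact_max Sample-size threshold for the exact distribution
#'   (default 25).
#' @return A `group_comparison` with `test = "signed_rank"`.
#' @export
signed_rank_test <- function(deltas, zero_method = c("wilcox", "pratt"),
                             exact_max = 25) {
  zero_method <- match.arg(zero_method)
  d <- as.numeric(deltas)
  d <- d[!is.na(d)]
  if (length(d) == 0 || all(d == 0)) {
    stop("degenerate data: no nonzero paired differences", call. = FALSE)
  }
  if (zero_method == "wilcox") {
    dd <- d[d != 0]
    n <- length(dd)
    ties <- anyDuplicated(abs(dd)) > 0
    exact <- n <= exact_max && !ties
    ht <- suppressWarnings(stats::wilcox.test(dd, exact = exact, correct = TRUE))
    v <- unname(ht$statistic)
    p <- ht$p.value
    rk <- rank(abs(dd))
  } else {
    # Pratt: rank |d| including zeros, drop zero ranks, normal approx
    rk_all <- rank(abs(d))
    nz <- d != 0
    rk <- rk_all[nz]
    dd <- d[nz]
    v <- sum(rk[dd > 0])
    mu <- sum(rk) / 2
    tt <- table(rk)
    sigma2 <- sum(rk^2) / 4 - sum(tt^3 - tt) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    n <- length(dd)
  }
  w_pos <- sum(rk[dd > 0])
  w_neg <- sum(rk[dd < 0])
  r_rb <- (w_pos - w_neg) / (w_pos + w_neg)
  group_comparison("signed_rank", v, p,
                   effect = list(rank_biserial = r_rb), n1 = n)
}

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != floor(m))) {
    stop("2x2 counts must be non-negative integers", call. = FALSE)
  }
  if (sum(m) == 0) stop("empty 2x2 table", call. = FALSE)
  m
}

sample_odds_ratio <- function(m) {
  if (any(m == 0)) m <- m + 0.5
  (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test (summing hypergeometric probabilities no larger
#' than the observed one). Reports both the conditional
#' maximum-likelihood odds ratio (with its exact CI) and the sample odds
#' ratio `ad/bc`, the latter with the Haldane–Anscombe 0.5 correction
#' applied to all cells when any cell is zero.
#'
#' @param table 2x2 matrix of counts: rows = groups, columns =
#'   feature present / absent.
#' @param level Confidence level for the odds-ratio CI (default 0.95).
#' @return A `group_comparison` with `test = "fisher_exact"` and effects
#'   `odds_ratio` (conditional MLE) and `sample_odds_ratio`.
#' @export
fisher_exact <- function(table, level = 0.95) {
  m <- as_2x2(table)
  ht <- stats::fisher.test(m, conf.level = level)
  group_comparison("fisher_exact", ht$estimate, ht$p.value,
                   effect = list(odds_ratio = unname(ht$estimate),
                                 sample_odds_ratio = sample_odds_ratio(m)),
                   n1 = sum(m[1, ]), n2 = sum(m[2, ]),
                   ci = list(low = ht$conf.int[1], high = ht$conf.int[2],
                             level = level))
}

#' McNemar's test from discordant pair counts
#'
#' Paired comparison of a binary feature (e.g. degron presence in
#' original vs shuffled sequences) from the two discordant counts:
#' `b` pairs positive only in the first condition, `c` positive only in
#' the second. Exact binomial test for `b + c <= 25`, chi-squared with
#' continuity correction otherwise. The paired odds ratio `b/c`
#' (0.5-corrected when either count is zero) is reported.
#'
#' @param b,c Discordant pair counts.
#' @param exact_max Threshold on `b + c` for the exact test (default 25).
#' @return A `group_comparison` with `test = "mcnemar"`.
#' @export
mcnemar_test <- function(b, c, exact_max = 25) {
  b <- assert_count(b, "b", min = 0)
  c <- assert_count(c, "c", min = 0)
  if (b + c == 0) stop("degenerate data: no discordant pairs", call. = FALSE)
  if (b + c <= exact_max) {
    ht <- stats::binom.test(b, b + c, p = 0.5)
    stat <- b
    p <- ht$p.value
  } else {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  or <- if (b == 0 || c == 0) (b + 0.5) / (c + 0.5) else b / c
  group_comparison("mcnemar", stat, p,
                   effect = list(paired_odds_ratio = or), n1 = b + c)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment with monotonicity
#' enforcement, preserving input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Wilson score confidence interval for a proportion
#'
#' Score-based interval with continuity correction (the behavior of
#' `stats::prop.test` with default settings).
#'
#' @param successes Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
proportion_ci <- function(successes, n, level = 0.95) {
  successes <- assert_count(successes, "successes", min = 0)
  n <- assert_count(n, "n", min = 1)
  if (successes > n) stop("successes cannot exceed n", call. = FALSE)
  ci <- suppressWarnings(
    stats::prop.test(successes, n, conf.level = level, correct = TRUE)$conf.int)
  c(low = ci[1], high = ci[2])
}

#' Spearman rank correlation
#'
#' Rho computed on average ranks (midranks under ties); p-value by the
#' exact permutation distribution for `n <= 7` without ties and the
#' t approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `group_comparison` with `test = "spearman"` and effect
#'   `rho`.
#' @export
spearman_corr <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("degenerate data: constant input", call. = FALSE)
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- length(x) <= 7 && !ties
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  group_comparison("spearman", ht$statistic, ht$p.value,
                   effect = list(rho = unname(ht$estimate)), n1 = length(x))
}

#' Exact two-group Poisson rate comparison
#'
#' Compares two event rates with unequal exposures (e.g. motif counts
#' normalized by summed protein length) via the exact conditional
#' binomial test: given the total count, the first group's count is
#' binomial with success probability `exposure1 / (exposure1 +
#' exposure2)` under equal rates. The rate ratio and an exact CI
#' (transformed from the conditional binomial CI) are reported.
#'
#' @param count1,count2 Event counts.
#' @param exposure1,exposure2 Positive exposures (e.g. total residues).
#' @param level Confidence level (default 0.95).
#' @return A `group_comparison` with `test = "poisson_rate"` and effect
#'   `rate_ratio`.
#' @export
poisson_rate_test <- function(count1, exposure1, count2, exposure2, level = 0.95) {
  count1 <- assert_count(count1, "count1", min = 0)
  count2 <- assert_count(count2, "count2", min = 0)
  if (exposure1 <= 0 || exposure2 <= 0) stop("exposures must be > 0", call. = FALSE)
  if (count1 + count2 == 0) stop("degenerate data: both counts zero", call. = FALSE)
  total <- count1 + count2
  p0 <- exposure1 / (exposure1 + exposure2)
  ht <- stats::binom.test(count1, total, p = p0, conf.level = level)
  rr <- if (count2 == 0) Inf else (count1 / exposure1) / (count2 / exposure2)
  ci <- ht$conf.int
  to_rr <- function(pi) if (pi >= 1) Inf else (pi / (1 - pi)) * (exposure2 / exposure1)
  group_comparison("poisson_rate", count1, ht$p.value,
                   effect = list(rate_ratio = rr),
                   n1 = count1, n2 = count2,
                   ci = list(low = to_rr(ci[1]), high = to_rr(ci[2]), level = level))
}

#' Cohen's d and rank-biserial effect sizes for two groups
#'
#' @param x,y Numeric vectors.
#' @return List with `cohens_d` (pooled-SD standardized mean difference)
#'   and `rank_biserial`.
#' @export
effect_sizes <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2 for Cohen's d", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(cohens_d = d, rank_biserial = 1 - 2 * u / (n1 * n2))
}

#' Risk ratio and odds ratio from a 2x2 table
#'
#' @param table 2x2 matrix: rows = groups, columns = feature present /
#'   absent.
#' @return List with `risk_ratio` and `odds_ratio` (sample, 0.5-corrected
#'   when any cell is zero).
#' @export
effect_sizes_2x2 <- function(table) {
  m <- as_2x2(table)
  rr <- (m[1, 1] / sum(m[1, ])) / (m[2, 1] / sum(m[2, ]))
  list(risk_ratio = rr, odds_ratio = sample_odds_ratio(m))
}
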