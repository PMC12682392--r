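#' Shapiro-Wilk normality test
#'
#' W statistic and p-value (Royston's approximation, as implemented in
#' \code{stats::shapiro.test}), used to gate the choice between parametric
#' and rank-based group comparisons.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `w` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant sample: zero variance")
  sw <- stats::shapiro.test(values)
  list(w = unname(sw$statistic), p_value = sw$p.value)
}

#' Distribution-gated two-group comparison
#'
#' If both groups pass Shapiro-Wilk at `alpha_normality`, an independent
#' samples t-test is used (Welch form when the variance-ratio F-test rejects
#' equality at 0.05, pooled otherwise); otherwise the Mann-Whitney U test
#' with normal approximation and tie correction.
#'
#' @param values Numeric vector of measurements.
#' @param group_labels Vector with exactly two levels, each n >= 3.
#' @param alpha_normality Normality gate level (default 0.05).
#' @return List of class `group_comparison`: `test_used` (`"t"`,
#'   `"welch_t"` or `"mann_whitney"`), `statistic`, `p_value`, and per-group
#'   `summaries` (n, mean, sd, median, q1, q3, normal flag).
#' @export
compare_groups <- function(values, group_labels, alpha_normality = 0.05) {
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  ok <- is.finite(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  xs <- split(values, g)
  if (any(lengths(xs) < 3L)) stop("each group needs n >= 3")
  norm_p <- vapply(xs, function(v) {
    if (stats::sd(v) == 0) 0 else shapiro_wilk(v)$p_value
  }, numeric(1))
  both_normal <- all(norm_p > alpha_normality)
  summaries <- lapply(seq_along(xs), function(i) {
    v <- xs[[i]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(group = names(xs)[i], n = length(v), mean = mean(v),
         sd = stats::sd(v), q1 = q[1], median = q[2], q3 = q[3],
         normal = norm_p[i] > alpha_normality)
  })
  names(summaries) <- names(xs)
  if (both_normal) {
    equal_var <- stats::var.test(xs[[1]], xs[[2]])$p.value >= 0.05
    tt <- stats::t.test(xs[[1]], xs[[2]], var.equal = equal_var)
    res <- list(test_used = if (equal_var) "t" else "welch_t",
                statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    wt <- stats::wilcox.test(xs[[1]], xs[[2]], exact = FALSE, correct = TRUE)
    res <- list(test_used = "mann_whitney",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  res$summaries <- summaries
  class(res) <- "group_comparison"
  res
}

#' 2x2 contingency table
#'
#' Cell layout: rows are the factor levels, columns the response classes
#' (pCR / non-pCR): `a`, `b` first row; `c`, `d` second row.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return Object of class `contingency_2x2` (a 2x2 integer matrix).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("counts must be non-negative integers")
  if (sum(cells) < 1) stop("table must contain at least one observation")
  m <- matrix(as.integer(cells), 2, 2, byrow = TRUE)
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Chi-squared test for a 2x2 table with expected-count-gated correction
#'
#' Pearson chi-square without continuity correction when the minimum
#' expected cell count is >= 5; Yates continuity correction when it is in
#' `[1, 5)`; below 1 the caller is directed to Fisher's exact test
#' (`fisher_recommended = TRUE`; the Yates statistic is still reported).
#'
#' @param t A [contingency_2x2()] or 2x2 matrix of counts.
#' @return List: `statistic`, `p_value`, `df` (1), `correction_applied`,
#'   `min_expected`, `fisher_recommended`.
#' @export
chi_square_2x2 <- function(t) {
  m <- as_2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: chi-square test undefined")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  min_exp <- min(expected)
  correct <- min_exp < 5
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L,
       correction_applied = correct, min_expected = min_exp,
       fisher_recommended = min_exp < 1)
}

as_2x2 <- function(t) {
  m <- unclass(as.matrix(t))
  if (!identical(dim(m), c(2L, 2L))) stop("a 2x2 table is required")
  storage.mode(m) <- "double"
  m
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of all
#' margin-fixed tables no more probable than the observed one.
#'
#' @param t A [contingency_2x2()] or 2x2 matrix of counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(t) {
  m <- as_2x2(t)
  stats::fisher.test(m)$p.value
}

#' Monte-Carlo Fisher test for r x c tables
#'
#' Permutation p-value for independence in an r x c table with sparse cells:
#' samples `reps` tables with the observed margins (Patefield's algorithm via
#' \code{stats::r2dtable}) and counts those whose multivariate
#' hypergeometric probability does not exceed the observed table's.
#' `p = (1 + n_extreme) / (reps + 1)`; deterministic given `seed`.
#'
#' @param table Matrix of non-negative integer counts.
#' @param reps Number of sampled tables, >= 1e4.
#' @param seed Integer seed.
#' @return List: `p_value`, `mc_se` (Monte-Carlo standard error), `reps`.
#' @export
fisher_rxc_montecarlo <- function(table, reps = 1e4, seed = 1L) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stop("counts must be integers >= 0")
  if (reps < 1e4) stop("reps must be >= 1e4 for a stable permutation p")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin")
  logp_obs <- table_log_prob(m)
  set.seed(seed)
  sampled <- stats::r2dtable(reps, rs, cs)
  logp <- vapply(sampled, table_log_prob, numeric(1))
  n_extreme <- sum(logp <= logp_obs + 1e-7)
  p <- (1 + n_extreme) / (reps + 1)
  list(p_value = p, mc_se = sqrt(p * (1 - p) / reps), reps = reps)
}

# log multivariate hypergeometric probability of a margin-fixed table
table_log_prob <- function(m) {
  sum(lfactorial(rowSums(m))) + sum(lfactorial(colSums(m))) -
    lfactorial(sum(m)) - sum(lfactorial(m))
}
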