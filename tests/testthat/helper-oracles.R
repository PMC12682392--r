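# Independent oracles used across the suite. Each is a deliberately naive
# (brute-force / closed-form) computation, kept separate from the package's
# code paths.

nominal_offsets <- c(-4.3, -3.5, -2.7, 2.7, 3.5, 4.3)

# closed-form Pearson chi-square, no correction
chisq_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# closed-form Yates-corrected chi-square
chisq_yates_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * max(0, abs(a * d - b * c) - n / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Fisher two-sided p by full enumeration over the free cell
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  amin <- max(0L, r1 + c1 - n); amax <- min(r1, c1)
  probs <- stats::dhyper(amin:amax, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by brute-force pair counting (ties = 1/2)
auc_pairs <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# least-squares slope oracle via lm()
slope_lm <- function(y, x) unname(stats::coef(stats::lm(y ~ x))[2])

# jackknife variance of the paired AUC difference
delong_var_jackknife <- function(scores_a, scores_b, labels) {
  n <- length(labels)
  d_i <- vapply(seq_len(n), function(i) {
    auc_pairs(scores_a[-i], labels[-i]) - auc_pairs(scores_b[-i], labels[-i])
  }, numeric(1))
  (n - 1) / n * sum((d_i - mean(d_i))^2)
}

# ICC(2,1) via the textbook two-way ANOVA decomposition done longhand
icc21_longhand <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1); msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

feature_columns_test <- function() {
  c("mean", "sd", "rms", "mad", paste0("p", feature_percentiles),
    "iqr", "skewness", "kurtosis")
}

# small default phantom used by several tests (shimmed: B0 field off)
test_scene <- function(...) {
  phantom_scene(dim = c(16, 16, 6), tumor_radius = c(5, 5, 2.2),
                core_radius = 0, seed = 11L, ...)
}
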