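test_that("Shapiro-Wilk wrapper reproduces the reference algorithm", {
  x <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  sw <- shapiro_wilk(x)
  ref <- stats::shapiro.test(x)            # Royston AS R94
  expect_equal(sw$w, unname(ref$statistic), tolerance = 1e-3)
  expect_equal(sw$p_value, ref$p.value, tolerance = 1e-6)

  set.seed(12)
  big <- rnorm(5000)
  expect_gt(shapiro_wilk(big)$p_value, 0.01)

  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("group comparison gates between t, Welch and Mann-Whitney", {
  # identical groups: t statistic 0, p = 1
  g <- rep(c("a", "b"), each = 6)
  r0 <- compare_groups(rep(1:6, 2), g)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_match(r0$test_used, "^t|welch_t$")

  # clearly separated normals
  set.seed(31)
  x <- c(rnorm(50), rnorm(50, 2))
  gl <- rep(0:1, each = 50)
  r1 <- compare_groups(x, gl)
  expect_lt(r1$p_value, 0.001)
  expect_true(r1$test_used %in% c("t", "welch_t"))

  # unequal variances route to Welch
  set.seed(32)
  xv <- c(rnorm(60, sd = 1), rnorm(60, 1, sd = 4))
  rv <- compare_groups(xv, rep(0:1, each = 60))
  expect_identical(rv$test_used, "welch_t")

  # heavy skew routes to Mann-Whitney
  set.seed(33)
  xs <- c(rlnorm(40, sdlog = 1.3), rlnorm(40, 0.5, sdlog = 1.3))
  rs <- compare_groups(xs, rep(0:1, each = 40))
  expect_identical(rs$test_used, "mann_whitney")

  expect_error(compare_groups(1:10, rep("a", 10)), "two groups")
  expect_error(compare_groups(1:5, c("a", "a", "a", "b", "b")), "n >= 3")
})

test_that("type-I error of the gated comparison is near nominal under
           normal and lognormal nulls", {
  alpha_hat <- function(gen) {
    reps <- 2000
    hits <- 0L
    for (i in seq_len(reps)) {
      x <- gen(i)
      p <- compare_groups(x, rep(0:1, each = 25))$p_value
      if (p < 0.05) hits <- hits + 1L
    }
    hits / reps
  }
  set.seed(77)
  a_norm <- alpha_hat(function(i) rnorm(50))
  a_lnorm <- alpha_hat(function(i) rlnorm(50, sdlog = 1.2))
  expect_lt(abs(a_norm - 0.05), 0.015)
  expect_lt(abs(a_lnorm - 0.05), 0.015)
})

test_that("2x2 chi-square reproduces closed formulas and the correction
           gate", {
  # perfectly proportional table -> 0
  expect_equal(chi_square_2x2(contingency_2x2(10, 20, 10, 20))$statistic, 0)

  set.seed(41)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(c(3, 10, 40), 1)) + 1L
    ct <- chi_square_2x2(contingency_2x2(cells[1], cells[2],
                                         cells[3], cells[4]))
    closed <- if (ct$correction_applied)
      chisq_yates_closed_form(cells[1], cells[2], cells[3], cells[4])
    else
      chisq_closed_form(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ct$statistic, closed, tolerance = 1e-9)
    expect_identical(ct$correction_applied, ct$min_expected < 5)
  }
  expect_error(chi_square_2x2(contingency_2x2(0, 0, 5, 5)), "zero margin")
})

test_that("Fisher 2x2 equals full enumeration", {
  expect_equal(fisher_exact_2x2(contingency_2x2(2, 0, 0, 2)), 1 / 3,
               tolerance = 1e-12)
  # single-column tables are uninformative: p = 1
  expect_equal(fisher_exact_2x2(contingency_2x2(4, 0, 7, 0)), 1)

  set.seed(42)
  for (i in 1:200) {
    cells <- rpois(4, 4)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    expect_equal(fisher_exact_2x2(contingency_2x2(cells[1], cells[2],
                                                  cells[3], cells[4])),
                 fisher_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("Monte-Carlo Fisher agrees with the exact 2x2 test and is
           deterministic", {
  tb <- matrix(c(8, 3, 2, 9), 2, 2)
  mc <- fisher_rxc_montecarlo(tb, reps = 2e4, seed = 7)
  exact <- fisher_exact_2x2(contingency_2x2(8, 3, 2, 9))
  expect_lt(abs(mc$p_value - exact), 3 * mc$mc_se)

  mc2 <- fisher_rxc_montecarlo(tb, reps = 2e4, seed = 7)
  expect_identical(mc$p_value, mc2$p_value)

  # independent table with large counts -> large p
  tb2 <- matrix(c(40, 60, 42, 58, 39, 61), nrow = 2)
  expect_gt(fisher_rxc_montecarlo(tb2, reps = 1e4, seed = 1)$p_value, 0.5)

  expect_error(fisher_rxc_montecarlo(tb, reps = 100, seed = 1), ">= 1e4")
})

test_that("univariate logistic OR equals the contingency cross-product", {
  set.seed(51)
  for (i in 1:25) {
    cells <- rpois(4, 15) + 1L
    x <- rep(c(1, 1, 0, 0), cells)
    y <- rep(c(1, 0, 1, 0), cells)
    mdl <- univariate_logistic(x, y)
    expect_equal(mdl$terms$or,
                 (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-6)
    # Wald CI arithmetic: exp(beta +/- 1.96 SE)
    expect_equal(mdl$terms$or_lo,
                 exp(mdl$terms$beta - 1.96 * mdl$terms$se))
  }
})

test_that("continuous-predictor logistic fit matches glm and flags
           separation", {
  set.seed(52)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(-0.3 + 0.8 * x))
  mdl <- univariate_logistic(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(mdl$terms$beta, unname(coef(ref)[2]), tolerance = 1e-8)
  expect_equal(mdl$log_likelihood, as.numeric(logLik(ref)),
               tolerance = 1e-8)

  # perfect separation -> explicit error, not a huge OR
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- xs
  expect_error(univariate_logistic(xs, ys), "separation|zero cell")
  xc <- sort(rnorm(40))
  yc <- as.integer(seq_along(xc) > 20)
  expect_error(univariate_logistic(xc, yc), "separation")
})

test_that("stepwise selection admits true predictors and resists noise", {
  # strong binary predictor among noise candidates: admitted in >= 95/100
  # replicates, while noise terms enter only at the family-wise false-
  # admission rate (~3 candidates x 5%)
  hit <- 0L; extra <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- 300
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + log(5) * x))
    cand <- data.frame(signal = x,
                       noise_a = rnorm(n), noise_b = rnorm(n),
                       noise_c = rbinom(n, 1, 0.5))
    mdl <- suppressWarnings(stepwise_logistic(cand, y))
    if ("signal" %in% mdl$terms$term) hit <- hit + 1L
    extra <- extra + sum(mdl$terms$term != "signal")
  }
  expect_gte(hit, 95)
  expect_lt(extra / 100, 0.35)

  # all-noise candidates: intercept-only in most replicates
  null_only <- 0L
  for (s in 1:60) {
    set.seed(3000 + s)
    n <- 200
    y <- rbinom(n, 1, 0.4)
    cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                       d = rbinom(n, 1, 0.5))
    mdl <- suppressWarnings(stepwise_logistic(cand, y))
    if (nrow(mdl$terms) == 0L) null_only <- null_only + 1L
  }
  expect_gt(null_only / 60, 0.6)

  # collinear duplicate: exactly one admitted, lexicographic tie-break
  set.seed(60)
  x <- rbinom(300, 1, 0.5)
  y <- rbinom(300, 1, plogis(-0.5 + 1.5 * x))
  cand <- data.frame(b_copy = x, a_orig = x)
  mdl <- suppressWarnings(stepwise_logistic(cand, y))
  expect_identical(mdl$terms$term, "a_orig")
})

test_that("ROC analysis matches hand counts and pairwise oracle", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$cutoff, 3)                # smallest cutoff at max J

  expect_equal(roc_analysis(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc, 0.75)

  # ties contribute 1/2; matches brute-force pair counting
  set.seed(71)
  for (i in 1:50) {
    sc <- sample(1:6, 40, replace = TRUE)   # heavy ties
    lb <- rbinom(40, 1, 0.45)
    if (length(unique(lb)) < 2) next
    r2 <- roc_analysis(sc, lb)
    oracle <- auc_pairs(sc, lb)
    expect_equal(r2$auc, max(oracle, 1 - oracle), tolerance = 1e-12)
  }

  # accuracy identity at the chosen cutoff
  set.seed(72)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.5)
  r3 <- roc_analysis(sc, lb)
  cts <- r3$counts
  expect_equal(r3$accuracy,
               100 * (cts["tp"] + cts["tn"]) / sum(cts),
               ignore_attr = TRUE)
  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("AUC orientation flips when the raw AUC is below 0.5", {
  set.seed(73)
  sc <- c(rnorm(30, 1), rnorm(30, 0))      # higher score in controls
  lb <- rep(c(0, 1), each = 30)
  r <- roc_analysis(sc, lb)
  expect_gte(r$auc, 0.5)
  expect_identical(r$direction, "<=")
})

test_that("DeLong test is antisymmetric, null on identical scores, and its
           variance matches the jackknife", {
  set.seed(81)
  n <- 40
  lb <- rep(c(0, 1), each = n / 2)
  s_a <- rnorm(n) + lb * 1.2
  s_b <- 0.6 * s_a + rnorm(n, sd = 0.8)

  same <- delong_test(s_a, s_a, lb)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  d1 <- delong_test(s_a, s_b, lb)
  d2 <- delong_test(s_b, s_a, lb)
  expect_equal(d1$z, -d2$z, tolerance = 1e-12)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)

  vjack <- delong_var_jackknife(s_a, s_b, lb)
  expect_lt(abs(d1$var_diff - vjack) / vjack, 0.10)
})

test_that("in-package ROC and DeLong agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(91)
  n <- 80
  lb <- rbinom(n, 1, 0.45)
  sc <- rnorm(n) + lb
  sc2 <- 0.5 * sc + rnorm(n)
  r <- roc_analysis(sc, lb)
  pr <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  expect_equal(r$se_delong^2, pROC::var(pr, method = "delong"),
               tolerance = 1e-8)
  d <- delong_test(sc, sc2, lb)
  pd <- pROC::roc.test(pROC::roc(lb, sc, quiet = TRUE, direction = "<"),
                       pROC::roc(lb, sc2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(d$p_value, pd$p.value, tolerance = 1e-8)
})
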