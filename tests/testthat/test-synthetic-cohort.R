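test_that("conditional generator recovers its class-conditional
           probabilities at large n", {
  spec <- cohort_spec(n_patients = 1e5, seed = 5)
  co <- generate_cohort_conditional(spec)
  for (nm in c("er_positive", "pr_positive", "her2_positive", "ki67_high")) {
    cc <- spec$categorical[[nm]]
    p1 <- mean(co[[nm]][co$pcr == 1])
    p0 <- mean(co[[nm]][co$pcr == 0])
    expect_lt(abs(p1 - cc$p_pcr), 0.01)
    expect_lt(abs(p0 - cc$p_nonpcr), 0.01)
  }
  # multi-level subtype conditionals
  st <- prop.table(table(co$subtype[co$pcr == 1]))
  expect_lt(max(abs(st - spec$categorical$subtype$p_pcr)), 0.01)
  # feature class means within Monte-Carlo error
  f <- spec$features$mtr_p5
  expect_lt(abs(mean(co$mtr_p5[co$pcr == 1]) - f$mean_pcr), 0.05)
  expect_lt(abs(sd(co$mtr_p5[co$pcr == 0]) - f$sd_nonpcr), 0.05)
})

test_that("null cohorts give uniform comparison p-values", {
  # equal group means, rho = 0: compare_groups p ~ U(0,1) across seeds
  feats <- list(f1 = list(mean_pcr = 0, sd_pcr = 1, mean_nonpcr = 0,
                          sd_nonpcr = 1, block = "f"))
  ps <- vapply(1:2000, function(s) {
    spec <- cohort_spec(n_patients = 40, prevalence = 0.5,
                        categorical = list(), features = feats,
                        rho = 0, seed = s)
    co <- generate_cohort_conditional(spec)
    if (min(table(co$pcr)) < 3) return(NA_real_)
    compare_groups(co$f1, co$pcr)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  # p-values from the rank branch are discrete, so ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("voxel-derived mode yields internally consistent percentile
           features", {
  spec <- cohort_spec(n_patients = 40, seed = 9)
  co <- generate_cohort_conditional(spec, mode = "voxel_derived")
  pc <- as.matrix(co[, c("mtr_p5", "mtr_p10", "mtr_p15", "mtr_p25",
                         "mtr_p50", "mtr_p75", "mtr_p85")])
  expect_true(all(apply(pc, 1, function(r) all(diff(r) >= 0))))
  expect_equal(co$mtr_iqr, co$mtr_p75 - co$mtr_p25, tolerance = 1e-12)
})

test_that("generators are seed-deterministic", {
  spec <- cohort_spec(n_patients = 500, seed = 33)
  expect_identical(generate_cohort_conditional(spec),
                   generate_cohort_conditional(spec))
  spec_l <- cohort_spec(n_patients = 500, seed = 33,
                        logistic = c("(Intercept)" = -0.5,
                                     her2_positive = log(3)))
  expect_identical(generate_cohort_logistic(spec_l),
                   generate_cohort_logistic(spec_l))
})

test_that("logistic-outcome generator hits the null prevalence and
           recovers coefficients", {
  # all-zero coefficients -> prevalence 1/2
  spec0 <- cohort_spec(n_patients = 1e5, seed = 13,
                       logistic = c("(Intercept)" = 0))
  co0 <- generate_cohort_logistic(spec0)
  expect_lt(abs(mean(co0$pcr) - 0.5), 0.005)

  # binary truth log(7.25): median fitted OR near truth, CI coverage high
  ors <- numeric(60); cover <- logical(60)
  for (s in 1:60) {
    spec <- cohort_spec(n_patients = 2000, seed = 7000 + s,
                        logistic = c("(Intercept)" = -1,
                                     her2_positive = log(7.25)))
    co <- generate_cohort_logistic(spec)
    mdl <- univariate_logistic(co$her2_positive, co$pcr, "her2")
    ors[s] <- mdl$terms$or
    cover[s] <- log(7.25) >= mdl$terms$beta - 1.96 * mdl$terms$se &&
      log(7.25) <= mdl$terms$beta + 1.96 * mdl$terms$se
  }
  expect_gt(median(ors), 6.5)
  expect_lt(median(ors), 8.1)
  expect_gte(mean(cover), 0.90)

  # continuous truth log(1.35)
  spec_c <- cohort_spec(n_patients = 2000, seed = 77,
                        logistic = c("(Intercept)" = -0.5,
                                     mtr_p5 = log(1.35)))
  co_c <- generate_cohort_logistic(spec_c)
  mdl_c <- univariate_logistic(co_c$mtr_p5, co_c$pcr, "mtr_p5")
  expect_gt(log(1.35), mdl_c$terms$beta - 1.96 * mdl_c$terms$se)
  expect_lt(log(1.35), mdl_c$terms$beta + 1.96 * mdl_c$terms$se)
})

test_that("full pipeline finds planted structure and is deterministic", {
  spec <- cohort_spec(n_patients = 300, seed = 55,
                      logistic = c("(Intercept)" = -0.9,
                                   er_positive = log(0.16),
                                   her2_positive = log(7.25),
                                   mtr_p5 = log(1.35)))
  co <- generate_cohort_logistic(spec)
  res <- suppressWarnings(run_full_pipeline(co, seed = 2))
  expect_true(all(c("er_positive", "her2_positive", "mtr_p5") %in%
                    res$multivariate$term))
  comb <- res$roc[res$roc$predictor == "combined_model", ]
  singles <- res$roc[res$roc$predictor != "combined_model", ]
  expect_true(all(comb$auc > singles$auc))

  res2 <- suppressWarnings(run_full_pipeline(co, seed = 2))
  res$model <- res2$model <- NULL          # glm objects carry environments
  expect_identical(res, res2)

  # written report is byte-identical across runs
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  r <- suppressWarnings(run_full_pipeline(co, seed = 2))
  write_report(r, d1); write_report(r, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("all-null cohorts usually yield no independent predictor", {
  none <- 0L
  for (s in 1:30) {
    spec <- cohort_spec(n_patients = 150, seed = 9000 + s,
                        categorical = list(
                          a_bin = list(p_pcr = 0.5, p_nonpcr = 0.5),
                          b_bin = list(p_pcr = 0.3, p_nonpcr = 0.3)),
                        features = list(
                          f1 = list(mean_pcr = 0, sd_pcr = 1,
                                    mean_nonpcr = 0, sd_nonpcr = 1,
                                    block = "f"),
                          f2 = list(mean_pcr = 0, sd_pcr = 1,
                                    mean_nonpcr = 0, sd_nonpcr = 1,
                                    block = "f")),
                        rho = 0)
    co <- generate_cohort_conditional(spec)
    res <- suppressWarnings(run_full_pipeline(co, seed = 3))
    if (nrow(res$multivariate) == 0L) none <- none + 1L
  }
  expect_gt(none / 30, 0.6)
})

test_that("pipeline rejects degenerate cohorts", {
  co <- data.frame(patient_id = c("a", "b"), pcr = c(1, 1), f = c(1, 2))
  expect_error(run_full_pipeline(co), "single outcome class")
})
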