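#!/usr/bin/env Rscript
# Step 5 — the full statistical chain.
#
# Part A reproduces the reference cohort's categorical statistics and
# univariate odds ratios exactly from its printed 2x2 counts (these numbers
# are fully determined by the counts, so they are recomputable without
# patient-level data).
# Part B runs the complete pipeline — group comparisons, categorical tests,
# univariate screen, forward-stepwise multivariate logistic regression,
# ROC and DeLong comparisons — on the synthetic cohort from step 4.

library(aptnac)

out_dir <- "results/05_stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## Part A: count-determined reference statistics -----------------------------
ref <- list(
  er          = c(11, 43, 32, 22),
  pr          = c(10, 34, 33, 31),
  her2        = c(26, 14, 17, 51),
  ki67        = c(42, 54, 1, 11),
  lymph_node  = c(26, 40, 17, 25),
  hist_grade  = c(31, 45, 12, 20),
  enh_pattern = c(35, 58, 8, 7))

rows <- lapply(names(ref), function(nm) {
  cells <- ref[[nm]]
  ct <- chi_square_2x2(contingency_2x2(cells[1], cells[2],
                                       cells[3], cells[4]))
  or <- if (nm %in% c("er", "pr", "her2", "ki67")) {
    x <- rep(c(1, 1, 0, 0), cells); y <- rep(c(1, 0, 1, 0), cells)
    m <- univariate_logistic(x, y, nm)
    round(m$terms$or, 2)
  } else NA_real_
  data.frame(variable = nm, chisq = round(ct$statistic, 3),
             yates = ct$correction_applied, p = signif(ct$p_value, 3),
             univariate_or = or)
})
ref_tab <- do.call(rbind, rows)
write.csv(ref_tab, file.path(out_dir, "reference_count_statistics.csv"),
          row.names = FALSE)
cat("count-determined reference statistics:\n")
print(ref_tab, row.names = FALSE)

## Part B: full pipeline on the synthetic cohort -----------------------------
cohort_file <- "results/04_cohort/cohort_synthetic.csv"
if (!file.exists(cohort_file)) stop("run analysis/04_simulate_cohort.R first")
cohort <- read_cohort_csv(cohort_file)
res <- suppressWarnings(run_full_pipeline(cohort, seed = 501))
write_report(res, file.path(out_dir, "synthetic_cohort_report"))
print(res)
cat("report tables written under", file.path(out_dir,
                                             "synthetic_cohort_report"), "\n")
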