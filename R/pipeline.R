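#' Run the full pre-treatment pCR prediction analysis on a cohort
#'
#' Executes, in order: (1) categorical tests of every factor against the
#' response label (expected-count-gated chi-square for binary factors,
#' Monte-Carlo Fisher for multi-level factors); (2) distribution-gated
#' two-group comparison of every imaging feature; (3) a univariate logistic
#' screen of every variable significant at `alpha`; (4) forward-stepwise
#' multivariate logistic regression over the univariate-significant set;
#' (5) ROC analysis of each selected independent predictor and of the
#' combined model's linear predictor; and (6) DeLong comparison of the
#' combined model against each single predictor. Deterministic given
#' (cohort, config).
#'
#' @param cohort `data.frame` with a binary `pcr` column, categorical
#'   predictor columns (integer 0/1 or factor) and numeric feature columns.
#' @param alpha Significance gate for the screening stages (default 0.05).
#' @param p_enter,p_remove Stepwise thresholds.
#' @param mc_reps,seed Monte-Carlo settings for multi-level factor tests.
#' @param id_cols Columns to ignore as identifiers.
#' @return List of class `pcr_analysis` with data.frames
#'   `categorical_tests`, `group_comparisons`, `univariate`,
#'   `multivariate` (term table), `roc` (one row per predictor + combined),
#'   `delong` (combined vs each predictor), the fitted `model`, and
#'   `n_tests` (count of hypothesis tests run; no multiplicity adjustment
#'   is applied).
#' @export
run_full_pipeline <- function(cohort, alpha = 0.05, p_enter = 0.05,
                              p_remove = 0.10, mc_reps = 1e4, seed = 1L,
                              id_cols = "patient_id") {
  stopifnot(is.data.frame(cohort), "pcr" %in% names(cohort))
  y <- as_binary_outcome(cohort$pcr)
  if (length(unique(y)) < 2L) stop("cohort contains a single outcome class")
  if (min(table(y)) < 20L)
    warning("fewer than 20 patients in a class; model fit may be unstable")

  vars <- setdiff(names(cohort), c(id_cols, "pcr"))
  is_cat <- vapply(cohort[vars], function(v)
    is.factor(v) || is.logical(v) ||
      (is.numeric(v) && all(v %in% c(0, 1))), logical(1))
  cat_vars <- vars[is_cat]
  num_vars <- vars[!is_cat]
  n_tests <- 0L

  # -- categorical tests ----------------------------------------------------
  cat_rows <- lapply(cat_vars, function(nm) {
    v <- cohort[[nm]]
    if (is.factor(v) && nlevels(v) > 2L) {
      tb <- table(v, y)
      tb <- tb[rowSums(tb) > 0, , drop = FALSE]   # unobserved levels
      if (nrow(tb) < 2L) {
        data.frame(variable = nm, test = "fisher_mc", statistic = NA_real_,
                   p_value = NA_real_, stringsAsFactors = FALSE)
      } else {
        ft <- fisher_rxc_montecarlo(tb, reps = mc_reps, seed = seed)
        data.frame(variable = nm, test = "fisher_mc", statistic = NA_real_,
                   p_value = ft$p_value, stringsAsFactors = FALSE)
      }
    } else {
      vb <- as_predictor(v)
      tb <- table(factor(vb, levels = c(1, 0)), factor(y, levels = c(1, 0)))
      ct <- chi_square_2x2(contingency_2x2(tb[1, 1], tb[1, 2],
                                           tb[2, 1], tb[2, 2]))
      if (ct$fisher_recommended) {
        p <- fisher_exact_2x2(contingency_2x2(tb[1, 1], tb[1, 2],
                                              tb[2, 1], tb[2, 2]))
        data.frame(variable = nm, test = "fisher", statistic = NA_real_,
                   p_value = p, stringsAsFactors = FALSE)
      } else {
        data.frame(variable = nm,
                   test = if (ct$correction_applied) "chisq_yates"
                          else "chisq",
                   statistic = ct$statistic, p_value = ct$p_value,
                   stringsAsFactors = FALSE)
      }
    }
  })
  categorical_tests <- do.call(rbind, cat_rows) %||%
    data.frame(variable = character(0))
  n_tests <- n_tests + nrow(categorical_tests)

  # -- feature comparisons --------------------------------------------------
  cmp_rows <- lapply(num_vars, function(nm) {
    gc <- compare_groups(cohort[[nm]], y)
    s1 <- gc$summaries[["1"]]; s0 <- gc$summaries[["0"]]
    data.frame(variable = nm, test = gc$test_used,
               statistic = gc$statistic, p_value = gc$p_value,
               mean_pcr = s1$mean, sd_pcr = s1$sd,
               median_pcr = s1$median,
               mean_nonpcr = s0$mean, sd_nonpcr = s0$sd,
               median_nonpcr = s0$median, stringsAsFactors = FALSE)
  })
  group_comparisons <- do.call(rbind, cmp_rows) %||%
    data.frame(variable = character(0))
  n_tests <- n_tests + nrow(group_comparisons)

  # -- univariate screen ----------------------------------------------------
  sig_cat <- categorical_tests$variable[
    which(categorical_tests$p_value < alpha)]
  sig_num <- group_comparisons$variable[
    which(group_comparisons$p_value < alpha)]
  screen_vars <- c(sig_cat, sig_num)
  # multi-level factors enter the screen only via binary indicator surrogacy
  screen_vars <- screen_vars[vapply(screen_vars, function(nm) {
    v <- cohort[[nm]]
    !(is.factor(v) && nlevels(v) > 2L)
  }, logical(1))]
  uni_rows <- lapply(screen_vars, function(nm) {
    mdl <- tryCatch(univariate_logistic(cohort[[nm]], y, term_name = nm),
                    error = function(e) NULL)
    if (is.null(mdl)) return(NULL)
    cbind(data.frame(variable = nm, stringsAsFactors = FALSE),
          mdl$terms[, c("beta", "se", "z", "wald_chisq", "p",
                        "or", "or_lo", "or_hi")])
  })
  univariate <- do.call(rbind, uni_rows) %||%
    data.frame(variable = character(0), p = numeric(0))
  n_tests <- n_tests + nrow(univariate)

  # -- stepwise multivariate ------------------------------------------------
  multi_vars <- univariate$variable[univariate$p < alpha]
  if (length(multi_vars) >= 1L) {
    model <- suppressWarnings(
      stepwise_logistic(cohort[multi_vars], y,
                        p_enter = p_enter, p_remove = p_remove))
  } else {
    model <- NULL
  }
  multivariate <- if (!is.null(model)) model$terms else
    data.frame(term = character(0))

  # -- ROC + DeLong ---------------------------------------------------------
  roc_rows <- list(); delong_rows <- list()
  if (!is.null(model) && nrow(model$terms) > 0) {
    sel <- model$terms$term
    lp <- as.numeric(stats::predict(model$fit, type = "link"))
    combined <- roc_analysis(lp, y)
    roc_rows[["combined"]] <- roc_row("combined_model", combined)
    for (nm in sel) {
      rs <- roc_analysis(as_predictor(cohort[[nm]]), y)
      roc_rows[[nm]] <- roc_row(nm, rs)
      dl <- tryCatch(delong_test(lp, as_predictor(cohort[[nm]]), y),
                     error = function(e) NULL)
      if (!is.null(dl))
        delong_rows[[nm]] <- data.frame(
          comparison = paste0("combined_vs_", nm), z = dl$z,
          p_value = dl$p_value, auc_combined = dl$auc_a,
          auc_single = dl$auc_b, stringsAsFactors = FALSE)
      n_tests <- n_tests + 1L
    }
  }
  roc <- do.call(rbind, roc_rows) %||% data.frame(predictor = character(0))
  delong <- do.call(rbind, delong_rows) %||%
    data.frame(comparison = character(0))
  rownames(roc) <- rownames(delong) <- NULL

  structure(list(categorical_tests = categorical_tests,
                 group_comparisons = group_comparisons,
                 univariate = univariate, multivariate = multivariate,
                 model = model, roc = roc, delong = delong,
                 n_tests = n_tests,
                 config = list(alpha = alpha, p_enter = p_enter,
                               p_remove = p_remove, mc_reps = mc_reps,
                               seed = seed)),
            class = "pcr_analysis")
}

roc_row <- function(name, rs) {
  data.frame(predictor = name, auc = rs$auc, se = rs$se_delong,
             ci_lo = rs$ci95[1], ci_hi = rs$ci95[2],
             cutoff = rs$cutoff, direction = rs$direction,
             sensitivity = rs$sensitivity, specificity = rs$specificity,
             accuracy = rs$accuracy, stringsAsFactors = FALSE)
}

#' @export
print.pcr_analysis <- function(x, ...) {
  cat("pCR prediction analysis\n")
  cat(sprintf("  %d categorical tests, %d feature comparisons, %d univariate fits (no multiplicity adjustment; %d tests total)\n",
              nrow(x$categorical_tests), nrow(x$group_comparisons),
              nrow(x$univariate), x$n_tests))
  if (!is.null(x$model) && nrow(x$multivariate) > 0) {
    cat("  independent predictors:",
        paste(x$multivariate$term, collapse = ", "), "\n")
    comb <- x$roc[x$roc$predictor == "combined_model", ]
    if (nrow(comb))
      cat(sprintf("  combined model AUC = %.3f (%.3f-%.3f)\n",
                  comb$auc, comb$ci_lo, comb$ci_hi))
  } else {
    cat("  no independent predictor selected\n")
  }
  invisible(x)
}

#' Write the analysis report bundle
#'
#' Emits one CSV per result table plus a short markdown summary. Re-running
#' on the same analysis object produces byte-identical files.
#'
#' @param analysis A [run_full_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "pcr_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(categorical_tests = analysis$categorical_tests,
                 group_comparisons = analysis$group_comparisons,
                 univariate = analysis$univariate,
                 multivariate = analysis$multivariate,
                 roc = analysis$roc, delong = analysis$delong)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(round_numeric(tables[[nm]], 6), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  md <- file.path(dir, "summary.md")
  con <- file(md, "w"); on.exit(close(con))
  writeLines(c(
    "# pCR prediction analysis summary", "",
    sprintf("- hypothesis tests run: %d (unadjusted)", analysis$n_tests),
    sprintf("- univariate-significant variables: %s",
            paste(analysis$univariate$variable[
              analysis$univariate$p < analysis$config$alpha],
              collapse = ", ") %||% "none"),
    sprintf("- independent predictors: %s",
            if (nrow(analysis$multivariate))
              paste(analysis$multivariate$term, collapse = ", ")
            else "none"),
    if (nrow(analysis$roc)) {
      comb <- analysis$roc[analysis$roc$predictor == "combined_model", ]
      sprintf("- combined model AUC: %.3f (95%% CI %.3f-%.3f)",
              comb$auc, comb$ci_lo, comb$ci_hi)
    } else "- no combined model"), con)
  invisible(c(paths, md))
}

round_numeric <- function(df, digits) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  df
}
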