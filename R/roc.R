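# ROC analysis and DeLong comparison of correlated AUCs.
#
# AUC is computed by the tie-aware Mann-Whitney identity (equivalent to the
# trapezoidal rule over all thresholds); variance and covariance use
# DeLong's placement-value (structural-component) estimator.

# placement values: for each case, the fraction of controls it exceeds
# (ties count 1/2); and symmetrically for controls.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1L]   # cases (pCR)
  y <- scores[labels == 0L]   # controls
  m <- length(x); n <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  rx <- r[seq_len(m)]
  ry <- r[m + seq_len(n)]
  auc <- (sum(rx) - m * (m + 1) / 2) / (m * n)
  # V10_i = mean_j psi(x_i, y_j) ; V01_j = mean_i psi(x_i, y_j)
  v10 <- (rx - rank(x, ties.method = "average")) / n
  v01 <- 1 - (ry - rank(y, ties.method = "average")) / m
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC analysis with DeLong standard error and Youden cutoff
#'
#' AUC via the tie-aware Mann-Whitney identity; SE and 95% CI by DeLong's
#' placement-value estimator; operating point at the cutoff maximizing
#' Youden's J (`sens + spec - 1`), ties resolved to the smallest cutoff,
#' with the orientation "score >= cutoff predicts the event". When the raw
#' AUC is below 0.5 the score is flipped (recorded in `direction`).
#'
#' @param scores Numeric predictor values.
#' @param labels Binary outcome (1/TRUE = event).
#' @return Object of class `roc_result`: `auc`, `se_delong`, `ci95`,
#'   `cutoff`, `direction` (">=" or "<="), `sensitivity`, `specificity`,
#'   `accuracy` (percent), `youden`, and `counts` (tp, fn, tn, fp).
#' @examples
#' roc_analysis(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc    # 0.75
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as_binary_outcome(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L) stop("both classes must be present")

  flipped <- FALSE
  pl <- delong_placements(scores, labels)
  if (pl$auc < 0.5) {
    flipped <- TRUE
    scores <- -scores
    pl <- delong_placements(scores, labels)
  }
  var_auc <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  se <- sqrt(var_auc)
  ci <- pmin(pmax(pl$auc + c(-1.96, 1.96) * se, 0), 1)

  # Youden scan over unique thresholds, orientation: score >= c -> event
  thr <- sort(unique(scores))
  n1 <- pl$m; n0 <- pl$n
  stat <- vapply(thr, function(cu) {
    pred <- scores >= cu
    tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
    c(tp / n1 + (n0 - fp) / n0 - 1, tp, fp)
  }, numeric(3))
  j <- stat[1, ]
  best <- which(j >= max(j) - 1e-12)[1L]     # smallest cutoff at max J
  cutoff <- thr[best]
  tp <- stat[2, best]; fp <- stat[3, best]
  fn <- n1 - tp; tn <- n0 - fp

  structure(list(
    auc = pl$auc, se_delong = se, ci95 = ci,
    cutoff = if (flipped) -cutoff else cutoff,
    direction = if (flipped) "<=" else ">=",
    sensitivity = 100 * tp / n1,
    specificity = 100 * tn / n0,
    accuracy = 100 * (tp + tn) / (n1 + n0),
    youden = j[best],
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (SE %.4f, 95%% CI %.3f-%.3f)\n",
    x$auc, x$se_delong, x$ci95[1], x$ci95[2]))
  cat(sprintf(
    "  cutoff %s %.4g: sens %.2f%%, spec %.2f%%, acc %.2f%% (tp %d fn %d tn %d fp %d)\n",
    x$direction, x$cutoff, x$sensitivity, x$specificity, x$accuracy,
    x$counts["tp"], x$counts["fn"], x$counts["tn"], x$counts["fp"]))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two predictors scored on the same subjects:
#' `z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov)` with variance and
#' covariance from the placement-value components; two-sided normal p.
#'
#' @param scores_a,scores_b Numeric score vectors over the same subjects.
#' @param labels Binary outcome (1 = event).
#' @return List: `z`, `p_value`, `auc_a`, `auc_b`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as_binary_outcome(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("paired design: equal-length score vectors are required")
  ok <- is.finite(scores_a) & is.finite(scores_b) & !is.na(labels)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    pa <- delong_placements(scores_a, labels)
    return(list(z = 0, p_value = 1, auc_a = pa$auc, auc_b = pa$auc,
                var_diff = 0))
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  smat <- s10 / pa$m + s01 / pa$n
  var_diff <- smat[1, 1] + smat[2, 2] - 2 * smat[1, 2]
  if (var_diff <= 0)
    stop("zero variance of the AUC difference")
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff)
}
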