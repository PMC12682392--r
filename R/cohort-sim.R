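# Synthetic patient-level cohort generator.
#
# Two generative modes with different uses:
#  * conditional-on-label: draw the response label first, then IHC
#    categoricals and imaging features from class-conditional distributions
#    (the structure summarised by a clinical baseline table) — tests the
#    comparison / screening stage.
#  * logistic-outcome: draw covariates marginally, then the label from
#    P(pCR) = expit(b0 + b'x) — tests coefficient recovery of the model fit.

#' Cohort generator specification
#'
#' Defaults encode the class-conditional structure of a reference cohort of
#' 108 breast-cancer patients treated with neoadjuvant chemotherapy (43 pCR,
#' 65 non-pCR): conditional probabilities of the IHC categoricals given
#' response class, and class-conditional means/SDs of the MTRasym and ADC
#' histogram features. Rows reported as median(IQR) in the reference are
#' approximated as normal with mean = median and sd = IQR/1.349.
#'
#' @param n_patients Cohort size.
#' @param prevalence P(pCR) (label-first mode) in (0, 1).
#' @param categorical Named list; each element is
#'   `list(p_pcr = , p_nonpcr = )` for a binary factor, or named probability
#'   vectors over levels for a multi-level factor.
#' @param features Named list; each element
#'   `list(mean_pcr, sd_pcr, mean_nonpcr, sd_nonpcr, block)`; features in
#'   the same `block` share the exchangeable correlation `rho`.
#' @param rho Exchangeable within-block feature correlation in `[0, 1)`.
#' @param logistic Named numeric vector of true log-odds coefficients plus
#'   an `"(Intercept)"` entry, for [generate_cohort_logistic()].
#' @param seed Integer seed (mandatory for generation).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 108,
                        prevalence = 43 / 108,
                        categorical = default_categorical_spec(),
                        features = default_feature_spec(),
                        rho = 0.8,
                        logistic = NULL,
                        seed = 1L) {
  stopifnot(n_patients >= 2, prevalence > 0, prevalence < 1,
            rho >= 0, rho < 1)
  for (nm in names(categorical)) {
    cc <- categorical[[nm]]
    pr <- unlist(cc)
    if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]: ", nm)
  }
  for (nm in names(features)) {
    fs <- features[[nm]]
    if (fs$sd_pcr <= 0 || fs$sd_nonpcr <= 0)
      stop("feature SDs must be positive: ", nm)
  }
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence, categorical = categorical,
                 features = features, rho = rho, logistic = logistic,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_categorical_spec <- function() {
  list(
    er_positive   = list(p_pcr = 11 / 43, p_nonpcr = 43 / 65),
    pr_positive   = list(p_pcr = 10 / 43, p_nonpcr = 34 / 65),
    her2_positive = list(p_pcr = 26 / 43, p_nonpcr = 14 / 65),
    ki67_high     = list(p_pcr = 42 / 43, p_nonpcr = 54 / 65),
    node_positive = list(p_pcr = 26 / 43, p_nonpcr = 40 / 65),
    hg3           = list(p_pcr = 12 / 43, p_nonpcr = 20 / 65),
    postmenopausal = list(p_pcr = 23 / 43, p_nonpcr = 32 / 65),
    subtype = list(
      p_pcr    = c(luminal_a = 1, luminal_b = 11, her2_enriched = 18,
                   tn = 13) / 43,
      p_nonpcr = c(luminal_a = 3, luminal_b = 40, her2_enriched = 5,
                   tn = 17) / 65))
}

#' @rdname cohort_spec
#' @export
default_feature_spec <- function() {
  f <- function(mp, sp, mn, sn, block)
    list(mean_pcr = mp, sd_pcr = sp, mean_nonpcr = mn, sd_nonpcr = sn,
         block = block)
  iqr_sd <- function(q1, q3) (q3 - q1) / 1.349
  list(
    mtr_p5   = f(0.83, 2.22, -0.54, 2.62, "mtr"),
    mtr_p10  = f(1.29, 2.05,  0.06, 2.23, "mtr"),
    mtr_p15  = f(1.59, 1.94,  0.44, 2.03, "mtr"),
    mtr_p25  = f(2.00, 1.80,  0.93, 1.89, "mtr"),
    mtr_p50  = f(2.63, 1.63,  1.74, 1.77, "mtr"),
    mtr_p75  = f(3.20, 1.55,  2.44, 1.78, "mtr"),
    mtr_p85  = f(3.50, 1.56,  2.81, 1.84, "mtr"),
    mtr_mean = f(2.55, 1.69,  1.64, 1.82, "mtr"),
    mtr_rmse = f(3.02, 1.17,  2.57, 1.15, "mtr"),
    mtr_iqr  = f(1.04, iqr_sd(0.76, 1.51),
                 1.35, iqr_sd(0.96, 1.91), "mtr"),
    adc_p1   = f(-0.15, iqr_sd(-0.45, 0.18),
                 -0.36, iqr_sd(-0.57, 0.08), "adc"),
    adc_p10  = f(0.13, iqr_sd(-0.23, 0.53),
                 0.26, iqr_sd(0.04, 0.78), "adc"))
}

# block-diagonal exchangeable correlation: standard normal draws with
# corr rho within each named block
draw_correlated_z <- function(n, blocks, rho) {
  z <- matrix(stats::rnorm(n * length(blocks)), n, length(blocks))
  if (rho > 0) {
    for (bl in unique(blocks)) {
      idx <- which(blocks == bl)
      if (length(idx) > 1L) {
        shared <- stats::rnorm(n)
        z[, idx] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, idx]
      }
    }
  }
  z
}

draw_categorical <- function(cc, lab, n) {
  p1 <- cc$p_pcr; p0 <- cc$p_nonpcr
  if (length(p1) == 1L) {
    p <- ifelse(lab == 1L, p1, p0)
    as.integer(stats::runif(n) < p)
  } else {
    lv <- names(p1)
    out <- character(n)
    for (cls in c(0L, 1L)) {
      sel <- lab == cls
      if (any(sel)) {
        pr <- if (cls == 1L) p1 else p0
        out[sel] <- sample(lv, sum(sel), replace = TRUE, prob = pr)
      }
    }
    factor(out, levels = lv)
  }
}

#' Generate a cohort by drawing covariates conditional on the label
#'
#' Labels are Bernoulli(prevalence); categoricals come from their
#' class-conditional probabilities; features are drawn jointly normal with
#' class-conditional means/SDs and exchangeable within-block correlation
#' `rho`. With `mode = "voxel_derived"` the MTRasym features of each patient
#' are instead computed by [compute_features()] on a per-patient simulated
#' voxel sample (normal mixture with an optional noisier subpopulation), so
#' percentile monotonicity and the IQR identity hold exactly within-patient.
#'
#' @param spec A [cohort_spec()].
#' @param mode `"gaussian"` (default) or `"voxel_derived"`.
#' @return `data.frame` with `patient_id`, `pcr` (0/1), the categorical
#'   columns and the feature columns; attribute `"spec_seed"` records the
#'   seed.
#' @export
generate_cohort_conditional <- function(spec, mode = c("gaussian",
                                                       "voxel_derived")) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  set.seed(spec$seed)
  n <- spec$n_patients
  lab <- as.integer(stats::runif(n) < spec$prevalence)
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)), pcr = lab,
                    stringsAsFactors = FALSE)
  for (nm in names(spec$categorical))
    out[[nm]] <- draw_categorical(spec$categorical[[nm]], lab, n)

  fs <- spec$features
  blocks <- vapply(fs, `[[`, character(1), "block")
  if (mode == "gaussian") {
    z <- draw_correlated_z(n, blocks, spec$rho)
    for (j in seq_along(fs)) {
      f <- fs[[j]]
      mu <- ifelse(lab == 1L, f$mean_pcr, f$mean_nonpcr)
      sdv <- ifelse(lab == 1L, f$sd_pcr, f$sd_nonpcr)
      out[[names(fs)[j]]] <- mu + sdv * z[, j]
    }
  } else {
    # per-patient voxel sample -> first-order features (MTRasym block);
    # non-mtr features still gaussian
    z <- draw_correlated_z(n, blocks, spec$rho)
    for (j in which(blocks != "mtr")) {
      f <- fs[[j]]
      mu <- ifelse(lab == 1L, f$mean_pcr, f$mean_nonpcr)
      sdv <- ifelse(lab == 1L, f$sd_pcr, f$sd_nonpcr)
      out[[names(fs)[j]]] <- mu + sdv * z[, j]
    }
    mtr_cols <- names(fs)[blocks == "mtr"]
    for (cn in mtr_cols) out[[cn]] <- NA_real_
    mfe <- fs[["mtr_mean"]]
    for (i in seq_len(n)) {
      nv <- sample(400:2000, 1L)
      mu_i <- if (lab[i] == 1L) mfe$mean_pcr else mfe$mean_nonpcr
      sd_b <- if (lab[i] == 1L) mfe$sd_pcr else mfe$sd_nonpcr
      centre <- stats::rnorm(1, mu_i, sd_b)
      # within-tumor voxel spread; non-responders get a noisier
      # subpopulation (residual cystic/necrotic voxels)
      vox <- stats::rnorm(nv, centre, 1.3)
      if (lab[i] == 0L) {
        n_noisy <- rbinom(1, nv, 0.10)
        if (n_noisy > 0)
          vox[seq_len(n_noisy)] <- stats::rnorm(n_noisy, centre - 1.5, 2.5)
      }
      fv <- compute_features(vox)
      out$mtr_p5[i] <- fv$p5;  out$mtr_p10[i] <- fv$p10
      out$mtr_p15[i] <- fv$p15; out$mtr_p25[i] <- fv$p25
      out$mtr_p50[i] <- fv$p50; out$mtr_p75[i] <- fv$p75
      out$mtr_p85[i] <- fv$p85; out$mtr_mean[i] <- fv$mean
      out$mtr_rmse[i] <- fv$rms; out$mtr_iqr[i] <- fv$iqr
    }
  }
  attr(out, "spec_seed") <- spec$seed
  out
}

#' Generate a cohort from a true logistic model
#'
#' Covariates are drawn marginally (binary factors at their pooled
#' prevalence, features as pooled normals); the outcome is Bernoulli with
#' `P(pCR) = expit(b0 + b'x)` using `spec$logistic`. This is the mode used
#' for coefficient-recovery testing.
#'
#' @param spec A [cohort_spec()] whose `logistic` element names the true
#'   coefficients (subset of covariate columns) and `"(Intercept)"`.
#' @return `data.frame` as in [generate_cohort_conditional()], with
#'   attribute `"true_beta"`.
#' @export
generate_cohort_logistic <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  beta <- spec$logistic
  if (is.null(beta) || is.null(names(beta)))
    stop("spec$logistic must be a named coefficient vector")
  if (any(!is.finite(beta))) stop("coefficients must be finite")
  set.seed(spec$seed)
  n <- spec$n_patients
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  # marginal draws: mixture of the class-conditionals at the spec prevalence
  pv <- spec$prevalence
  for (nm in names(spec$categorical)) {
    cc <- spec$categorical[[nm]]
    if (length(cc$p_pcr) == 1L) {
      p <- pv * cc$p_pcr + (1 - pv) * cc$p_nonpcr
      out[[nm]] <- as.integer(stats::runif(n) < p)
    } else {
      pr <- pv * cc$p_pcr + (1 - pv) * cc$p_nonpcr
      out[[nm]] <- factor(sample(names(pr), n, TRUE, prob = pr),
                          levels = names(pr))
    }
  }
  fs <- spec$features
  blocks <- vapply(fs, `[[`, character(1), "block")
  z <- draw_correlated_z(n, blocks, spec$rho)
  for (j in seq_along(fs)) {
    f <- fs[[j]]
    mu <- pv * f$mean_pcr + (1 - pv) * f$mean_nonpcr
    sdv <- sqrt(pv * f$sd_pcr^2 + (1 - pv) * f$sd_nonpcr^2)
    out[[names(fs)[j]]] <- mu + sdv * z[, j]
  }
  eta <- rep(unname(beta["(Intercept)"]) %||% 0, n)
  for (nm in setdiff(names(beta), "(Intercept)")) {
    if (!nm %in% names(out)) stop("unknown coefficient term: ", nm)
    eta <- eta + beta[[nm]] * as_predictor(out[[nm]])
  }
  out$pcr <- as.integer(stats::runif(n) < stats::plogis(eta))
  out <- out[, c("patient_id", "pcr",
                 setdiff(names(out), c("patient_id", "pcr")))]
  attr(out, "true_beta") <- beta
  attr(out, "spec_seed") <- spec$seed
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
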