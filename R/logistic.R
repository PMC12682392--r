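# Logistic regression surface: maximum-likelihood fits with Wald inference
# (Table-style beta / SE / z / OR / 95% CI reporting), explicit separation
# handling, and forward-stepwise selection by likelihood-ratio p-values.

fit_logistic_glm <- function(formula, data) {
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  if (warned_sep && any(abs(coefs[-1]) > 10, na.rm = TRUE))
    stop("perfect separation: maximum-likelihood estimate does not exist")
  fit
}

logistic_term_table <- function(fit) {
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  tt <- data.frame(
    term = rownames(sm)[keep],
    beta = sm[keep, 1], se = sm[keep, 2],
    z = sm[keep, 3], wald_chisq = sm[keep, 3]^2,
    p = sm[keep, 4],
    or = exp(sm[keep, 1]),
    or_lo = exp(sm[keep, 1] - 1.96 * sm[keep, 2]),
    or_hi = exp(sm[keep, 1] + 1.96 * sm[keep, 2]),
    stringsAsFactors = FALSE)
  rownames(tt) <- NULL
  tt
}

logistic_model <- function(fit, terms) {
  structure(list(
    terms = terms,
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    log_likelihood = as.numeric(stats::logLik(fit)),
    n = stats::nobs(fit),
    fit = fit), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic model (n = %d, logLik = %.3f, intercept = %.3f)\n",
              x$n, x$log_likelihood, x$intercept))
  tt <- x$terms
  if (nrow(tt) == 0) {
    cat("  intercept-only model\n")
  } else {
    tt_p <- data.frame(term = tt$term,
                       beta = round(tt$beta, digits),
                       SE = round(tt$se, digits),
                       z = round(tt$z, digits),
                       p = signif(tt$p, digits),
                       OR = round(tt$or, 2),
                       CI95 = sprintf("(%.2f ~ %.2f)", tt$or_lo, tt$or_hi))
    print(tt_p, row.names = FALSE)
  }
  invisible(x)
}

#' Univariate logistic regression
#'
#' Maximum-likelihood fit of a single predictor (binary factor or
#' continuous) against a binary outcome, reporting beta, SE (observed
#' information), Wald z and its square, p, OR and Wald 95% CI
#' (`exp(beta +/- 1.96 SE)`). Perfect separation and zero cells raise
#' explicit errors rather than returning runaway estimates.
#'
#' @param x Predictor vector (numeric, logical or 2-level factor).
#' @param y Binary outcome (logical, 0/1, or 2-level factor; the second
#'   level / 1 / TRUE is the event).
#' @param term_name Label for the reported term.
#' @return A `logistic_model`.
#' @examples
#' # OR for a binary predictor equals the contingency cross-product ratio
#' x <- rep(c(1, 1, 0, 0), c(11, 43, 32, 22))
#' y <- rep(c(1, 0, 1, 0), c(11, 43, 32, 22))
#' univariate_logistic(x, y)$terms$or    # (11*22)/(43*32) = 0.176
#' @export
univariate_logistic <- function(x, y, term_name = "x") {
  y <- as_binary_outcome(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  xb <- as_predictor(x)
  if (length(unique(xb)) == 2L) {
    tab <- table(xb, y)
    if (any(tab == 0))
      stop("zero cell for binary predictor: model does not converge")
  }
  df <- data.frame(.y = y, x = xb)
  names(df)[2] <- term_name
  fit <- fit_logistic_glm(stats::as.formula(paste(".y ~", term_name)), df)
  logistic_model(fit, logistic_term_table(fit))
}

as_binary_outcome <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("outcome must have exactly 2 levels")
    as.integer(y) - 1L
  } else if (is.logical(y)) {
    as.integer(y)
  } else {
    yv <- as.numeric(y)
    if (!all(yv %in% c(0, 1))) stop("outcome must be binary (0/1)")
    as.integer(yv)
  }
}

as_predictor <- function(x) {
  if (is.factor(x)) {
    if (nlevels(x) != 2L)
      stop("factor predictors must have exactly 2 levels")
    as.integer(x) - 1L
  } else if (is.logical(x)) as.integer(x) else as.numeric(x)
}

#' Multivariate logistic regression (all terms, no selection)
#'
#' Maximum-likelihood fit of every supplied predictor jointly, with the
#' same Wald reporting as [univariate_logistic()]. Used for coefficient
#' recovery checks and for scoring a fixed predictor set; use
#' [stepwise_logistic()] when the predictor set itself is to be selected.
#'
#' @param predictors `data.frame` of predictor columns.
#' @param y Binary outcome.
#' @return A `logistic_model`.
#' @export
multivariate_logistic <- function(predictors, y) {
  stopifnot(is.data.frame(predictors), ncol(predictors) >= 1L)
  y <- as_binary_outcome(y)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  df <- as.data.frame(lapply(predictors, as_predictor))
  names(df) <- names(predictors)
  df$.y <- y
  fit <- fit_logistic_glm(
    stats::as.formula(paste(".y ~", paste(names(predictors),
                                          collapse = " + "))), df)
  logistic_model(fit, logistic_term_table(fit))
}

#' Forward-stepwise multivariate logistic regression
#'
#' Forward selection by likelihood-ratio test: at each step the candidate
#' with the smallest LR p-value (ties broken lexicographically by name)
#' enters if `p < p_enter`; after each admission every included term is
#' re-tested and dropped if its LR p exceeds `p_remove`. Deterministic.
#'
#' @param candidates `data.frame` of candidate predictors (numeric/logical/
#'   2-level factor columns).
#' @param y Binary outcome.
#' @param p_enter,p_remove Entry / removal thresholds (defaults 0.05, 0.10).
#' @return A `logistic_model` with an extra `selection` element tracing
#'   each step; intercept-only (with a warning) if no candidate enters.
#' @export
stepwise_logistic <- function(candidates, y, p_enter = 0.05,
                              p_remove = 0.10) {
  stopifnot(is.data.frame(candidates), ncol(candidates) >= 1L)
  y <- as_binary_outcome(y)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (nrow(candidates) != length(y)) stop("candidates and y lengths differ")
  if (length(y) <= 10 * ncol(candidates))
    warning("fewer than 10 observations per candidate predictor")
  df <- as.data.frame(lapply(candidates, as_predictor))
  names(df) <- names(candidates)
  df$.y <- y

  included <- character(0)
  pool <- sort(names(candidates))     # lexicographic scan order
  trace <- list()

  model_fit <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fit_logistic_glm(stats::as.formula(paste(".y ~", rhs)), df)
  }
  lr_p <- function(fit_small, fit_big) {
    dev <- stats::deviance(fit_small) - stats::deviance(fit_big)
    dfd <- length(stats::coef(fit_big)) - length(stats::coef(fit_small))
    # aliased (collinear) columns contribute no parameters
    dfd <- dfd - sum(is.na(stats::coef(fit_big))) +
      sum(is.na(stats::coef(fit_small)))
    if (dfd <= 0 || dev <= 0) return(1)
    stats::pchisq(dev, dfd, lower.tail = FALSE)
  }

  current <- model_fit(included)
  repeat {
    changed <- FALSE
    # forward scan
    candidates_left <- setdiff(pool, included)
    if (length(candidates_left)) {
      ps <- vapply(candidates_left, function(tm) {
        fit_try <- tryCatch(model_fit(c(included, tm)),
                            error = function(e) NULL)
        if (is.null(fit_try)) return(1)
        lr_p(current, fit_try)
      }, numeric(1))
      best <- candidates_left[which.min(ps)]   # ties -> first in lex order
      if (ps[best] < p_enter) {
        included <- c(included, best)
        current <- model_fit(included)
        trace[[length(trace) + 1L]] <-
          list(action = "add", term = best, p = unname(ps[best]))
        changed <- TRUE
      }
    }
    # backward re-test
    if (length(included) > 1L) {
      repeat {
        ps_rm <- vapply(included, function(tm) {
          lr_p(model_fit(setdiff(included, tm)), current)
        }, numeric(1))
        worst <- included[which.max(ps_rm)]
        if (ps_rm[worst] > p_remove) {
          included <- setdiff(included, worst)
          current <- model_fit(included)
          trace[[length(trace) + 1L]] <-
            list(action = "drop", term = worst, p = unname(ps_rm[worst]))
          changed <- TRUE
          if (length(included) <= 1L) break
        } else break
      }
    }
    if (!changed) break
  }
  if (length(included) == 0L) {
    warning("no candidate met the entry criterion; intercept-only model")
    mdl <- logistic_model(current,
                          logistic_term_table(current)[0, , drop = FALSE])
  } else {
    tt <- logistic_term_table(current)
    tt <- tt[match(included, tt$term), , drop = FALSE]   # selection order
    rownames(tt) <- NULL
    mdl <- logistic_model(current, tt)
  }
  mdl$selection <- trace
  mdl$p_enter <- p_enter
  mdl$p_remove <- p_remove
  mdl
}
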