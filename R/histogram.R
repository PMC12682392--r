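#' Extract whole-tumor ROI voxel values from a parametric map
#'
#' Returns the finite map values where `mask` is 1 and `exclusion_mask`
#' (cystic/necrotic/hemorrhagic areas) is 0. Invalid (`NA`) voxels are
#' dropped; an empty result is an error (tumors below the minimum size are
#' not analysable).
#'
#' @param map A [parametric_map()].
#' @param mask Logical (or 0/1) 3D array congruent with the map.
#' @param exclusion_mask Optional logical 3D array of voxels to exclude.
#' @param patient_id,reader_id Identifiers carried on the sample.
#' @return Object of class `roi_sample`: list with `values`, `source_kind`,
#'   `patient_id`, `reader_id`.
#' @export
extract_roi <- function(map, mask, exclusion_mask = NULL,
                        patient_id = NA_character_,
                        reader_id = NA_character_) {
  stopifnot(inherits(map, "parametric_map"))
  mask <- as_binary_mask(mask, dim(map$values), "mask")
  keep <- mask
  if (!is.null(exclusion_mask)) {
    exclusion_mask <- as_binary_mask(exclusion_mask, dim(map$values),
                                     "exclusion_mask")
    keep <- keep & !exclusion_mask
  }
  v <- map$values[keep]
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    stop("ROI contains no valid voxels")
  structure(list(values = as.numeric(v), source_kind = map$kind,
                 patient_id = patient_id, reader_id = reader_id),
            class = "roi_sample")
}

as_binary_mask <- function(m, dims, what) {
  if (!identical(dim(m), as.integer(dims)) &&
      !identical(dim(m), dims))
    stop(what, " grid is not congruent with the map")
  if (is.logical(m)) return(m)
  u <- unique(as.numeric(m))
  if (!all(u %in% c(0, 1)))
    stop(what, " must be binary (0/1)")
  array(m == 1, dim(m))
}

#' The percentile set reported by [compute_features()]
#' @export
feature_percentiles <- c(1, 5, 10, 15, 25, 50, 75, 85, 90, 95, 99)

#' First-order histogram features of an ROI sample
#'
#' Computes the whole-tumor first-order feature vector: mean; sample SD
#' (n-1); RMS (`sqrt(mean(x^2))`, the "root-mean-square deviation" of
#' first-order radiomics); mean absolute deviation about the mean;
#' percentiles p1..p99 by linear interpolation between order statistics
#' (`h = (n-1)q + 1`); IQR = p75 - p25; skewness and excess kurtosis as
#' bias-uncorrected standardized moments. Moments below their minimum n
#' (sd: 2, skewness: 3, kurtosis: 4) are `NA`.
#'
#' @param sample An [extract_roi()] result, or a bare numeric vector of
#'   finite voxel values.
#' @return One-row `data.frame` of class `histogram_features` with columns
#'   `mean, sd, rms, mad, p1, p5, p10, p15, p25, p50, p75, p85, p90, p95,
#'   p99, iqr, skewness, kurtosis, n_voxels` (plus `patient_id`, `reader_id`,
#'   `source_kind` when extracted from an ROI).
#' @examples
#' f <- compute_features(1:100)
#' f[, c("p25", "p50", "p75", "iqr")]   # 25.75 50.5 75.25 49.5
#' @export
compute_features <- function(sample) {
  if (inherits(sample, "roi_sample")) {
    x <- sample$values
    meta <- data.frame(patient_id = sample$patient_id,
                       reader_id = sample$reader_id,
                       source_kind = sample$source_kind,
                       stringsAsFactors = FALSE)
  } else {
    x <- as.numeric(sample)
    meta <- NULL
  }
  if (length(x) == 0L) stop("empty sample")
  if (any(!is.finite(x))) stop("sample contains non-finite values")
  n <- length(x)
  m <- mean(x)
  qs <- stats::quantile(x, probs = feature_percentiles / 100,
                        type = 7, names = FALSE)
  sdv <- if (n >= 2L) stats::sd(x) else NA_real_
  m2 <- mean((x - m)^2)
  skew <- if (n >= 3L && m2 > 0) mean((x - m)^3) / m2^1.5 else NA_real_
  kurt <- if (n >= 4L && m2 > 0) mean((x - m)^4) / m2^2 - 3 else NA_real_
  out <- data.frame(
    mean = m, sd = sdv, rms = sqrt(mean(x^2)), mad = mean(abs(x - m)),
    p1 = qs[1], p5 = qs[2], p10 = qs[3], p15 = qs[4], p25 = qs[5],
    p50 = qs[6], p75 = qs[7], p85 = qs[8], p90 = qs[9], p95 = qs[10],
    p99 = qs[11], iqr = qs[7] - qs[5], skewness = skew, kurtosis = kurt,
    n_voxels = n)
  if (!is.null(meta)) out <- cbind(meta, out)
  class(out) <- c("histogram_features", "data.frame")
  out
}

feature_columns <- c("mean", "sd", "rms", "mad",
                     paste0("p", feature_percentiles),
                     "iqr", "skewness", "kurtosis")

#' Average two readers' feature vectors
#'
#' Element-wise arithmetic mean of every feature (the per-patient value used
#' for all downstream statistics); `n_voxels` is the floor of the mean count.
#'
#' @param a,b `histogram_features` rows for the same patient and map kind.
#' @return A `histogram_features` row.
#' @export
average_readers <- function(a, b) {
  stopifnot(inherits(a, "histogram_features"),
            inherits(b, "histogram_features"))
  if (!is.null(a$source_kind) && !is.null(b$source_kind) &&
      !identical(a$source_kind, b$source_kind))
    stop("cannot average features of different map kinds")
  if (!is.null(a$patient_id) && !is.null(b$patient_id) &&
      !identical(a$patient_id, b$patient_id))
    stop("cannot average features of different patients")
  out <- a
  for (cn in feature_columns) out[[cn]] <- (a[[cn]] + b[[cn]]) / 2
  out$n_voxels <- floor((a$n_voxels + b$n_voxels) / 2)
  if (!is.null(out$reader_id)) out$reader_id <- "mean"
  out
}

#' Two-way random-effects absolute-agreement single-measure ICC(2,1)
#'
#' Inter-reader agreement from the mean squares of the subject x reader
#' ANOVA decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Values above 0.8 conventionally indicate good agreement.
#'
#' @param measurements Numeric matrix, subjects in rows, readers in columns
#'   (>= 3 subjects, >= 2 readers, no missing cells).
#' @return List with `icc`, mean squares `msr`, `msc`, `mse`, `n_subjects`,
#'   `n_readers`.
#' @export
icc_two_way <- function(measurements) {
  m <- as.matrix(measurements)
  if (any(!is.finite(m))) stop("measurements must be complete and finite")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 readers")
  grand <- mean(m)
  if (sum((m - grand)^2) == 0) stop("zero total variance")
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, msr = msr, msc = msc, mse = mse,
       n_subjects = n, n_readers = k)
}

#' Feature table for a set of maps and reader masks
#'
#' Convenience wrapper: extracts the ROI from each map for each reader mask
#' and stacks the [compute_features()] rows.
#'
#' @param maps Named list of [parametric_map()]s.
#' @param reader_masks Named list of logical masks (one per reader).
#' @param exclusion_mask Optional exclusion mask applied to every extraction.
#' @param patient_id Identifier for all rows.
#' @return `data.frame`, one row per (reader, map).
#' @export
feature_table <- function(maps, reader_masks, exclusion_mask = NULL,
                          patient_id = "p1") {
  rows <- list()
  for (rd in names(reader_masks)) {
    for (mk in names(maps)) {
      roi <- extract_roi(maps[[mk]], reader_masks[[rd]], exclusion_mask,
                         patient_id = patient_id, reader_id = rd)
      rows[[paste(rd, mk)]] <- compute_features(roi)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
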