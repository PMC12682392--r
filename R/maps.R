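#' Construct a parametric map
#'
#' A 3D scalar volume with voxel spacing and a kind tag. `NA` marks voxels
#' where the input data were invalid; they are excluded at ROI extraction,
#' never silently zeroed.
#'
#' @param values 3D numeric array.
#' @param spacing_mm Voxel dimensions in mm (length 3).
#' @param kind One of `"mtrasym_pct"` (%), `"adc_e3"` (x 1e-3 mm^2/s),
#'   `"net_enh"` (signal units).
#' @return Object of class `parametric_map`.
#' @export
parametric_map <- function(values, spacing_mm = c(1, 1, 1),
                           kind = c("mtrasym_pct", "adc_e3", "net_enh")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers")
  structure(list(values = values, spacing_mm = spacing_mm, kind = kind),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  u <- c(mtrasym_pct = "%", adc_e3 = "x 1e-3 mm^2/s", net_enh = "a.u.")[x$kind]
  cat(sprintf("parametric_map <%s> %s, spacing %s mm, %d/%d valid voxels\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              sum(is.finite(x$values)), length(x$values)))
  cat(sprintf("  range of valid voxels: [%g, %g] %s\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)), u))
  invisible(x)
}

#' ADC map from diffusion-weighted volumes
#'
#' Mono-exponential model `S(b) = S(0) * exp(-b * ADC)` fitted per voxel by
#' least squares on `log(S)` versus b-value (for exactly two b-values this is
#' `ADC = log(S_low / S_high) / (b_high - b_low)`). Voxels with any
#' non-positive signal are `NA`.
#'
#' @param signals 4D array `[x, y, z, b]` of DWI signal volumes.
#' @param b_values b-values in s/mm^2, length >= 2, distinct, matching the
#'   4th dimension.
#' @param spacing_mm Voxel spacing.
#' @return A [parametric_map()] of kind `"adc_e3"` in x 1e-3 mm^2/s.
#' @export
compute_adc_map <- function(signals, b_values, spacing_mm = c(1, 1, 1)) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L) stop("at least 2 b-values are required")
  if (anyDuplicated(b_values)) stop("b_values must be distinct")
  d <- dim(signals)
  if (length(d) != 4L || d[4L] != length(b_values))
    stop("signals must be [x, y, z, b] matching b_values")
  nv <- prod(d[1:3])
  s <- matrix(signals, nrow = nv)
  bad <- rowSums(!is.finite(s) | s <= 0) > 0L
  ls <- log(s)
  ls[bad, ] <- NA_real_
  bc <- b_values - mean(b_values)
  slope <- (ls %*% bc) / sum(bc^2)        # d log(S) / d b  = -ADC (mm^2/s)
  adc <- -as.numeric(slope) * 1e3         # x 1e-3 mm^2/s
  adc[bad] <- NA_real_
  dim(adc) <- d[1:3]
  parametric_map(adc, spacing_mm, kind = "adc_e3")
}

#' Net-enhancement (silhouette) map
#'
#' Voxel-wise early post-contrast minus pre-contrast signal ("net increment").
#'
#' @param pre_volume,post_volume 3D arrays of equal shape.
#' @param spacing_mm Voxel spacing.
#' @return A [parametric_map()] of kind `"net_enh"`.
#' @export
compute_net_enhancement <- function(pre_volume, post_volume,
                                    spacing_mm = c(1, 1, 1)) {
  if (!identical(dim(pre_volume), dim(post_volume)))
    stop("pre and post volumes must have identical shape")
  parametric_map(post_volume - pre_volume, spacing_mm, kind = "net_enh")
}
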