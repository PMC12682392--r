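#' Construct a Z-spectrum
#'
#' A Z-spectrum is the saturated water signal as a function of RF saturation
#' frequency offset (ppm relative to water at 0), together with the
#' unsaturated reference signal `s0` acquired far off-resonance.
#'
#' @param offsets_ppm Numeric vector of saturation offsets in ppm, strictly
#'   increasing. The nominal acquisition schedule is
#'   `c(-4.3, -3.5, -2.7, 2.7, 3.5, 4.3)`.
#' @param signals Numeric vector of saturated signal intensities, one per
#'   offset (arbitrary units; `NA` marks an invalid sample).
#' @param s0 Unsaturated reference signal (> 0).
#' @return An object of class `z_spectrum`.
#' @examples
#' z <- z_spectrum(c(-4.3, -3.5, -2.7, 2.7, 3.5, 4.3),
#'                 c(0.70, 0.72, 0.75, 0.73, 0.62, 0.68), s0 = 1)
#' compute_mtrasym(z)
#' @export
z_spectrum <- function(offsets_ppm, signals, s0) {
  offsets_ppm <- as.numeric(offsets_ppm)
  signals <- as.numeric(signals)
  if (length(offsets_ppm) != length(signals))
    stop("offsets_ppm and signals must have equal length")
  if (any(diff(offsets_ppm) <= 0))
    stop("offsets_ppm must be strictly increasing")
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0)
    stop("s0 must be a single positive number")
  if (any(signals < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  structure(list(offsets_ppm = offsets_ppm, signals = signals, s0 = s0),
            class = "z_spectrum")
}

#' @export
print.z_spectrum <- function(x, ...) {
  cat("Z-spectrum:", length(x$offsets_ppm), "offsets,",
      sprintf("s0 = %g", x$s0), "\n")
  print(stats::setNames(x$signals, paste0(x$offsets_ppm, " ppm")))
  invisible(x)
}

#' Estimate the B0 off-resonance shift from multi-echo phase data
#'
#' Fits, per voxel, the least-squares slope of (unwrapped) phase versus echo
#' time; the slope divided by 2*pi is the off-resonance frequency in Hz,
#' converted to ppm by the scanner proton frequency.
#'
#' @param phases Numeric array whose last dimension indexes echoes (a plain
#'   vector is treated as a single voxel), phase in radians.
#' @param echo_times Echo times in seconds, strictly increasing, length >= 3.
#' @param field_mhz Proton resonance frequency in MHz (127.728 at 3 T).
#' @return A list of class `b0_map` with elements `shift_ppm` (array with the
#'   spatial dimensions of `phases`), `freq_hz`, `field_mhz` and `unreliable`
#'   (logical, `|shift| >= 2` ppm).
#' @examples
#' # 100 Hz off-resonance: phase advances 0.2*pi per ms
#' estimate_b0_shift(c(0, 0.2 * pi, 0.4 * pi), c(2, 3, 4) * 1e-3)$shift_ppm
#' @export
estimate_b0_shift <- function(phases, echo_times, field_mhz = 127.728) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 3L)
    stop("at least 3 echo times are required")
  if (any(diff(echo_times) <= 0))
    stop("echo_times must be strictly increasing")
  ne <- length(echo_times)
  if (is.null(dim(phases))) {
    if (length(phases) != ne) stop("phases length must match echo_times")
    ph <- matrix(phases, nrow = 1L)
    spatial_dim <- NULL
  } else {
    d <- dim(phases)
    if (d[length(d)] != ne)
      stop("last dimension of phases must match length(echo_times)")
    spatial_dim <- d[-length(d)]
    ph <- matrix(phases, ncol = ne)
  }
  ph <- unwrap_phase_rows(ph)
  # closed-form least-squares slope of phase vs TE, per voxel
  tc <- echo_times - mean(echo_times)
  slope <- (ph %*% tc) / sum(tc^2)              # rad / s
  freq <- as.numeric(slope) / (2 * pi)          # Hz
  shift <- freq / field_mhz                     # ppm (Hz per MHz)
  if (!is.null(spatial_dim)) {
    dim(shift) <- spatial_dim
    dim(freq) <- spatial_dim
  }
  structure(list(shift_ppm = shift, freq_hz = freq, field_mhz = field_mhz,
                 unreliable = abs(shift) >= 2),
            class = "b0_map")
}

# Row-wise 1D phase unwrapping: add multiples of 2*pi so successive
# differences lie in (-pi, pi].
unwrap_phase_rows <- function(ph) {
  if (ncol(ph) < 2L) return(ph)
  d <- ph[, -1L, drop = FALSE] - ph[, -ncol(ph), drop = FALSE]
  d <- d - 2 * pi * round(d / (2 * pi))
  out <- matrix(0, nrow(ph), ncol(ph))
  out[, 1L] <- ph[, 1L]
  for (j in 2:ncol(ph)) out[, j] <- out[, j - 1L] + d[, j - 1L]
  out
}

#' B0-correct a Z-spectrum by per-branch quadratic interpolation
#'
#' Resamples the measured spectrum at (nominal offset + shift), separately on
#' the negative- and positive-offset branches, using 3-point Lagrange
#' (quadratic) interpolation — exact for signals polynomial of degree <= 2 in
#' offset. Offsets whose shifted target leaves the sampled branch are set to
#' `NA` (the voxel is flagged invalid there, never extrapolated).
#'
#' @param z A [z_spectrum()].
#' @param shift_ppm Scalar water-resonance shift in ppm for this voxel.
#' @return A corrected `z_spectrum` on the same nominal offsets; `s0`
#'   unchanged.
#' @export
correct_z_spectrum <- function(z, shift_ppm) {
  stopifnot(inherits(z, "z_spectrum"))
  if (!is.finite(shift_ppm)) {
    z$signals[] <- NA_real_
    return(z)
  }
  neg <- which(z$offsets_ppm < 0)
  pos <- which(z$offsets_ppm > 0)
  if (length(neg) < 3L || length(pos) < 3L)
    stop("need at least 3 offsets on each side of 0 for quadratic correction")
  half_span <- min(diff(range(z$offsets_ppm[neg])),
                   diff(range(z$offsets_ppm[pos]))) / 2
  if (abs(shift_ppm) > half_span)
    warning("B0 shift exceeds half the sampled branch span; ",
            "edge offsets will be invalid")
  out <- z$signals
  for (idx in list(neg, pos)) {
    xo <- z$offsets_ppm[idx]
    yo <- z$signals[idx]
    target <- z$offsets_ppm[idx] + shift_ppm
    out[idx] <- lagrange3_eval(xo, yo, target)
    # outside the sampled branch -> invalid, not extrapolated
    out[idx][target < min(xo) | target > max(xo)] <- NA_real_
  }
  z$signals <- out
  z
}

# Quadratic Lagrange interpolation through up to the 3 nearest nodes.
# xo must be sorted; uses the 3-node window containing/nearest each target.
lagrange3_eval <- function(xo, yo, t) {
  n <- length(xo)
  if (n == 3L) {
    i1 <- rep(1L, length(t))
  } else {
    # window start: nearest 3 consecutive nodes
    i1 <- findInterval(t, xo)
    i1 <- pmin(pmax(i1 - 1L, 1L), n - 2L)
  }
  x1 <- xo[i1]; x2 <- xo[i1 + 1L]; x3 <- xo[i1 + 2L]
  y1 <- yo[i1]; y2 <- yo[i1 + 1L]; y3 <- yo[i1 + 2L]
  l1 <- (t - x2) * (t - x3) / ((x1 - x2) * (x1 - x3))
  l2 <- (t - x1) * (t - x3) / ((x2 - x1) * (x2 - x3))
  l3 <- (t - x1) * (t - x2) / ((x3 - x1) * (x3 - x2))
  y1 * l1 + y2 * l2 + y3 * l3
}

#' MTRasym at +/- 3.5 ppm (APTw %)
#'
#' The asymmetry of the magnetization transfer ratio at the amide resonance:
#' `(S(-3.5) - S(+3.5)) / S0 * 100`. May be negative. Returns `NA` when either
#' +/-3.5 ppm sample is invalid (e.g. after an extreme B0 shift).
#'
#' @param z A [z_spectrum()] whose offsets include -3.5 and +3.5 ppm.
#' @param delta_ppm Analysis offset, default 3.5 (amide protons).
#' @return MTRasym in percent (scalar).
#' @export
compute_mtrasym <- function(z, delta_ppm = 3.5) {
  stopifnot(inherits(z, "z_spectrum"))
  i_neg <- match_offset(z$offsets_ppm, -delta_ppm)
  i_pos <- match_offset(z$offsets_ppm, +delta_ppm)
  if (is.na(i_neg) || is.na(i_pos))
    stop(sprintf("offsets must include -%g and +%g ppm", delta_ppm, delta_ppm))
  (z$signals[i_neg] - z$signals[i_pos]) / z$s0 * 100
}

match_offset <- function(offsets, target, tol = 1e-6) {
  i <- which(abs(offsets - target) < tol)
  if (length(i) == 1L) i else NA_integer_
}

#' Voxel-wise B0-corrected MTRasym map
#'
#' Vectorised pipeline over a volume: for every voxel, resample the measured
#' Z-spectrum at the B0-shifted +/-3.5 ppm positions (per-branch quadratic
#' Lagrange interpolation) and form the asymmetry against `s0`.
#'
#' @param offset_series 4D array `[x, y, z, offset]` of saturated signals.
#' @param s0 3D array of unsaturated reference signals (> 0 where valid).
#' @param offsets_ppm Offset schedule matching the 4th dimension.
#' @param shift_ppm 3D array (or scalar) of per-voxel B0 shifts in ppm; 0
#'   disables correction.
#' @param spacing_mm Voxel spacing, stored on the result.
#' @return A [parametric_map()] of kind `"mtrasym_pct"`; invalid voxels `NA`.
#' @export
mtrasym_map <- function(offset_series, s0, offsets_ppm,
                        shift_ppm = 0, spacing_mm = c(1, 1, 1)) {
  d <- dim(offset_series)
  if (length(d) != 4L || d[4L] != length(offsets_ppm))
    stop("offset_series must be [x, y, z, offset] matching offsets_ppm")
  nv <- prod(d[1:3])
  sig <- matrix(offset_series, nrow = nv)
  if (length(shift_ppm) == 1L) shift_ppm <- rep(shift_ppm, nv)
  shift <- as.numeric(shift_ppm)
  neg <- which(offsets_ppm < 0)
  pos <- which(offsets_ppm > 0)
  if (length(neg) < 3L || length(pos) < 3L)
    stop("need >= 3 offsets per branch")
  s_neg <- branch_sample(offsets_ppm[neg], sig[, neg, drop = FALSE],
                         -3.5 + shift)
  s_pos <- branch_sample(offsets_ppm[pos], sig[, pos, drop = FALSE],
                         +3.5 + shift)
  m <- (s_neg - s_pos) / as.numeric(s0) * 100
  m[!is.finite(m)] <- NA_real_
  m[as.numeric(s0) <= 0] <- NA_real_
  dim(m) <- d[1:3]
  parametric_map(m, spacing_mm, kind = "mtrasym_pct")
}

# Vectorised per-voxel quadratic sampling of one branch at per-voxel targets.
branch_sample <- function(xo, ymat, t) {
  n <- length(xo)
  if (n == 3L) {
    i1 <- rep(1L, length(t))
  } else {
    i1 <- findInterval(t, xo)
    i1 <- pmin(pmax(i1 - 1L, 1L), n - 2L)
  }
  idx <- cbind(seq_along(t), i1)
  x1 <- xo[i1]; x2 <- xo[i1 + 1L]; x3 <- xo[i1 + 2L]
  y1 <- ymat[cbind(idx[, 1L], i1)]
  y2 <- ymat[cbind(idx[, 1L], i1 + 1L)]
  y3 <- ymat[cbind(idx[, 1L], i1 + 2L)]
  out <- y1 * (t - x2) * (t - x3) / ((x1 - x2) * (x1 - x3)) +
         y2 * (t - x1) * (t - x3) / ((x2 - x1) * (x2 - x3)) +
         y3 * (t - x1) * (t - x2) / ((x3 - x1) * (x3 - x2))
  out[t < min(xo) | t > max(xo)] <- NA_real_
  out
}
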