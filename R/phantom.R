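#' Saturation pool specification
#'
#' One Lorentzian saturation pool of the Z-spectrum model: water at 0 ppm,
#' amide protons at +3.5 ppm, MT/NOE contributions on the negative side.
#'
#' @param center_ppm Resonance offset in ppm.
#' @param amplitude Peak saturation depth in `[0, 1)`.
#' @param width_ppm Full width at half maximum in ppm (> 0).
#' @return Object of class `pool_spec`.
#' @export
pool_spec <- function(center_ppm, amplitude, width_ppm) {
  if (!is.finite(center_ppm)) stop("center_ppm must be finite")
  if (!is.finite(amplitude) || amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1)")
  if (!is.finite(width_ppm) || width_ppm <= 0)
    stop("width_ppm must be > 0")
  structure(list(center_ppm = center_ppm, amplitude = amplitude,
                 width_ppm = width_ppm), class = "pool_spec")
}

# Lorentzian saturation of a pool list at offsets (ppm), water shifted by b0.
lorentzian_z <- function(pools, offsets_ppm, b0_shift = 0) {
  z <- rep(1, length(offsets_ppm))
  for (p in pools) {
    hw2 <- (p$width_ppm / 2)^2
    z <- z - p$amplitude * hw2 /
      (hw2 + (offsets_ppm - p$center_ppm - b0_shift)^2)
  }
  z
}

#' Simulate a voxel Z-spectrum from Lorentzian pools
#'
#' `Z(dw) = 1 - sum_k A_k (w_k/2)^2 / ((w_k/2)^2 + (dw - d_k - b0)^2)`,
#' scaled by `s0`, with optional additive Gaussian noise on the saturated
#' samples. `s0` is returned noiseless.
#'
#' @param pools List of [pool_spec()] objects; amplitudes must sum to < 1.
#' @param offsets_ppm Offsets at which to sample, strictly increasing.
#' @param b0_shift Water-resonance shift in ppm (shifts every pool).
#' @param noise_sd Gaussian noise SD on the saturated signals (units of s0).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @param s0 Reference signal level.
#' @return A [z_spectrum()].
#' @examples
#' water <- pool_spec(0, 0.9, 2.0)
#' amide <- pool_spec(3.5, 0.05, 1.5)
#' simulate_z_spectrum(list(water, amide), c(-4.3, -3.5, -2.7, 2.7, 3.5, 4.3))
#' @export
simulate_z_spectrum <- function(pools, offsets_ppm, b0_shift = 0,
                                noise_sd = 0, seed = NULL, s0 = 1) {
  if (length(offsets_ppm) == 0L) stop("offsets_ppm must be non-empty")
  amps <- vapply(pools, function(p) p$amplitude, numeric(1))
  if (length(amps) && sum(amps) >= 1)
    stop("pool amplitudes must sum to < 1 (signal must stay positive)")
  z <- lorentzian_z(pools, offsets_ppm, b0_shift) * s0
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required for noisy simulation")
    set.seed(seed)
    z <- z + stats::rnorm(length(z), 0, noise_sd * s0)
    z <- pmax(z, 0)
  }
  z_spectrum(offsets_ppm, z, s0 = s0)
}

#' Define a digital phantom scene
#'
#' A 3D grid with a background, an ellipsoidal tumor, and an optional
#' necrotic core inside the tumor, each with its own saturation pools, ADC
#' and contrast-enhancement levels; a smooth in-plane polynomial B0 field;
#' and a noise level. All stochastic output is reproducible from `seed`.
#'
#' @param dim Grid dimensions, e.g. `c(24, 24, 8)`.
#' @param spacing_mm Voxel spacing in mm.
#' @param tumor_center,tumor_radius Voxel-index center (1-based) and radii
#'   (scalar or length 3) of the tumor ellipsoid.
#' @param core_radius Radii of the necrotic core (same center); `0` for none.
#' @param pools_background,pools_tumor,pools_core Lists of [pool_spec()].
#' @param adc Named ADC values in x 1e-3 mm^2/s for background, tumor, core.
#' @param enhancement Named net-enhancement amplitudes (a.u.).
#' @param b0_coef In-plane B0 polynomial coefficients
#'   `(c0, cx, cy, cxy, cx2, cy2)` in ppm over normalised coords `[-1, 1]`.
#' @param noise_sd Gaussian noise SD on saturated Z-signals (fraction of s0).
#' @param seed Integer seed (mandatory).
#' @param offsets_ppm,echo_times,b_values,s0 Acquisition schedule.
#' @return Object of class `phantom_scene`.
#' @export
phantom_scene <- function(dim = c(24, 24, 8),
                          spacing_mm = c(2, 2, 4),
                          tumor_center = NULL,
                          tumor_radius = 7,
                          core_radius = 0,
                          pools_background = list(pool_spec(0, 0.85, 2.8)),
                          pools_tumor = list(pool_spec(0, 0.80, 2.6),
                                             pool_spec(3.5, 0.035, 1.8),
                                             pool_spec(-3.5, 0.010, 3.0)),
                          pools_core = list(pool_spec(0, 0.70, 2.4)),
                          adc = c(background = 1.8, tumor = 0.9, core = 2.4),
                          enhancement = c(background = 5, tumor = 60,
                                          core = 8),
                          b0_coef = c(0, 0, 0, 0, 0, 0),
                          noise_sd = 0,
                          seed = 1L,
                          offsets_ppm = c(-4.3, -3.5, -2.7, 2.7, 3.5, 4.3),
                          echo_times = c(2, 3, 4) * 1e-3,
                          b_values = c(0, 800),
                          s0 = 1000) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 4L))
  if (is.null(tumor_center)) tumor_center <- (dim + 1) / 2
  tumor_radius <- rep_len(as.numeric(tumor_radius), 3L)
  core_radius <- rep_len(as.numeric(core_radius), 3L)
  if (any(core_radius >= tumor_radius) && any(core_radius > 0))
    stop("necrotic core must lie strictly inside the tumor")
  stopifnot(length(b0_coef) == 6L, is.numeric(seed), length(seed) == 1L)
  req <- c("background", "tumor", "core")
  if (!all(req %in% names(adc)) || !all(req %in% names(enhancement)))
    stop("adc and enhancement must name background, tumor and core")
  structure(list(dim = dim, spacing_mm = spacing_mm,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 core_radius = core_radius,
                 pools = list(background = pools_background,
                              tumor = pools_tumor, core = pools_core),
                 adc = adc, enhancement = enhancement,
                 b0_coef = b0_coef, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 offsets_ppm = offsets_ppm, echo_times = echo_times,
                 b_values = b_values, s0 = s0),
            class = "phantom_scene")
}

ellipsoid_mask <- function(dim, center, radius) {
  x <- (seq_len(dim[1]) - center[1]) / radius[1]
  y <- (seq_len(dim[2]) - center[2]) / radius[2]
  z <- (seq_len(dim[3]) - center[3]) / radius[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

# Smooth in-plane B0 field (ppm), identical across slices.
b0_field <- function(dim, coef) {
  u <- seq(-1, 1, length.out = dim[1])
  v <- seq(-1, 1, length.out = dim[2])
  slice <- coef[1] +
    coef[2] * matrix(u, dim[1], dim[2]) +
    coef[3] * matrix(v, dim[1], dim[2], byrow = TRUE) +
    coef[4] * outer(u, v) +
    coef[5] * matrix(u^2, dim[1], dim[2]) +
    coef[6] * matrix(v^2, dim[1], dim[2], byrow = TRUE)
  array(rep(slice, dim[3]), dim = dim)
}

#' Simulate all phantom volumes with ground truth
#'
#' Generates, from a [phantom_scene()]: the saturation offset series and
#' reference `s0` volume, three-echo phase volumes consistent with the B0
#' field, DWI volumes, pre/post-contrast volumes, tumor and necrotic-core
#' masks, and noiseless ground-truth MTRasym and ADC maps. Deterministic
#' given the scene seed; noise applies to the saturated Z-signals only.
#'
#' @param scene A [phantom_scene()].
#' @return A list (class `phantom_bundle`) with elements `offset_series`,
#'   `s0`, `phase_series`, `dwi`, `pre`, `post`, `mask`, `core_mask`,
#'   `b0_true`, `truth` (`mtrasym`, `adc` as [parametric_map()]s) and the
#'   acquisition schedule.
#' @export
simulate_phantom_volumes <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  d <- scene$dim
  tumor <- ellipsoid_mask(d, scene$tumor_center, scene$tumor_radius)
  core <- if (all(scene$core_radius > 0))
    ellipsoid_mask(d, scene$tumor_center, scene$core_radius)
  else array(FALSE, d)
  region <- array("background", d)
  region[tumor] <- "tumor"
  region[core] <- "core"    # core subset of tumor by construction

  b0 <- b0_field(d, scene$b0_coef)
  off <- scene$offsets_ppm
  nv <- prod(d)

  # Z-spectrum series: per region, Lorentzian at (offset - b0) voxel-wise
  series <- array(NA_real_, c(d, length(off)))
  truth_mtr <- array(NA_real_, d)
  for (rg in c("background", "tumor", "core")) {
    sel <- region == rg
    if (!any(sel)) next
    pools <- scene$pools[[rg]]
    shifts <- b0[sel]
    for (k in seq_along(off)) {
      zk <- rep(1, sum(sel))
      for (p in pools) {
        hw2 <- (p$width_ppm / 2)^2
        zk <- zk - p$amplitude * hw2 /
          (hw2 + (off[k] - p$center_ppm - shifts)^2)
      }
      sl <- slice.index(series, 4L) == k
      series[sl][sel] <- zk * scene$s0
    }
    z_ideal <- lorentzian_z(pools, c(-3.5, 3.5), b0_shift = 0)
    truth_mtr[sel] <- (z_ideal[1] - z_ideal[2]) * 100
  }
  if (scene$noise_sd > 0) {
    set.seed(scene$seed)
    series <- series + stats::rnorm(length(series), 0,
                                    scene$noise_sd * scene$s0)
    series <- pmax(series, 0)
  }
  s0_vol <- array(scene$s0, d)

  # multi-echo phases from the B0 field: phase = 2*pi * df * TE
  df_hz <- b0 * 127.728
  phases <- array(0, c(d, length(scene$echo_times)))
  for (k in seq_along(scene$echo_times)) {
    ph <- 2 * pi * df_hz * scene$echo_times[k]
    ph <- atan2(sin(ph), cos(ph))        # wrapped to (-pi, pi]
    sl <- slice.index(phases, 4L) == k
    phases[sl] <- ph
  }

  # DWI from region ADC (x 1e-3 mm^2/s)
  adc_map <- array(scene$adc["background"], d)
  adc_map[tumor] <- scene$adc["tumor"]
  adc_map[core] <- scene$adc["core"]
  dwi <- array(NA_real_, c(d, length(scene$b_values)))
  for (k in seq_along(scene$b_values)) {
    sl <- slice.index(dwi, 4L) == k
    dwi[sl] <- scene$s0 * exp(-scene$b_values[k] * adc_map * 1e-3)
  }

  # contrast: pre flat, post = pre + region enhancement
  pre <- array(100, d)
  enh <- array(scene$enhancement["background"], d)
  enh[tumor] <- scene$enhancement["tumor"]
  enh[core] <- scene$enhancement["core"]
  post <- pre + enh

  structure(list(
    offset_series = series, s0 = s0_vol, phase_series = phases,
    dwi = dwi, pre = pre, post = post,
    mask = tumor, core_mask = core, b0_true = b0,
    truth = list(
      mtrasym = parametric_map(truth_mtr, scene$spacing_mm, "mtrasym_pct"),
      adc = parametric_map(adc_map, scene$spacing_mm, "adc_e3")),
    offsets_ppm = off, echo_times = scene$echo_times,
    b_values = scene$b_values, spacing_mm = scene$spacing_mm,
    scene = scene), class = "phantom_bundle")
}

#' Run the quantification pipeline on a phantom bundle
#'
#' Estimates the B0 map from the multi-echo phases, computes the B0-corrected
#' MTRasym map, the ADC map and the net-enhancement map — the same code path
#' used for real acquisitions.
#'
#' @param bundle Output of [simulate_phantom_volumes()].
#' @param correct_b0 If `FALSE`, skip the Z-spectrum correction (for
#'   quantifying the benefit of correction).
#' @return List with `mtrasym`, `adc`, `net_enh` ([parametric_map()]s) and
#'   `b0` (the estimated `b0_map`).
#' @export
quantify_phantom <- function(bundle, correct_b0 = TRUE) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  b0 <- estimate_b0_shift(bundle$phase_series, bundle$echo_times)
  shift <- if (correct_b0) b0$shift_ppm else 0
  list(
    mtrasym = mtrasym_map(bundle$offset_series, bundle$s0,
                          bundle$offsets_ppm, shift_ppm = shift,
                          spacing_mm = bundle$spacing_mm),
    adc = compute_adc_map(bundle$dwi, bundle$b_values, bundle$spacing_mm),
    net_enh = compute_net_enhancement(bundle$pre, bundle$post,
                                      bundle$spacing_mm),
    b0 = b0)
}

# 6-connectivity binary erosion / dilation by one voxel
shift_arr <- function(a, dm, by) {
  out <- array(if (is.logical(a)) FALSE else 0, dim(a))
  d <- dim(a)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { src[[dm]] <- 1:(d[dm] - by); dst[[dm]] <- (1 + by):d[dm] }
  else { src[[dm]] <- (1 - by):d[dm]; dst[[dm]] <- 1:(d[dm] + by) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

erode1 <- function(m) {
  out <- m
  for (dm in 1:3) for (by in c(-1L, 1L))
    out <- out & shift_arr(m, dm, by)
  out
}

dilate1 <- function(m) {
  out <- m
  for (dm in 1:3) for (by in c(-1L, 1L))
    out <- out | shift_arr(m, dm, by)
  out
}

morph_n <- function(m, n, f) { for (i in seq_len(n)) m <- f(m); m }

#' Simulate two readers' ROI masks
#'
#' Emulates independent manual delineations by two observers: voxels in the
#' band between the `jitter_vox`-fold erosion and dilation of the reference
#' mask are included by each reader independently with probability 1/2;
#' voxels inside the eroded core are always included. `jitter_vox = 0`
#' returns two copies of the input. Deterministic given `seed`.
#'
#' @param mask Logical 3D array (reference delineation).
#' @param jitter_vox Non-negative integer boundary jitter in voxels.
#' @param seed Integer seed.
#' @return List of two logical arrays `reader_a`, `reader_b`.
#' @export
simulate_reader_masks <- function(mask, jitter_vox = 1L, seed = 1L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("mask is empty")
  jitter_vox <- as.integer(jitter_vox)
  if (jitter_vox < 0L) stop("jitter_vox must be >= 0")
  if (jitter_vox == 0L)
    return(list(reader_a = mask, reader_b = mask))
  core <- morph_n(mask, jitter_vox, erode1)
  if (!any(core)) stop("jitter larger than the object: eroded mask is empty")
  band <- morph_n(mask, jitter_vox, dilate1) & !core
  nb <- sum(band)
  set.seed(seed)
  a <- core; a[band] <- stats::runif(nb) < 0.5
  b <- core; b[band] <- stats::runif(nb) < 0.5
  list(reader_a = a, reader_b = b)
}

#' Dice similarity of two binary masks
#' @param a,b Logical arrays of identical shape.
#' @return Dice coefficient `2|A n B| / (|A| + |B|)`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
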