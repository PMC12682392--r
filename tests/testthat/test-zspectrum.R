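test_that("B0 shift estimation matches the closed-form slope and an lm fit", {
  te <- c(2, 3, 4) * 1e-3

  expect_equal(estimate_b0_shift(c(0, 0, 0), te)$shift_ppm, 0)

  # 0.2*pi rad per ms -> 100 Hz -> 100 / 127.728 ppm
  ph <- c(0, 0.2 * pi, 0.4 * pi)
  b0 <- estimate_b0_shift(ph, te)
  expect_equal(b0$freq_hz, 100, tolerance = 1e-12)
  expect_equal(b0$shift_ppm, 100 / 127.728, tolerance = 1e-12)
  expect_equal(b0$freq_hz, slope_lm(ph, te) / (2 * pi), tolerance = 1e-10)

  # a wrapped middle sample unwraps to the same answer
  b0w <- estimate_b0_shift(c(0, 0.2 * pi + 2 * pi, 0.4 * pi), te)
  expect_equal(b0w$shift_ppm, b0$shift_ppm, tolerance = 1e-12)

  # noisy phases: agree with lm on unwrapped data
  set.seed(4)
  ph2 <- 2 * pi * 37 * te + rnorm(3, 0, 0.05)
  expect_equal(estimate_b0_shift(ph2, te)$freq_hz,
               slope_lm(ph2, te) / (2 * pi), tolerance = 1e-9)
})

test_that("B0 estimation input contracts", {
  expect_error(estimate_b0_shift(c(0, 1), c(1, 2) * 1e-3), "at least 3")
  expect_error(estimate_b0_shift(c(0, 1, 2), c(3, 2, 4) * 1e-3),
               "strictly increasing")
  # array input keeps spatial shape and flags extreme voxels
  ph <- array(0, c(2, 2, 1, 3))
  ph[1, 1, 1, ] <- 2 * pi * 300 * c(2, 3, 4) * 1e-3   # 300 Hz -> 2.35 ppm
  b0 <- estimate_b0_shift(ph, c(2, 3, 4) * 1e-3)
  expect_identical(dim(b0$shift_ppm), c(2L, 2L, 1L))
  expect_true(b0$unreliable[1, 1, 1])
  expect_false(any(b0$unreliable[-1]))
})

test_that("Z-spectrum correction is the identity at zero shift", {
  z <- simulate_z_spectrum(list(pool_spec(0, 0.8, 2.5),
                                pool_spec(3.5, 0.04, 2)),
                           nominal_offsets)
  zc <- correct_z_spectrum(z, 0)
  expect_equal(zc$signals, z$signals, tolerance = 1e-14)
  expect_identical(zc$s0, z$s0)
})

test_that("quadratic correction is exact for polynomial branches", {
  off <- nominal_offsets
  # linear per branch; in-branch shifted targets are reproduced exactly,
  # targets pushed past a branch end (here -2.7 and +4.3) become NA
  lin <- function(x) 0.9 - 0.05 * abs(x)
  z <- z_spectrum(off, lin(off), s0 = 2)
  zc <- correct_z_spectrum(z, 0.3)
  expect_equal(zc$signals[c(1, 2, 4, 5)], lin(off[c(1, 2, 4, 5)] + 0.3),
               tolerance = 1e-12)
  expect_true(all(is.na(zc$signals[c(3, 6)])))

  # quadratic on the positive branch, shift 0.4 -> exact at 3.9 ppm
  q <- function(x) 2 + 0.3 * x - 0.05 * x^2
  zq <- z_spectrum(off, q(abs(off)), s0 = 10)
  zcq <- correct_z_spectrum(zq, 0.4)
  expect_equal(zcq$signals[5], q(3.9), tolerance = 1e-12)
})

test_that("targets leaving the sampled branch become NA, not errors", {
  z <- simulate_z_spectrum(list(pool_spec(0, 0.8, 2.5)), nominal_offsets)
  zc <- suppressWarnings(correct_z_spectrum(z, 0.5))
  # +4.3 + 0.5 = 4.8 is outside [2.7, 4.3]
  expect_true(is.na(zc$signals[6]))
  # +/-3.5 stay valid
  expect_false(anyNA(zc$signals[c(2, 5)]))
  expect_error(correct_z_spectrum(z_spectrum(c(-1, 0.5, 1),
                                             c(1, 1, 1), 1), 0.1),
               "3 offsets on each side")
})

test_that("MTRasym follows its defining ratio and contracts", {
  z <- z_spectrum(nominal_offsets, c(0.7, 0.7, 0.7, 0.7, 0.6, 0.7), s0 = 1)
  expect_equal(compute_mtrasym(z), 10)

  # symmetric spectrum -> exactly zero
  sym <- simulate_z_spectrum(list(pool_spec(0, 0.9, 2)), nominal_offsets)
  expect_identical(compute_mtrasym(sym), 0)

  # phantom spectrum matches the analytic pool difference at -/+3.5 ppm
  pools <- list(pool_spec(0, 0.8, 2.5), pool_spec(3.5, 0.035, 1.8))
  z2 <- simulate_z_spectrum(pools, nominal_offsets)
  lor <- function(p, x) p$amplitude * (p$width_ppm / 2)^2 /
    ((p$width_ppm / 2)^2 + (x - p$center_ppm)^2)
  analytic <- 100 * sum(vapply(pools, function(p)
    lor(p, 3.5) - lor(p, -3.5), numeric(1)))
  expect_equal(compute_mtrasym(z2), analytic, tolerance = 1e-12)

  expect_error(compute_mtrasym(z_spectrum(c(-4, -3, -2, 2, 3, 4),
                                          rep(0.5, 6), 1)),
               "offsets must include")
})

test_that("MTRasym is linear in the amide-pool amplitude", {
  base <- list(pool_spec(0, 0.8, 2.5))
  m_at <- function(a) {
    pools <- c(base, list(pool_spec(3.5, a, 1.8)))
    compute_mtrasym(simulate_z_spectrum(pools, nominal_offsets))
  }
  amps <- c(0.01, 0.02, 0.03, 0.04)
  vals <- vapply(amps, m_at, numeric(1))
  hw2 <- (1.8 / 2)^2
  slope_analytic <- 100 * (1 - hw2 / (hw2 + 49))   # per unit amplitude
  fit_slope <- slope_lm(vals, amps)
  expect_equal(fit_slope, slope_analytic, tolerance = 1e-9)
  # intercept zero: no amide -> only (symmetric) water remains
  expect_equal(m_at(0), 0, tolerance = 1e-12)
})

test_that("symmetric spectra stay zero after shift + correction when the
           branches are quadratic (interpolation-exact class)", {
  off <- nominal_offsets
  even_quad <- function(x) 0.95 - 0.02 * x^2       # even, quadratic branches
  for (d in c(-0.4, -0.1, 0.2, 0.5)) {
    meas <- z_spectrum(off, even_quad(off - d), s0 = 1)
    zc <- suppressWarnings(correct_z_spectrum(meas, d))
    expect_equal((zc$signals[2] - zc$signals[5]) * 100, 0,
                 tolerance = 1e-10)
  }
})

test_that("correction strongly suppresses the spurious asymmetry of a
           shifted symmetric Lorentzian", {
  pools <- list(pool_spec(0, 0.9, 2))
  for (d in c(0.1, 0.25, 0.4)) {
    zs <- simulate_z_spectrum(pools, nominal_offsets, b0_shift = d)
    raw <- abs(compute_mtrasym(zs))
    cor <- abs(compute_mtrasym(correct_z_spectrum(zs, d)))
    expect_lt(cor, 0.2 * raw)
  }
})

test_that("vectorised map agrees with the scalar spectrum path", {
  set.seed(9)
  d <- c(3, 2, 2)
  nv <- prod(d)
  pools <- list(pool_spec(0, 0.8, 2.5), pool_spec(3.5, 0.04, 2))
  shifts <- array(runif(nv, -0.3, 0.3), d)
  series <- array(NA_real_, c(d, 6))
  for (i in seq_len(nv)) {
    z <- simulate_z_spectrum(pools, nominal_offsets,
                             b0_shift = shifts[i])
    sl <- slice.index(series, 4)
    for (k in 1:6) series[(k - 1) * nv + i] <- z$signals[k]
  }
  mp <- mtrasym_map(series, array(1, d), nominal_offsets, shifts)
  for (i in seq_len(nv)) {
    sig_i <- vapply(1:6, function(k) series[(k - 1) * nv + i], numeric(1))
    zc <- correct_z_spectrum(z_spectrum(nominal_offsets, sig_i, 1),
                             shifts[i])
    expect_equal(mp$values[i], compute_mtrasym(zc), tolerance = 1e-10)
  }
})
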