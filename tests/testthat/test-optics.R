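# Defocus calculus, sampling bounds, pupil assembly and PSF/MTF.

test_that("defocus coefficient reproduces the catalog design points", {
  a50 <- 1.07e-3 / 2
  # 50X, z0 = 4 mm, lambda = 550 nm
  expect_equal(defocus_coefficient(2.5e-3, 4e-3, a50), 245.54,
               tolerance = 0.01)
  expect_equal(defocus_coefficient(3e-3, 4e-3, a50), 136.24,
               tolerance = 0.01)
  expect_identical(defocus_coefficient(4e-3, 4e-3, a50), 0)
  # sign flips across focus
  expect_lt(defocus_coefficient(5e-3, 4e-3, a50), 0)
  expect_error(defocus_coefficient(-1e-3, 4e-3, a50), "positive")
})

test_that("max_defocus picks the near-side endpoint of a symmetric range", {
  a <- 0.535e-3
  spec <- depth_spec(3e-3, 5e-3, 4e-3)
  expect_equal(max_defocus(spec, a), 136.25, tolerance = 1e-3)
  # near side strictly dominates by convexity of 1/z
  expect_gt(abs(defocus_coefficient(3e-3, 4e-3, a)),
            abs(defocus_coefficient(5e-3, 4e-3, a)))
  expect_equal(max_defocus(depth_spec(3.9e-3, 4.1e-3, 4e-3), a), 10.48,
               tolerance = 1e-3)
})

test_that("design calculator matches the verified catalog rows within 1%", {
  rows <- list(
    list(preset = "mitutoyo50x", half = 100e-6, psi = 10.48, pitch = 20),
    list(preset = "mitutoyo50x", half = 1e-3, psi = 136.24, pitch = 1.54),
    list(preset = "mitutoyo50x", half = 1.5e-3, psi = 245.54, pitch = 0.858),
    list(preset = "rms20x", half = 100e-6, psi = 14.69, pitch = 38)
  )
  for (r in rows) {
    d <- design_row(r$preset, r$half)
    expect_equal(d$psi_max, r$psi, tolerance = 0.01)
    expect_equal(d$max_pitch_um, r$pitch, tolerance = 0.015)
  }
  # low-magnification rows are looser (about 2 %): in-focus depth not
  # printed for that objective, standard focal length assumed
  d4a <- design_row("rms4x", 100e-6)
  expect_equal(d4a$psi_max, 0.97, tolerance = 0.02)
  d4b <- design_row("rms4x", 1e-3)
  expect_equal(d4b$psi_max, 9.877, tolerance = 0.02)
})

test_that("sampling-pitch bound behaves as an inverse law with psi_max", {
  a <- 0.535e-3
  p1 <- max_sampling_pitch(a, 136.24)
  expect_equal(p1 * 1e6, 1.54, tolerance = 0.01)
  expect_equal(max_sampling_pitch(a, 2 * 136.24), p1 / 2)
  expect_equal(max_sampling_pitch(1.435e-3, 14.69) * 1e6, 38.37,
               tolerance = 0.01)
  expect_error(max_sampling_pitch(a, 0), "psi_max")
})

test_that("minimum pupil radius is homogeneous and f1*NA at the NA edge", {
  k <- wavenumber(550e-9)
  expect_identical(min_pupil_radius(0.2, k, 0, 0), 0)
  # kx = k * NA on axis: r = f1 * NA
  expect_equal(min_pupil_radius(0.2, k, k * 0.42, 0), 0.2 * 0.42)
  r1 <- min_pupil_radius(0.2, k, 3e5, 4e5)
  expect_equal(min_pupil_radius(0.2, k, 3 * 3e5, 3 * 4e5), 3 * r1)
})

test_that("defocus phase map is quadratic, zero at center, psi at the edge", {
  sys <- toy_system(16L)
  psi <- 7.3
  ph <- defocus_phase_map(sys, psi)
  c0 <- floor(16 / 2) + 1
  expect_identical(ph[c0, c0], 0)
  expect_true(all(defocus_phase_map(sys, 0) == 0))
  # exactly psi where x^2 + y^2 = a^2, psi/4 at half the radius
  x <- pupil_axis(sys)
  r2 <- outer(x^2, x^2, "+")
  i_edge <- which.min(abs(r2 - sys$effective_radius^2))
  expect_equal(ph[i_edge], psi * r2[i_edge] / sys$effective_radius^2)
  expect_equal(defocus_phase_map(sys, psi)[c0, c0 + 4] /
                 (psi * x[c0 + 4]^2 / sys$effective_radius^2), 1)
})

test_that("pupil assembly is additive in phases and clips to the disc", {
  sys <- toy_system(16L)
  ph1 <- defocus_phase_map(sys, 3)
  ph2 <- matrix(0.2, 16, 16)
  p12 <- assemble_pupil(sys, ph1, ph2)
  p21 <- assemble_pupil(sys, ph2, ph1)
  expect_identical(p12$phase, p21$phase)
  expect_identical(p12$amplitude, aperture_amplitude(sys))
  expect_true(all(p12$amplitude %in% c(0, 1)))
  # amplitude zero outside the disc
  x <- pupil_axis(sys)
  r2 <- outer(x^2, x^2, "+")
  expect_true(all(p12$amplitude[r2 > sys$effective_radius^2] == 0))
  expect_error(assemble_pupil(sys, matrix(0, 8, 8)), "grid")
})

test_that("psf_from_pupil matches a direct DFT oracle to 1e-10", {
  sys <- toy_system(16L)
  for (psi in c(0, 4.5)) {
    pupil <- assemble_pupil(sys, defocus_phase = defocus_phase_map(sys, psi))
    psf <- psf_from_pupil(pupil, pad_factor = 1L)
    p <- pupil$amplitude * exp(1i * pupil$phase)
    oracle <- brute_dft_intensity(p)
    oracle <- fftshift2(oracle / sum(oracle))
    expect_lt(max(abs(psf - oracle)) / max(oracle), 1e-10)
  }
})

test_that("PSFs are non-negative, unit-sum, and Parseval-consistent", {
  sys <- toy_system(16L)
  pupil <- assemble_pupil(sys, defocus_phase = defocus_phase_map(sys, 2))
  psf <- psf_from_pupil(pupil, pad_factor = 2L)
  expect_true(all(psf >= 0))
  expect_equal(sum(psf), 1, tolerance = 1e-9)
  # Parseval: pre-normalization energy = N^2 * sum |P|^2 for the
  # unnormalized DFT, checked on an 8x8 pupil against the brute DFT
  p8 <- matrix(complex(real = stats::runif(64), imaginary = stats::runif(64)),
               8, 8)
  raw <- brute_dft_intensity(p8)
  expect_equal(sum(raw), 64 * sum(Mod(p8)^2), tolerance = 1e-8)
  # a linear phase ramp translates the PSF but leaves its values intact
  n <- sys$grid_size
  ramp <- outer(seq_len(n), rep(1, n)) * (2 * pi * 2 / (2 * n))
  pupil2 <- assemble_pupil(sys, ramp, defocus_phase_map(sys, 2))
  psf2 <- psf_from_pupil(pupil2, pad_factor = 2L)
  shifted <- rbind(psf2[-(1:2), ], psf2[1:2, ])   # undo the 2-sample shift
  expect_equal(shifted, psf, tolerance = 1e-9)
  expect_error(psf_from_pupil(structure(list(amplitude = matrix(0, 4, 4),
                                             phase = matrix(0, 4, 4)),
                                        class = "pupil_field")), "energy")
})

test_that("clear-aperture PSF is centered and rotationally symmetric", {
  sys <- toy_system(32L)
  psf <- psf_from_pupil(assemble_pupil(sys), pad_factor = 2L)
  c0 <- floor(64 / 2) + 1
  expect_equal(which.max(psf), (c0 - 1) * 64 + c0)
  expect_equal(psf, t(psf), tolerance = 1e-12)        # x/y exchange
  expect_equal(psf[c0 + 5, c0], psf[c0 - 5, c0], tolerance = 1e-12)
})

test_that("MTF is 1 at DC, bounded by 1, and translation invariant", {
  sys <- toy_system(16L)
  psf <- psf_from_pupil(assemble_pupil(sys,
                                       defocus_phase = defocus_phase_map(sys, 3)),
                        pad_factor = 2L)
  m <- mtf_from_psf(psf)
  expect_equal(m$radial[1], 1)
  expect_true(all(m$magnitude <= 1 + 1e-12))
  # delta PSF: MTF identically one
  d <- matrix(0, 16, 16); d[9, 9] <- 1
  expect_true(all(abs(mtf_from_psf(d)$magnitude - 1) < 1e-12))
  # translation leaves the magnitude unchanged
  d2 <- matrix(0, 16, 16); d2[5, 12] <- 1
  expect_equal(mtf_from_psf(d2)$magnitude, mtf_from_psf(d)$magnitude,
               tolerance = 1e-12)
})

test_that("clear-aperture MTF equals the normalized disc autocorrelation", {
  sys <- toy_system(16L)
  pupil <- assemble_pupil(sys)
  psf <- psf_from_pupil(pupil, pad_factor = 2L)
  m <- mtf_from_psf(psf)
  ac <- brute_autocorrelation(pupil$amplitude)
  ac <- ac / max(ac)
  # embed the (2n-1) autocorrelation into the centered 2n frame
  full <- matrix(0, 32, 32)
  full[2:32, 2:32] <- ac
  expect_equal(m$magnitude, full, tolerance = 1e-9)
})

test_that("psf stacks share grid conventions and export to TIFF/CSV", {
  sys <- toy_system(16L)
  depths <- c(3.9e-3, 4e-3, 4.1e-3)
  stack <- psf_stack(sys, depths, psf_size = 17L)
  expect_s3_class(stack, "psf_stack")
  expect_length(stack$psfs, 3)
  for (p in stack$psfs) expect_equal(sum(p), 1, tolerance = 1e-9)
  tf <- tempfile(fileext = ".tiff"); cf <- tempfile(fileext = ".csv")
  export_psf_stack(stack, tf, cf)
  expect_length(tiff::readTIFF(tf, all = TRUE), 3)
  mt <- utils::read.csv(cf)
  expect_equal(ncol(mt), 4)   # frequency + one column per depth
  expect_equal(mt[1, 2], 1)   # DC of the radial MTF
})
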