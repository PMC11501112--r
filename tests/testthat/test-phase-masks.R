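# DOE, metalens (LUT) and cubic mask parameterizations.

test_that("DOE phase is k (n-1) h with the standard material values", {
  k <- wavenumber(550e-9)
  h0 <- matrix(0, 8, 8)
  expect_true(all(doe_phase(doe_mask(h0), k) == 0))
  # one full wave of material: h = lambda / (n - 1) = 1100 nm at n = 1.5
  h <- matrix(1100e-9, 4, 4)
  expect_equal(doe_phase(doe_mask(h), k), matrix(2 * pi, 4, 4),
               tolerance = 1e-12)
  expect_equal(doe_phase(doe_mask(matrix(550e-9, 2, 2)), k)[1, 1], pi,
               tolerance = 1e-12)
  expect_error(doe_mask(matrix(-1e-9, 2, 2)), "non-negative")
})

test_that("cubic mask is wrapped to [0, 2pi), zero at origin, odd pre-wrap", {
  n <- 32L
  for (alpha in c(6 * pi, 200 * pi, 360 * pi)) {
    ph <- cubic_phase(cubic_mask(alpha, n))
    expect_true(all(ph >= 0 & ph < 2 * pi))
    c0 <- floor(n / 2) + 1
    expect_equal(ph[c0, c0], 0)
    # raw cubic is odd: check via a direct evaluation
    x <- seq_len(n) - c0
    raw <- alpha / n^3 * (outer(x^3, rep(1, n)) + outer(rep(1, n), x^3))
    for (idx in list(c(3, 7), c(10, 20))) {
      i <- idx[1]; j <- idx[2]
      im <- 2 * c0 - i; jm <- 2 * c0 - j   # mirrored coordinates
      expect_equal(raw[i, j], -raw[im, jm], tolerance = 1e-9)
    }
    expect_equal(ph, raw %% (2 * pi), tolerance = 1e-12)
  }
})

test_that("cubic strength presets map depth targets to 6/200/360 pi", {
  expect_equal(cubic_alpha_for_dof(200e-6), 6 * pi)
  expect_equal(cubic_alpha_for_dof(2e-3), 200 * pi)
  expect_equal(cubic_alpha_for_dof(3e-3), 360 * pi)
})

test_that("LUT interpolation is exact at knots, monotone, linear between", {
  lut <- default_lut(1.54e-6)
  # endpoint and knot exactness
  rm1 <- matrix(lut$radii[1], 1, 1)
  expect_equal(radius_to_phase(rm1, lut)[1, 1], lut$phases[1])
  rm7 <- matrix(lut$radii[7], 1, 1)
  expect_equal(radius_to_phase(rm7, lut)[1, 1], lut$phases[7])
  # midpoint linearity
  mid <- (lut$radii[3] + lut$radii[4]) / 2
  expect_equal(radius_to_phase(matrix(mid, 1, 1), lut)[1, 1],
               (lut$phases[3] + lut$phases[4]) / 2, tolerance = 1e-12)
  # monotone over a random radius set
  set.seed(5)
  r <- sort(stats::runif(50, min(lut$radii), max(lut$radii)))
  ph <- radius_to_phase(matrix(r, 1), lut)
  expect_true(all(diff(as.numeric(ph)) >= 0))
  expect_error(radius_to_phase(matrix(1e-9, 2, 2), lut), "cell \\(1, 1\\)")
})

test_that("phase -> radius inversion round-trips within 1e-3 rad", {
  lut <- default_lut(1.54e-6)
  set.seed(7)
  phases <- matrix(stats::runif(100, 0, 2 * pi), 10)
  radii <- phase_to_radius(phases, lut)
  expect_true(all(radii >= min(lut$radii) & radii <= max(lut$radii)))
  expect_true(all(2 * radii <= 1.54e-6 - 50e-9 + 1e-15))
  back <- radius_to_phase(radii, lut)
  err <- abs((back - phases + pi) %% (2 * pi) - pi)
  expect_lt(max(err), 1e-3)
  # 2 pi ties wrap to 0
  expect_equal(phase_to_radius(matrix(2 * pi, 1, 1), lut)[1, 1],
               phase_to_radius(matrix(0, 1, 1), lut)[1, 1])
  # phase 0 maps to the LUT radius carrying phase 0
  expect_equal(phase_to_radius(matrix(0, 1, 1), lut)[1, 1], lut$radii[1])
})

test_that("LUT CSV round-trips and rejects malformed tables", {
  lut <- default_lut(20e-6)
  path <- tempfile(fileext = ".csv")
  write_lut_csv(lut, path)
  lut2 <- read_lut_csv(path)
  expect_equal(lut2$radii, lut$radii, tolerance = 1e-12)
  expect_equal(lut2$phases, lut$phases)
  expect_error(phase_radius_lut(c(2e-7, 1e-7), c(0, 7)), "increasing")
  expect_error(phase_radius_lut(c(1e-7, 2e-7), c(0, 3)), "2 pi")
})

test_that("every mask family emits a phase on the shared pupil grid", {
  sys <- toy_system(16L)
  masks <- list(
    doe_mask(matrix(200e-9, 16, 16)),
    metalens_mask(matrix(200e-9, 16, 16), default_lut(sys$sample_pitch),
                  sys$sample_pitch),
    cubic_mask(6 * pi, 16L),
    free_phase_mask(matrix(0.3, 16, 16))
  )
  for (m in masks) {
    ph <- mask_phase(m, sys)
    expect_identical(dim(ph), c(16L, 16L))
    pupil <- assemble_pupil(sys, ph, defocus_phase_map(sys, 1),
                            amplitude = mask_amplitude(m, sys))
    psf <- psf_from_pupil(pupil)
    expect_equal(sum(psf), 1, tolerance = 1e-9)
  }
})

test_that("phase-only masks leave total PSF energy unchanged", {
  # lossless assumption: any pure phase in the pupil redistributes but
  # does not destroy energy
  sys <- toy_system(16L)
  e <- function(mask_phase_map) {
    p <- assemble_pupil(sys, mask_phase_map)
    np <- matrix(0 + 0i, 32, 32)
    np[1:16, 1:16] <- p$amplitude * exp(1i * p$phase)
    sum(Mod(stats::fft(np))^2)
  }
  set.seed(3)
  e0 <- e(matrix(0, 16, 16))
  e1 <- e(matrix(stats::runif(256, 0, 2 * pi), 16))
  e2 <- e(cubic_phase(cubic_mask(6 * pi, 16L)))
  expect_equal(e1, e0, tolerance = 1e-9)
  expect_equal(e2, e0, tolerance = 1e-9)
})

test_that("fabrication perturbation is seeded Gaussian with physical clipping", {
  h <- matrix(300e-9, 100, 100)
  m <- doe_mask(h)
  expect_identical(perturb_mask(m, 0, 1)$height_map, h)
  p1 <- perturb_mask(m, 30e-9, 11)
  p2 <- perturb_mask(m, 30e-9, 11)
  expect_identical(p1$height_map, p2$height_map)   # reproducible
  dev <- p1$height_map - h
  expect_equal(stats::sd(dev), 30e-9, tolerance = 0.05)
  expect_equal(mean(dev), 0, tolerance = 1e-9 + 3 * 30e-9 / 100)
  expect_true(all(perturb_mask(doe_mask(matrix(1e-9, 50, 50)),
                               50e-9, 2)$height_map >= 0))
  # metalens radii stay within LUT range
  lut <- default_lut(1.54e-6)
  rmask <- metalens_mask(matrix(mean(lut$radii), 50, 50), lut, 1.54e-6)
  pr <- perturb_mask(rmask, 12e-9, 3)
  expect_true(all(pr$radius_map >= min(lut$radii)))
  expect_true(all(2 * pr$radius_map <= pr$max_diameter + 1e-15))
})

test_that("learned phase exports to DOE heights and metalens radii", {
  sys <- toy_system(16L)
  set.seed(21)
  mask <- free_phase_mask(matrix(stats::runif(256, -pi, 3 * pi), 16))
  d <- as_doe_mask(mask, sys)
  expect_true(all(d$height_map >= 0))
  # heights stay below one wrapped wave of material
  expect_true(all(d$height_map < 550e-9 / 0.5))
  expect_equal(doe_phase(d, wavenumber(sys$wavelength)),
               mask$phase %% (2 * pi), tolerance = 1e-12)
  ml <- as_metalens_mask(mask, sys)
  expect_s3_class(ml, "metalens_mask")
  back <- radius_to_phase(ml$radius_map, ml$lut)
  err <- abs((back - mask$phase + pi) %% (2 * pi) - pi)
  expect_lt(max(err), 1e-3)
})

test_that("mask export writes TIFF, CSV and a JSON sidecar", {
  sys <- toy_system(16L)
  m <- doe_mask(matrix(stats::runif(256, 0, 1000e-9), 16))
  prefix <- tempfile()
  paths <- export_mask(m, prefix, sys)
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(meta$quantity, "height_m")
  expect_equal(meta$wavelength_m, 550e-9)
  back <- tiff::readTIFF(paste0(prefix, ".tiff")) * meta$tiff_scale_m
  expect_equal(max(abs(back - m$height_map)), 0, tolerance = 1e-7 * 1000e-9)
})
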