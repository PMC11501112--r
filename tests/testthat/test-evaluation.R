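# PSNR/SSIM metrics, MTF bandwidth and depth invariance, robustness.

test_that("psnr matches its closed form and handles identical images", {
  ref <- matrix(0.5, 10, 10)
  test <- ref + 0.1                       # MSE = 0.01
  expect_equal(psnr(ref, test), 20)
  expect_identical(psnr(ref, ref), Inf)
  # direct per-pixel cross-check on a random pair
  set.seed(6)
  a <- matrix(stats::runif(64), 8); b <- matrix(stats::runif(64), 8)
  expect_equal(psnr(a, b), 10 * log10(1 / mean((a - b)^2)))
  expect_equal(psnr(a * 10, b * 10, peak = 10),
               10 * log10(100 / mean((10 * a - 10 * b)^2)))
})

test_that("ssim agrees with the reference implementation", {
  # frozen oracle: scikit-image structural_similarity with
  # gaussian_weights=TRUE, sigma=1.5, use_sample_covariance=FALSE,
  # data_range=1 on this exact seeded fixture
  set.seed(42)
  x <- matrix(stats::runif(32 * 32), 32)
  y <- pmin(pmax(x + matrix(stats::rnorm(32 * 32, 0, 0.1), 32), 0), 1)
  expect_equal(ssim(x, y), 0.9465330595, tolerance = 1e-8)
  expect_equal(psnr(x, y), 20.6051987960, tolerance = 1e-8)
  expect_equal(ssim(x, x), 1)
  # structural dissimilarity with the negative
  expect_lt(ssim(x, 1 - x), 0.5)
  expect_error(ssim(x, matrix(0, 8, 8)), "dim")
})

test_that("mtf bandwidth finds the outermost above-threshold frequency", {
  # delta PSF: full band up to Nyquist
  d <- matrix(0, 32, 32); d[17, 17] <- 1
  md <- mtf_from_psf(d)
  expect_equal(mtf_bandwidth(md, 0.1), max(md$frequencies))
  # threshold 1: only DC qualifies for a blurred PSF
  sys <- toy_system(16L)
  psf <- psf_from_pupil(assemble_pupil(sys,
                                       defocus_phase = defocus_phase_map(sys, 6)))
  m <- mtf_from_psf(psf)
  expect_equal(mtf_bandwidth(m, 1), 0)
  # clear-aperture cutoff within one frequency bin of the autocorrelation
  # support edge
  pupil <- assemble_pupil(sys)
  psf0 <- psf_from_pupil(pupil, pad_factor = 2L)
  m0 <- mtf_from_psf(psf0)
  ac <- brute_autocorrelation(pupil$amplitude)
  prof <- ac[16, 16:31] / max(ac)                # radial cut of the support
  cut_oracle <- (max(which(prof >= 0.1)) - 1) / 32
  expect_lt(abs(mtf_bandwidth(m0, 0.1) - cut_oracle), 1.5 / 32)
})

test_that("depth invariance score is zero iff PSFs coincide, order-free", {
  sys <- toy_system(32L)
  psf <- psf_from_pupil(assemble_pupil(sys), psf_size = 33L)
  same <- structure(list(depths = c(1, 2, 3) * 1e-3,
                         psfs = list(psf, psf, psf)), class = "psf_stack")
  expect_equal(depth_invariance_score(same), 0)
  stack <- psf_stack(sys, c(3.8e-3, 4e-3, 4.2e-3), psf_size = 33L)
  s1 <- depth_invariance_score(stack)
  expect_gt(s1, 0)
  perm <- stack; perm$psfs <- stack$psfs[c(3, 1, 2)]
  expect_equal(depth_invariance_score(perm), s1)
  # focused-vs-strongly-defocused pair scores worse than two equal
  # defocus levels
  st_mixed <- psf_stack(sys, c(4e-3, 3.6e-3), psf_size = 33L)
  st_equal <- psf_stack(sys, c(3.6e-3, 3.6001e-3), psf_size = 33L)
  expect_gt(depth_invariance_score(st_mixed),
            depth_invariance_score(st_equal))
})

test_that("depth evaluation reports per-depth PSNR/SSIM reproducibly", {
  sys <- toy_system(16L)
  net <- build_network(network_spec(base_channels = 8L), seed = 1)
  imgs <- toy_images(2, 64L, seed = 7L)
  depths <- sample_depths(depth_spec(3.9e-3, 4.1e-3, 4e-3, 3L))
  mask <- free_phase_mask(matrix(0, 16, 16))
  rep1 <- evaluate_depths(sys, mask, net, imgs, depths, patch_size = 48L,
                          sigma_s = 0.01, seed = 5, psf_size = 17L)
  expect_s3_class(rep1, "metrics_report")
  expect_equal(nrow(rep1$per_depth), 3)
  expect_true(all(rep1$per_depth$ssim >= -1 & rep1$per_depth$ssim <= 1))
  rep2 <- evaluate_depths(sys, mask, net, imgs, depths, patch_size = 48L,
                          sigma_s = 0.01, seed = 5, psf_size = 17L)
  expect_identical(rep1$per_depth, rep2$per_depth)
})

test_that("robustness table: sigma = 0 reproduces the unperturbed metrics", {
  sys <- toy_system(16L)
  net <- build_network(network_spec(base_channels = 8L), seed = 2)
  imgs <- toy_images(1, 64L, seed = 9L)
  depths <- c(3.9e-3, 4.1e-3)
  mask <- doe_mask(matrix(200e-9, 16, 16))
  spec <- robustness_spec(c(0, 50e-9), n_trials = 2L, seed = 3L)
  tab <- fabrication_robustness(mask, spec, sys, net, imgs, depths,
                                patch_size = 48L, sigma_s = 0.01,
                                psf_size = 17L)
  expect_identical(tab$sigma_nm, c(0, 50))
  # the sigma = 0 row equals the mean over trials of the unperturbed
  # evaluation under the same per-trial noise seeds
  base <- vapply(1:2, function(tr) {
    evaluate_depths(sys, mask, net, imgs, depths, patch_size = 48L,
                    sigma_s = 0.01, seed = derive_seed(3L, "eval", tr),
                    psf_size = 17L)$mean_psnr
  }, numeric(1))
  expect_equal(tab$mean_psnr_db[1], mean(base), tolerance = 1e-12)
})
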