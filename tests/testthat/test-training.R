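# Depth sampling, loss, end-to-end differentiability, training stages.

test_that("depth sampling is uniform in diopters with endpoints included", {
  spec <- depth_spec(3e-3, 5e-3, 4e-3, 5L)
  z <- sample_depths(spec)
  expect_length(z, 5)
  expect_equal(min(z), 3e-3)
  expect_equal(max(z), 5e-3)
  expect_lt(stats::sd(diff(1 / z)), 1e-12)        # constant diopter spacing
  # single sample: the diopter midpoint
  z1 <- sample_depths(depth_spec(3e-3, 5e-3, 4e-3, 1L))
  expect_equal(1 / z1, (1 / 3e-3 + 1 / 5e-3) / 2)
  # depths are not uniform in z (diopter spacing concentrates near z_min)
  expect_gt(diff(z)[4], diff(z)[1])
})

test_that("rmse loss matches its closed forms", {
  gt <- matrix(0, 2, 2)
  expect_identical(rmse_loss(gt, gt), 0)
  r <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(rmse_loss(gt, r), 0.5)             # sqrt(1/4)
  # depth averaging of per-depth RMSEs 0.2 and 0.4
  r1 <- matrix(0.2, 2, 2); r2 <- matrix(0.4, 2, 2)
  expect_equal(rmse_loss(gt, list(r1, r2)), 0.3)
  # gradient against finite differences
  set.seed(1)
  a <- matrix(stats::runif(16), 4); b <- matrix(stats::runif(16), 4)
  g <- edofscope:::rmse_loss_grad(a, b)
  eps <- 1e-7
  bp <- b; bp[7] <- bp[7] + eps
  expect_equal(g[7], (rmse_loss(a, bp) - rmse_loss(a, b)) / eps,
               tolerance = 1e-4)
})

test_that("backpropagated mask gradient matches finite differences (16x16 pupil)", {
  sys <- toy_system(16L)
  net <- build_network(network_spec(base_channels = 8L), seed = 7)
  set.seed(11)
  patch <- matrix(stats::runif(32 * 32, 0.15, 0.85), 32)
  mask <- free_phase_mask(matrix(stats::rnorm(256, 0, 0.3), 16))
  z <- 3.9e-3
  lg <- loss_and_mask_gradient(sys, mask, net, patch, z,
                               patch_size = 32L, psf_size = 17L)
  f <- function(m) loss_and_mask_gradient(sys, m, net, patch, z,
                                          patch_size = 32L,
                                          psf_size = 17L)$loss
  eps <- 1e-5
  set.seed(2)
  idx <- order(-abs(lg$grad))[c(1, 5, 20)]
  for (i in idx) {
    mp <- mask; mp$phase[i] <- mp$phase[i] + eps
    mm <- mask; mm$phase[i] <- mm$phase[i] - eps
    fd <- (f(mp) - f(mm)) / (2 * eps)
    expect_equal(lg$grad[i], fd, tolerance = 1e-3,
                 label = sprintf("mask-phase gradient at %d", i))
  }
  # the DOE height parameterization carries the k (n - 1) Jacobian
  doe <- doe_mask(matrix(stats::runif(256, 0, 500e-9), 16))
  lgd <- loss_and_mask_gradient(sys, doe, net, patch, z,
                                patch_size = 32L, psf_size = 17L)
  i <- which.max(abs(lgd$grad))
  epsh <- 1e-12
  dp <- doe; dp$height_map[i] <- dp$height_map[i] + epsh
  dm <- doe; dm$height_map[i] <- dm$height_map[i] - epsh
  fd <- (loss_and_mask_gradient(sys, dp, net, patch, z, 32L, 17L)$loss -
           loss_and_mask_gradient(sys, dm, net, patch, z, 32L, 17L)$loss) /
    (2 * epsh)
  expect_equal(lgd$grad[i], fd, tolerance = 1e-3)
})

make_smoke_setup <- function(seed = 100L, grid = 32L, n_images = 3L) {
  p <- objective_preset("mitutoyo50x")
  sys <- optical_system(z0 = p$z0, pupil_diameter = p$pupil_diameter,
                        tube_focal_length = p$tube_focal_length,
                        grid_size = grid, na = p$na)
  ds <- depth_spec(p$z0 - 100e-6, p$z0 + 100e-6, p$z0, 5L)
  imgs <- toy_images(n_images, 128L, seed)
  net <- build_network(network_spec(base_channels = 8L),
                       seed = derive_seed(seed, "net"))
  mask <- free_phase_mask(with_local_seed(derive_seed(seed, "mask"), {
    matrix(stats::rnorm(grid^2, 0, 0.1), grid)
  }) * aperture_amplitude(sys))
  cfg <- train_config(ds, lr_optics = 5e-3, lr_network = 1e-4,
                      stage1_steps = 30L, joint_steps = 30L,
                      patch_size = 32L, sigma_s = 0.01, seed = seed,
                      psf_size = 17L)
  list(sys = sys, ds = ds, imgs = imgs, net = net, mask = mask, cfg = cfg)
}

test_that("stage-1 training reduces the loss and is reproducible", {
  s <- make_smoke_setup()
  r1 <- train_stage1(s$cfg, s$sys, s$mask, s$net, s$imgs)
  expect_lt(mean(utils::tail(r1$loss, 10)), mean(utils::head(r1$loss, 10)))
  # bit-identical trace across two runs with the same seed
  r2 <- train_stage1(s$cfg, s$sys, s$mask, s$net, s$imgs)
  expect_identical(r1$loss, r2$loss)
  # zero steps leaves the network untouched
  r0 <- train_stage1(s$cfg, s$sys, s$mask, s$net, s$imgs, steps = 0L)
  expect_identical(r0$net$params, s$net$params)
})

test_that("joint training moves the mask; lr_optics = 0 freezes it", {
  s <- make_smoke_setup()
  r <- train_joint(s$cfg, s$sys, s$mask, s$net, s$imgs, steps = 10L)
  expect_gt(max(abs(r$mask$phase - s$mask$phase)), 0)
  expect_identical(r$net$training_stage, "joint")
  cfg0 <- s$cfg; cfg0$lr_optics <- 0
  r0 <- train_joint(cfg0, s$sys, s$mask, s$net, s$imgs, steps = 10L)
  expect_identical(r0$mask$phase, s$mask$phase)
  # frozen-optics joint run accepts a non-learnable (cubic) mask
  rc <- train_joint(cfg0, s$sys, cubic_mask(6 * pi, 32L), s$net, s$imgs,
                    steps = 2L)
  expect_s3_class(rc$mask, "cubic_mask")
  # ... but learning it is an error
  expect_error(train_joint(s$cfg, s$sys, cubic_mask(6 * pi, 32L), s$net,
                           s$imgs, steps = 2L), "not learnable")
})
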