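# End-to-end optimization: depth sampling in diopters, RMSE loss, the
# differentiable optics chain (mask phase -> pupil -> PSF -> sensor), and
# the two-stage schedule (network-only, then joint optics + network).
#
# The learnable optical parameter is the pupil phase map itself (a
# free_phase_mask) or, for a DOE, its height map (phase linear in height);
# conversion to a fabricable radius map happens at export time.

#' Sample depth positions uniformly in diopters
#'
#' Returns M depths whose reciprocals are equally spaced between
#' 1/z_max and 1/z_min, endpoints included (M = 1 yields the diopter
#' midpoint). Uniform diopter spacing makes the defocus coefficient psi
#' vary linearly across the samples.
#'
#' @param spec a [depth_spec()].
#' @return increasing vector of M depths in meters.
#' @export
sample_depths <- function(spec) {
  stopifnot(inherits(spec, "depth_spec"))
  m <- spec$n_depths
  if (m == 1) return(2 / (1 / spec$z_min + 1 / spec$z_max))
  diopters <- seq(1 / spec$z_max, 1 / spec$z_min, length.out = m)
  sort(1 / diopters)
}

#' Depth-averaged RMSE loss
#'
#' Mean over depths of the per-depth root-mean-square pixel error
#' sqrt((1/N) * sum((I - I_R)^2)) between the ground truth and each
#' reconstruction.
#'
#' @param ground_truth reference image matrix.
#' @param reconstructions a matrix or list of matrices (one per depth).
#' @return scalar loss.
#' @export
rmse_loss <- function(ground_truth, reconstructions) {
  if (is.matrix(reconstructions)) reconstructions <- list(reconstructions)
  stopifnot(length(reconstructions) >= 1)
  mean(vapply(reconstructions, function(r) {
    stopifnot(all(dim(r) == dim(ground_truth)))
    sqrt(mean((ground_truth - r)^2))
  }, numeric(1)))
}

# Gradient of rmse_loss with respect to one reconstruction (index i of M).
rmse_loss_grad <- function(ground_truth, reconstruction, m = 1L) {
  n <- length(reconstruction)
  r <- sqrt(mean((ground_truth - reconstruction)^2))
  if (r == 0) return(matrix(0, nrow(reconstruction), ncol(reconstruction)))
  (reconstruction - ground_truth) / (m * n * r)
}

#' Training configuration
#'
#' Defaults follow the study protocol: M = 5 depth positions uniform in
#' diopters, Adam with learning rates 1e-7 (optics) and 1e-4 (network),
#' Gaussian sensor noise sigma_s = 0.01, random crops with 90-degree
#' rotations, flips and +/- 10 % brightness augmentation.
#'
#' @param depth_spec a [depth_spec()].
#' @param lr_optics optics learning rate.
#' @param lr_network network learning rate.
#' @param stage1_steps,joint_steps step budgets of the two stages.
#' @param patch_size training patch side (multiple of 16).
#' @param sigma_s sensor noise standard deviation.
#' @param seed integer seed governing patch sampling, augmentation and
#'   sensor noise.
#' @param psf_size side of the cropped PSF kernels used for rendering.
#' @param pad_factor pupil zero-padding factor.
#' @param brightness_range multiplicative brightness augmentation range.
#' @return a `train_config` list.
#' @export
train_config <- function(depth_spec, lr_optics = 1e-7, lr_network = 1e-4,
                         stage1_steps = 200L, joint_steps = 300L,
                         patch_size = 256L, sigma_s = 0.01, seed = 1L,
                         psf_size = NULL, pad_factor = 2L,
                         brightness_range = c(0.9, 1.1)) {
  stopifnot(inherits(depth_spec, "depth_spec"), lr_optics >= 0,
            lr_network > 0, patch_size %% 16 == 0, sigma_s >= 0)
  structure(list(depth_spec = depth_spec, lr_optics = lr_optics,
                 lr_network = lr_network,
                 stage1_steps = as.integer(stage1_steps),
                 joint_steps = as.integer(joint_steps),
                 patch_size = as.integer(patch_size), sigma_s = sigma_s,
                 seed = as.integer(seed), psf_size = psf_size,
                 pad_factor = as.integer(pad_factor),
                 brightness_range = brightness_range),
            class = "train_config")
}

# ---- learnable-mask plumbing -----------------------------------------------

mask_param <- function(mask) {
  if (inherits(mask, "free_phase_mask")) mask$phase
  else if (inherits(mask, "doe_mask")) mask$height_map
  else stop("mask type '", class(mask)[1], "' is not learnable; use a ",
            "free_phase_mask or doe_mask")
}

mask_param_set <- function(mask, theta) {
  if (inherits(mask, "free_phase_mask")) mask$phase <- theta
  else mask$height_map <- pmax(theta, 0)
  mask
}

# d(phase)/d(parameter): 1 for a free phase, k (n - 1) for a DOE height map.
mask_phase_jacobian <- function(mask, system) {
  if (inherits(mask, "doe_mask")) {
    wavenumber(system$wavelength) * (mask$refractive_index - 1)
  } else 1
}

# ---- differentiable optics chain -------------------------------------------

# PSF forward pass retaining what the backward pass needs.
psf_forward <- function(system, mask_phase_map, psi, pad_factor = 2L,
                        psf_size = NULL, amplitude = NULL) {
  pupil <- assemble_pupil(system, mask_phase_map,
                          defocus_phase_map(system, psi),
                          amplitude = amplitude)
  n <- system$grid_size
  np <- as.integer(round(pad_factor * n))
  p <- matrix(0 + 0i, np, np)
  p[1:n, 1:n] <- pupil$amplitude * exp(1i * pupil$phase)
  u <- stats::fft(p)
  intens <- fftshift2(Mod(u)^2)
  if (is.null(psf_size)) psf_size <- np
  cropped <- crop_center(intens, psf_size)
  s <- sum(cropped)
  list(psf = cropped / s,
       cache = list(p = p, u = u, s = s, psf = cropped / s, n = n, np = np,
                    psf_size = psf_size))
}

# Backward: gradient of the loss w.r.t. the mask phase map, given the
# gradient w.r.t. the unit-sum PSF.
psf_backward <- function(cache, dpsf) {
  # unit-sum normalization
  dcrop <- (dpsf - sum(dpsf * cache$psf)) / cache$s
  # undo the center crop (zero-pad into the shifted intensity frame)
  np <- cache$np
  g <- matrix(0, np, np)
  c0 <- floor(np / 2) + 1
  half <- floor(cache$psf_size / 2)
  i1 <- c0 - half
  g[i1:(i1 + cache$psf_size - 1), i1:(i1 + cache$psf_size - 1)] <- dcrop
  g <- fftshift2(g, inverse = TRUE)
  # |U|^2 and the unnormalized DFT: adjoint of fft is the unnormalized ifft
  gu <- 2 * g * cache$u
  gp <- stats::fft(gu, inverse = TRUE)
  # phase gradient: P = A exp(i phi) => dL/dphi = Re(conj(G_P) * i * P)
  n <- cache$n
  Re(Conj(gp[1:n, 1:n]) * 1i * cache$p[1:n, 1:n])
}

# One differentiable rendering + deblurring pass at a single depth.
# Returns the loss, the network gradients and the mask-phase gradient.
forward_backward_step <- function(system, mask, net, patch, z, config,
                                  noise_seed, training = TRUE,
                                  want_mask_grad = TRUE) {
  psi <- defocus_coefficient(z, system$z0, system$effective_radius,
                             system$wavelength)
  pf <- psf_forward(system, mask_phase(mask, system), psi,
                    pad_factor = config$pad_factor,
                    psf_size = config$psf_size,
                    amplitude = mask_amplitude(mask, system))
  fc <- fft_conv_same(patch, pf$psf)
  blurred <- crop_center(fc$out, config$patch_size)
  noisy <- blurred
  if (config$sigma_s > 0) {
    noisy <- noisy + with_local_seed(noise_seed, {
      matrix(stats::rnorm(length(blurred), 0, config$sigma_s),
             nrow(blurred))
    })
  }
  sensor <- clip01(noisy)
  nf <- net_forward(net, sensor, training = training)
  gt <- crop_center(patch, config$patch_size)
  loss <- rmse_loss(gt, nf$out)
  dout <- rmse_loss_grad(gt, nf$out)
  nb <- net_backward(net, nf$cache, dout)
  dmask_phase <- NULL
  if (want_mask_grad) {
    dsensor <- nb$dx * (noisy > 0 & noisy < 1)
    # undo the center crop of the blurred frame
    d <- dim(fc$out)
    gfull <- matrix(0, d[1], d[2])
    c0 <- floor(d / 2) + 1
    half <- floor(config$patch_size / 2)
    i1 <- c0 - half
    gfull[i1[1]:(i1[1] + config$patch_size - 1),
          i1[2]:(i1[2] + config$patch_size - 1)] <- dsensor
    dpsf <- fft_conv_grad_psf(fc$cache, gfull)
    dmask_phase <- psf_backward(pf$cache, dpsf)
  }
  list(loss = loss, grads = nb$grads, dmask_phase = dmask_phase,
       new_stats = nf$cache$new_stats, sensor = sensor, output = nf$out)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- augmentation and patch sampling ---------------------------------------

sample_patch <- function(images, patch_size, brightness_range) {
  img <- images[[sample.int(length(images), 1)]]
  d <- dim(img)
  if (any(d < patch_size)) stop("training image smaller than the patch size")
  i <- sample.int(d[1] - patch_size + 1, 1)
  j <- sample.int(d[2] - patch_size + 1, 1)
  p <- img[i:(i + patch_size - 1), j:(j + patch_size - 1)]
  k <- sample.int(4, 1) - 1L            # quarter-turn rotations
  if (k > 0) for (q in seq_len(k)) p <- t(p[nrow(p):1, ])
  if (stats::runif(1) < 0.5) p <- p[nrow(p):1, ]
  if (stats::runif(1) < 0.5) p <- p[, ncol(p):1]
  clip01(p * stats::runif(1, brightness_range[1], brightness_range[2]))
}

# ---- training stages -------------------------------------------------------

#' Stage 1: train the network with fixed optics
#'
#' Cycles through the M sampled depths (one depth per patch per step,
#' matching the sequential per-depth loss evaluation), rendering each
#' augmented patch through the frozen mask's depth-dependent PSF and
#' updating only the network by Adam. PSFs are precomputed once since the
#' optics do not move.
#'
#' @param config a [train_config()].
#' @param system an [optical_system()].
#' @param mask any mask with a [mask_phase()] method.
#' @param net an `edof_net` from [build_network()].
#' @param images list of training images (matrices in `[0, 1]`).
#' @param steps number of optimization steps (default
#'   `config$stage1_steps`); 0 returns the network unchanged.
#' @return list with the updated `net` and the per-step `loss` trace.
#' @export
train_stage1 <- function(config, system, mask, net, images,
                         steps = config$stage1_steps) {
  depths <- sample_depths(config$depth_spec)
  phase_map <- mask_phase(mask, system)
  amp <- mask_amplitude(mask, system)
  psfs <- lapply(depths, function(z) {
    psi <- defocus_coefficient(z, system$z0, system$effective_radius,
                               system$wavelength)
    psf_forward(system, phase_map, psi, config$pad_factor,
                config$psf_size, amp)$psf
  })
  losses <- numeric(steps)
  if (steps == 0) return(list(net = net, loss = losses))
  opt <- adam_init(net$params)
  with_local_seed(derive_seed(config$seed, "stage1"), {
    for (step in seq_len(steps)) {
      patch <- sample_patch(images, config$patch_size,
                            config$brightness_range)
      di <- ((step - 1L) %% length(depths)) + 1L
      fc <- fft_conv_same(patch, psfs[[di]])
      blurred <- crop_center(fc$out, config$patch_size)
      noisy <- blurred + matrix(stats::rnorm(length(blurred), 0,
                                             config$sigma_s), nrow(blurred))
      sensor <- clip01(noisy)
      nf <- net_forward(net, sensor, training = TRUE)
      gt <- crop_center(patch, config$patch_size)
      losses[step] <- rmse_loss(gt, nf$out)
      if (!is.finite(losses[step])) {
        stop(sprintf("training diverged at step %d (loss = %g)", step,
                     losses[step]))
      }
      nb <- net_backward(net, nf$cache, rmse_loss_grad(gt, nf$out))
      upd <- adam_step(net$params, nb$grads, opt, config$lr_network)
      net$params <- upd$params
      opt <- upd$state
      net$stats <- nf$cache$new_stats
    }
  })
  net$training_stage <- "stage1"
  list(net = net, loss = losses)
}

#' Stage 2: joint optimization of optics and network
#'
#' Both the mask parameter (phase map or DOE height map) and the network
#' weights receive Adam updates at their respective learning rates; the
#' loss gradient reaches the mask through the sensor image, the PSF and
#' the pupil phase. Setting `config$lr_optics = 0` freezes the mask and
#' reduces to stage-1 behavior.
#'
#' @inheritParams train_stage1
#' @param steps number of joint steps (default `config$joint_steps`).
#' @return list with the updated `mask`, `net` and the `loss` trace.
#' @export
train_joint <- function(config, system, mask, net, images,
                        steps = config$joint_steps) {
  learn_mask <- config$lr_optics > 0
  depths <- sample_depths(config$depth_spec)
  losses <- numeric(steps)
  if (steps == 0) return(list(mask = mask, net = net, loss = losses))
  opt_net <- adam_init(net$params)
  if (learn_mask) {
    # errors out for non-learnable masks (e.g. cubic)
    opt_mask <- adam_init(list(theta = mask_param(mask)))
    jac <- mask_phase_jacobian(mask, system)
  }
  base_seed <- derive_seed(config$seed, "joint")
  with_local_seed(base_seed, {
    for (step in seq_len(steps)) {
      patch <- sample_patch(images, config$patch_size,
                            config$brightness_range)
      di <- ((step - 1L) %% length(depths)) + 1L
      fb <- forward_backward_step(system, mask, net, patch, depths[di],
                                  config,
                                  noise_seed = derive_seed(base_seed, step),
                                  training = TRUE,
                                  want_mask_grad = learn_mask)
      losses[step] <- fb$loss
      if (!is.finite(losses[step])) {
        stop(sprintf("training diverged at step %d (loss = %g)", step,
                     losses[step]))
      }
      upd <- adam_step(net$params, fb$grads, opt_net, config$lr_network)
      net$params <- upd$params
      opt_net <- upd$state
      net$stats <- fb$new_stats
      if (learn_mask) {
        gtheta <- fb$dmask_phase * jac
        updm <- adam_step(list(theta = mask_param(mask)),
                          list(theta = gtheta), opt_mask, config$lr_optics)
        opt_mask <- updm$state
        mask <- mask_param_set(mask, updm$params$theta)
      }
    }
  })
  net$training_stage <- "joint"
  list(mask = mask, net = net, loss = losses)
}

#' End-to-end loss and its mask-phase gradient at one depth
#'
#' Convenience wrapper used for verifying end-to-end differentiability:
#' computes the depth-averaged RMSE loss of the full pipeline (mask ->
#' PSF -> sensor -> network) and the backpropagated gradient with respect
#' to the mask parameter, with sensor noise disabled so the map is
#' deterministic.
#'
#' @param system an [optical_system()].
#' @param mask a learnable mask (free phase or DOE).
#' @param net an `edof_net`.
#' @param patch scene patch matrix.
#' @param z depth in meters.
#' @param patch_size crop size (multiple of 16).
#' @param psf_size PSF crop side.
#' @return list with `loss` and `grad` (matrix like the mask parameter).
#' @export
loss_and_mask_gradient <- function(system, mask, net, patch, z,
                                   patch_size = nrow(patch),
                                   psf_size = NULL) {
  config <- train_config(depth_spec(z * 0.9, z * 1.1,
                                    z), # placeholder spec; unused fields
                         patch_size = patch_size, sigma_s = 0,
                         psf_size = psf_size)
  config$depth_spec$z0 <- system$z0
  fb <- forward_backward_step(system, mask, net, patch, z, config,
                              noise_seed = 1L, training = TRUE,
                              want_mask_grad = TRUE)
  list(loss = fb$loss, grad = fb$dmask_phase * mask_phase_jacobian(mask, system))
}
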