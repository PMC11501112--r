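# Image-quality metrics, MTF depth-invariance analysis and the
# fabrication-error robustness protocol.

#' Peak signal-to-noise ratio
#'
#' 10 log10(peak^2 / MSE) in dB. Identical images yield +Inf; tabular
#' reports cap the value at 99 dB to stay numeric (see
#' [fabrication_robustness()]).
#'
#' @param reference,test matrices of equal shape.
#' @param peak peak signal value (1 for `[0, 1]` images).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test, peak = 1) {
  stopifnot(all(dim(reference) == dim(test)))
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index (single scale)
#'
#' Mean local SSIM with an 11-tap Gaussian window (sigma = 1.5), stability
#' constants K1 = 0.01 and K2 = 0.03, and unit dynamic range -- the
#' standard single-scale formulation. Local statistics use the Gaussian
#' window itself (no sample-covariance correction) and the mean is taken
#' over the fully valid interior.
#'
#' @param reference,test matrices of equal shape with values in `[0, 1]`.
#' @param sigma Gaussian window standard deviation.
#' @param window window width in samples (odd).
#' @param K1,K2 stability constants.
#' @param data_range dynamic range of the data.
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, sigma = 1.5, window = 11L,
                 K1 = 0.01, K2 = 0.03, data_range = 1) {
  stopifnot(all(dim(reference) == dim(test)))
  if (any(dim(reference) < window)) stop("images smaller than the SSIM window")
  r <- (window - 1) / 2
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  smooth <- function(x) {
    # separable valid-region Gaussian filtering
    n1 <- nrow(x); n2 <- ncol(x)
    rowf <- vapply(seq_len(n1 - window + 1),
                   function(i) colSums(x[i:(i + window - 1), , drop = FALSE] * w),
                   numeric(n2))            # n2 x (n1 - window + 1)
    vapply(seq_len(n2 - window + 1),
           function(j) colSums(rowf[j:(j + window - 1), , drop = FALSE] * w),
           numeric(n1 - window + 1))       # (n1-w+1) x (n2-w+1)
  }
  ux <- smooth(reference); uy <- smooth(test)
  uxx <- smooth(reference^2); uyy <- smooth(test^2)
  uxy <- smooth(reference * test)
  vx <- uxx - ux^2; vy <- uyy - uy^2
  cxy <- uxy - ux * uy
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  s <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Effective MTF bandwidth at a contrast threshold
#'
#' The largest radial frequency at which the radially averaged MTF still
#' reaches the threshold; the band edge of information the optics can
#' transmit at usable contrast.
#'
#' @param mtf an `mtf_curve` from [mtf_from_psf()].
#' @param threshold contrast threshold in (0, 1]; 0.1 by convention.
#' @return frequency in cycles per sample (0 if only DC qualifies).
#' @export
mtf_bandwidth <- function(mtf, threshold = 0.1) {
  stopifnot(inherits(mtf, "mtf_curve"), threshold > 0, threshold <= 1)
  ok <- which(mtf$radial >= threshold - 1e-12)
  if (length(ok) == 0) return(0)
  mtf$frequencies[max(ok)]
}

#' Depth-invariance score of a PSF stack
#'
#' Mean pairwise Euclidean distance between the radially averaged MTFs of
#' all depths; 0 iff all MTFs coincide, invariant to depth reordering.
#' Lower is better for depth-agnostic deblurring.
#'
#' @param stack a [psf_stack()] with at least two depths.
#' @return non-negative scalar.
#' @export
depth_invariance_score <- function(stack) {
  stopifnot(inherits(stack, "psf_stack"), length(stack$psfs) >= 2)
  profiles <- lapply(stack$psfs, function(p) mtf_from_psf(p)$radial)
  m <- length(profiles)
  tot <- 0; np <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    tot <- tot + sqrt(sum((profiles[[i]] - profiles[[j]])^2))
    np <- np + 1
  }
  tot / np
}

#' Evaluate reconstruction quality across the depth range
#'
#' Renders each test image at each depth through the mask's PSF, adds
#' sensor noise, deblurs with the network and scores PSNR/SSIM against
#' the ground truth, mirroring the protocol of assigning test images to
#' depths uniformly distributed over the target range.
#'
#' @param system an [optical_system()].
#' @param mask any mask with a [mask_phase()] method.
#' @param net an `edof_net`.
#' @param images list of test images (matrices in `[0, 1]`).
#' @param depths vector of evaluation depths (m).
#' @param patch_size rendered/evaluated patch side (multiple of 16).
#' @param sigma_s sensor noise standard deviation.
#' @param seed seed for the sensor noise.
#' @param psf_size,pad_factor PSF rendering controls.
#' @return a `metrics_report`: data.frame `per_depth` (depth, psnr_db,
#'   ssim) plus `mean_psnr` and `mean_ssim`.
#' @export
evaluate_depths <- function(system, mask, net, images, depths,
                            patch_size = 256L, sigma_s = 0.01, seed = 1L,
                            psf_size = NULL, pad_factor = 2L) {
  stopifnot(length(images) >= 1, length(depths) >= 1)
  phase_map <- mask_phase(mask, system)
  amp <- mask_amplitude(mask, system)
  rows <- list()
  for (di in seq_along(depths)) {
    psi <- defocus_coefficient(depths[di], system$z0,
                               system$effective_radius, system$wavelength)
    psf <- psf_forward(system, phase_map, psi, pad_factor, psf_size, amp)$psf
    ps <- numeric(length(images)); ss <- numeric(length(images))
    for (ii in seq_along(images)) {
      gt <- crop_center(images[[ii]], patch_size)
      blurred <- render_slice(images[[ii]], psf, patch_size)
      sensor <- render_sensor(blurred, sigma_s,
                              seed = derive_seed(seed, di, ii))
      rec <- deblur(net, sensor)
      ps[ii] <- psnr(gt, rec)
      ss[ii] <- ssim(gt, rec)
    }
    rows[[di]] <- data.frame(depth = depths[di], psnr_db = mean(ps),
                             ssim = mean(ss))
  }
  per_depth <- do.call(rbind, rows)
  structure(list(per_depth = per_depth,
                 mean_psnr = mean(per_depth$psnr_db),
                 mean_ssim = mean(per_depth$ssim)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_depth, row.names = FALSE)
  cat(sprintf("  mean PSNR %.2f dB, mean SSIM %.4f\n",
              x$mean_psnr, x$mean_ssim))
  invisible(x)
}

#' Robustness specification for fabrication-error analysis
#'
#' @param sigma_levels fabrication noise standard deviations in meters
#'   (include 0 for the unperturbed baseline); the studied levels are
#'   5 and 12 nm for metalens radii, 30 and 50 nm for DOE heights.
#' @param n_trials independent perturbation draws per level.
#' @param seed base seed.
#' @return a `robustness_spec` list.
#' @export
robustness_spec <- function(sigma_levels, n_trials = 10L, seed = 1L) {
  stopifnot(all(sigma_levels >= 0), n_trials >= 1)
  structure(list(sigma_levels = sigma_levels,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "robustness_spec")
}

#' Fabrication-error robustness table
#'
#' For each noise level, perturbs the fabricated mask quantities
#' (heights or radii) `n_trials` times, re-evaluates PSNR/SSIM with the
#' unmodified network and reports the means. Sensor-noise seeds depend
#' only on the trial (not the level), so the sigma = 0 rows reproduce the
#' unperturbed evaluation exactly.
#'
#' @param mask a [doe_mask()] or [metalens_mask()].
#' @param spec a [robustness_spec()].
#' @inheritParams evaluate_depths
#' @param psnr_cap finite cap replacing infinite PSNR in the table.
#' @return data.frame with columns `sigma_nm`, `mean_psnr_db`,
#'   `mean_ssim`, `n_trials`.
#' @export
fabrication_robustness <- function(mask, spec, system, net, images, depths,
                                   patch_size = 256L, sigma_s = 0.01,
                                   psf_size = NULL, pad_factor = 2L,
                                   psnr_cap = 99) {
  stopifnot(inherits(spec, "robustness_spec"))
  rows <- lapply(spec$sigma_levels, function(sig) {
    ps <- numeric(spec$n_trials); ss <- numeric(spec$n_trials)
    for (tr in seq_len(spec$n_trials)) {
      pmask <- perturb_mask(mask, sig, seed = derive_seed(spec$seed, "fab",
                                                          sig * 1e9, tr))
      rep <- evaluate_depths(system, pmask, net, images, depths,
                             patch_size = patch_size, sigma_s = sigma_s,
                             seed = derive_seed(spec$seed, "eval", tr),
                             psf_size = psf_size, pad_factor = pad_factor)
      ps[tr] <- min(rep$mean_psnr, psnr_cap)
      ss[tr] <- rep$mean_ssim
    }
    data.frame(sigma_nm = sig * 1e9, mean_psnr_db = mean(ps),
               mean_ssim = mean(ss), n_trials = spec$n_trials)
  })
  do.call(rbind, rows)
}
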