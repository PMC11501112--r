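# Sensor image formation: depth-slice convolution with the PSF
# (pad-convolve-crop), depth integration, and Gaussian sensor noise.
#
# Convolution is FFT-based. The scene patch is zero-padded by half the PSF
# support on each side, the PSF is embedded (center at the DFT origin) in
# the padded frame, and the product of transforms is inverted; the padding
# guarantees the centered region equals exact linear convolution with no
# circular wrap-around. fft_conv_same() exposes the cache and adjoint used
# by the differentiable training path.

#' FFT linear convolution with a centered kernel ("same" output)
#'
#' @param image H x W matrix.
#' @param psf kernel matrix with its center at index floor(P/2) + 1.
#' @return list with `out` (H x W linear convolution) and `cache` for
#'   [fft_conv_grad_psf()] / [fft_conv_grad_image()].
#' @export
fft_conv_same <- function(image, psf) {
  hw <- dim(image); pd <- dim(psf)
  pad <- floor(pd / 2)
  L <- hw + 2 * pad
  impad <- matrix(0, L[1], L[2])
  impad[(pad[1] + 1):(pad[1] + hw[1]), (pad[2] + 1):(pad[2] + hw[2])] <- image
  # embed kernel with its center at (1, 1) circularly
  ci <- floor(pd / 2) + 1
  kfull <- matrix(0, L[1], L[2])
  ri <- ((seq_len(pd[1]) - ci[1]) %% L[1]) + 1
  rj <- ((seq_len(pd[2]) - ci[2]) %% L[2]) + 1
  kfull[ri, rj] <- psf
  FI <- stats::fft(impad)
  FK <- stats::fft(kfull)
  full <- Re(stats::fft(FI * FK, inverse = TRUE)) / prod(L)
  out <- full[(pad[1] + 1):(pad[1] + hw[1]), (pad[2] + 1):(pad[2] + hw[2])]
  list(out = out,
       cache = list(FI = FI, FK = FK, pad = pad, hw = hw, pd = pd, L = L,
                    ri = ri, rj = rj))
}

#' Adjoint passes of [fft_conv_same()]
#'
#' Given the gradient of a scalar loss with respect to the "same" output,
#' returns the gradient with respect to the PSF (or the image).
#'
#' @param cache cache list from [fft_conv_same()].
#' @param gout gradient matrix matching the `out` shape.
#' @return gradient with respect to the psf (same shape as the kernel).
#' @export
fft_conv_grad_psf <- function(cache, gout) {
  gfull <- matrix(0, cache$L[1], cache$L[2])
  gfull[(cache$pad[1] + 1):(cache$pad[1] + cache$hw[1]),
        (cache$pad[2] + 1):(cache$pad[2] + cache$hw[2])] <- gout
  gk_full <- Re(stats::fft(Conj(cache$FI) * stats::fft(gfull),
                           inverse = TRUE)) / prod(cache$L)
  gk_full[cache$ri, cache$rj]
}

#' @rdname fft_conv_grad_psf
#' @return for [fft_conv_grad_image()]: gradient with respect to the
#'   image (same shape as the image).
#' @export
fft_conv_grad_image <- function(cache, gout) {
  gfull <- matrix(0, cache$L[1], cache$L[2])
  gfull[(cache$pad[1] + 1):(cache$pad[1] + cache$hw[1]),
        (cache$pad[2] + 1):(cache$pad[2] + cache$hw[2])] <- gout
  gi_full <- Re(stats::fft(Conj(cache$FK) * stats::fft(gfull),
                           inverse = TRUE)) / prod(cache$L)
  gi_full[(cache$pad[1] + 1):(cache$pad[1] + cache$hw[1]),
          (cache$pad[2] + 1):(cache$pad[2] + cache$hw[2])]
}

#' Render one depth slice onto the sensor
#'
#' Linear convolution of the scene slice with the depth's PSF, computed on
#' the zero-padded patch and center-cropped, so borders carry no circular
#' artifacts. Flux is preserved for interior content because PSFs are
#' unit-sum.
#'
#' @param image scene patch, values in `[0, 1]`.
#' @param psf unit-sum non-negative PSF.
#' @param out_size side length of the centered crop returned (default 256,
#'   the training patch size); must not exceed the patch size.
#' @return `out_size` x `out_size` matrix.
#' @export
render_slice <- function(image, psf, out_size = 256L) {
  out_size <- rep(as.integer(out_size), length.out = 2)
  if (any(dim(image) < out_size)) {
    stop(sprintf("scene patch (%dx%d) is smaller than the crop target (%dx%d)",
                 nrow(image), ncol(image), out_size[1], out_size[2]))
  }
  crop_center(fft_conv_same(image, psf)$out, out_size)
}

#' Integrate rendered slices into a noisy sensor image
#'
#' Averages the depth slices (keeping intensities in `[0, 1]` without a
#' radiometric model), adds i.i.d. zero-mean Gaussian read noise of
#' standard deviation `sigma`, and clips to the sensor range.
#'
#' @param slices list of rendered slice matrices of equal shape.
#' @param sigma noise standard deviation on the `[0, 1]` intensity scale.
#' @param seed integer seed making the noise reproducible.
#' @return an object of class `sensor_image`: `image` (clipped matrix) and
#'   `noise_sigma`.
#' @export
render_sensor <- function(slices, sigma = 0.01, seed = 1L) {
  if (is.matrix(slices)) slices <- list(slices)
  if (length(slices) == 0) stop("no slices to integrate")
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) all(dim(s) == d), logical(1)))) {
    stop("all slices must share the same shape")
  }
  acc <- Reduce(`+`, slices) / length(slices)
  if (sigma > 0) {
    acc <- acc + with_local_seed(seed, {
      matrix(stats::rnorm(length(acc), 0, sigma), d[1], d[2])
    })
  }
  structure(list(image = clip01(acc), noise_sigma = sigma),
            class = "sensor_image")
}

#' Read a grayscale image file into a [0, 1] matrix
#'
#' @param path PNG (8-bit) or TIFF (float) file; RGB input is averaged to
#'   grayscale.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                              drop = FALSE], c(1, 2), mean)
  clip01(img)
}

#' Write a [0, 1] matrix as PNG or 32-bit float TIFF
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  image <- clip01(image)
  switch(ext,
         png = png::writePNG(image, path),
         tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 32L),
         stop("unsupported image format: ", ext))
  invisible(path)
}
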