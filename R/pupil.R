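# Pupil assembly and PSF/MTF computation.
#
# Grid convention: the pupil is sampled on an N x N grid with the optical
# axis at index floor(N/2) + 1 (1-based), i.e. the sample that fftshift
# maps to/from the DFT origin. All phase maps share this grid.

#' Swap quadrants so the DFT origin moves to the grid center
#' @param x a matrix.
#' @param inverse undo the shift (relevant for odd sizes).
#' @return the shifted matrix.
#' @export
fftshift2 <- function(x, inverse = FALSE) {
  d <- dim(x)
  s <- if (inverse) -floor(d / 2) else floor(d / 2)
  idx1 <- ((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1
  idx2 <- ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1
  x[idx1, idx2, drop = FALSE]
}

#' Pupil-plane coordinate axis
#' @param system an [optical_system()].
#' @return vector of physical coordinates (m) for one grid axis, zero at
#'   index floor(N/2) + 1.
#' @export
pupil_axis <- function(system) {
  n <- system$grid_size
  (seq_len(n) - (floor(n / 2) + 1)) * system$sample_pitch
}

#' Circular aperture indicator on the pupil grid
#' @param system an [optical_system()].
#' @return binary matrix: 1 inside the aperture disc, 0 outside.
#' @export
aperture_amplitude <- function(system) {
  x <- pupil_axis(system)
  r2 <- outer(x^2, x^2, "+")
  (r2 <= system$effective_radius^2 * (1 + 1e-12)) * 1
}

#' Quadratic defocus phase on the pupil grid
#'
#' phi_DF(x1, y1) = psi * (x1^2 + y1^2) / a^2: zero on the optical axis,
#' exactly `psi` radians at the aperture edge.
#'
#' @param system an [optical_system()].
#' @param psi dimensionless defocus coefficient (see
#'   [defocus_coefficient()]).
#' @return phase matrix in radians on the pupil grid.
#' @export
defocus_phase_map <- function(system, psi) {
  x <- pupil_axis(system)
  r2 <- outer(x^2, x^2, "+")
  psi * r2 / system$effective_radius^2
}

#' Assemble the generalized pupil function
#'
#' The amplitude is the circular aperture indicator (the mask is assumed
#' lossless unless `amplitude` says otherwise); the phase is the sum of the
#' defocus term and the mask modulation.
#'
#' @param system an [optical_system()].
#' @param mask_phase mask phase map in radians (matrix on the pupil grid),
#'   or a scalar 0.
#' @param defocus_phase defocus phase map in radians, or a scalar 0.
#' @param amplitude optional amplitude map in `[0, 1]` (e.g. metalens
#'   transmission); multiplied into the aperture indicator.
#' @return an object of class `pupil_field` with fields `amplitude` and
#'   `phase`.
#' @export
assemble_pupil <- function(system, mask_phase = 0, defocus_phase = 0,
                           amplitude = NULL) {
  n <- system$grid_size
  check_grid <- function(m, what) {
    if (is.matrix(m) && !all(dim(m) == c(n, n))) {
      stop(sprintf("%s has dimensions %dx%d but the pupil grid is %dx%d",
                   what, nrow(m), ncol(m), n, n))
    }
  }
  check_grid(mask_phase, "mask_phase")
  check_grid(defocus_phase, "defocus_phase")
  amp <- aperture_amplitude(system)
  if (!is.null(amplitude)) {
    check_grid(amplitude, "amplitude")
    if (any(amplitude < 0) || any(amplitude > 1 + 1e-9)) {
      stop("amplitude values must lie in [0, 1]")
    }
    amp <- amp * amplitude
  }
  phase <- matrix(0, n, n) + mask_phase + defocus_phase
  structure(list(amplitude = amp, phase = phase), class = "pupil_field")
}

#' Incoherent PSF from a pupil function
#'
#' The PSF is the squared magnitude of the discrete Fourier transform of
#' the (zero-padded) complex pupil, centered on the grid and normalized to
#' unit sum so that image formation preserves flux.
#'
#' @param pupil a `pupil_field` from [assemble_pupil()].
#' @param pad_factor integer >= 1; the pupil is zero-padded to
#'   `pad_factor * N` per side before transforming to avoid wrap-around.
#' @param psf_size optional side length of the center crop returned
#'   (defaults to the padded size); an odd value keeps the peak centered.
#' @return a `psf_size` x `psf_size` non-negative matrix summing to 1.
#' @export
psf_from_pupil <- function(pupil, pad_factor = 2L, psf_size = NULL) {
  stopifnot(inherits(pupil, "pupil_field"), pad_factor >= 1)
  if (all(pupil$amplitude == 0)) stop("pupil carries no energy (amplitude all zero)")
  n <- nrow(pupil$amplitude)
  np <- as.integer(round(pad_factor * n))
  p <- matrix(0 + 0i, np, np)
  p[1:n, 1:n] <- pupil$amplitude * exp(1i * pupil$phase)
  intens <- Mod(stats::fft(p))^2
  psf <- fftshift2(intens)
  if (!is.null(psf_size)) {
    psf <- crop_center(psf, psf_size)
    if (sum(psf) <= 0) stop("PSF crop retained no energy; increase psf_size")
  }
  psf / sum(psf)
}

#' Center crop of a matrix
#' @param x matrix.
#' @param size target side length (scalar or length-2).
#' @return the centered `size` crop, aligned on the fftshift center
#'   floor(N/2) + 1.
#' @export
crop_center <- function(x, size) {
  size <- rep(as.integer(size), length.out = 2)
  d <- dim(x)
  if (any(size > d)) stop("crop size exceeds input size")
  c0 <- floor(d / 2) + 1          # center index
  half <- floor(size / 2)
  i1 <- c0[1] - half[1]
  j1 <- c0[2] - half[2]
  x[i1:(i1 + size[1] - 1), j1:(j1 + size[2] - 1), drop = FALSE]
}

#' MTF of a PSF
#'
#' Magnitude of the Fourier transform of the PSF, normalized to 1 at zero
#' frequency, with a radially averaged profile for bandwidth analysis.
#'
#' @param psf a non-negative PSF matrix with positive sum.
#' @return an object of class `mtf_curve`: `magnitude` (2-D, centered),
#'   `radial` (1-D profile over `frequencies`), `frequencies` in cycles per
#'   sample.
#' @export
mtf_from_psf <- function(psf) {
  s <- sum(psf)
  if (s <= 0) stop("PSF must have positive total energy")
  mag <- Mod(stats::fft(psf / s))      # DC entry is exactly 1
  mag2d <- fftshift2(mag)
  rad <- radial_average(mag2d)
  structure(list(magnitude = mag2d,
                 radial = rad,
                 frequencies = (seq_along(rad) - 1) / nrow(psf)),
            class = "mtf_curve")
}

#' Radial average about the centered origin
#'
#' Averages a centered 2-D map over annuli of integer radius (nearest-bin
#' assignment), producing ceil(N/2) bins from DC outward.
#'
#' @param x centered matrix (origin at floor(N/2) + 1).
#' @return vector of bin means, bin k holding radius k - 1.
#' @export
radial_average <- function(x) {
  d <- dim(x)
  c0 <- floor(d / 2) + 1
  r <- sqrt(outer((seq_len(d[1]) - c0[1])^2, (seq_len(d[2]) - c0[2])^2, "+"))
  bin <- round(r)
  nb <- ceiling(min(d) / 2)
  keep <- bin < nb
  as.numeric(tapply(x[keep], bin[keep], mean))
}

#' Depth-indexed PSF stack
#'
#' Computes the incoherent PSF at each requested depth for a given mask
#' phase, sharing the pupil grid and normalization conventions.
#'
#' @param system an [optical_system()].
#' @param depths vector of object depths in meters.
#' @param mask_phase mask phase map (radians) or 0.
#' @param amplitude optional pupil amplitude map.
#' @param pad_factor zero-padding factor for the transform.
#' @param psf_size side of the returned center-cropped PSFs.
#' @return an object of class `psf_stack`: `depths` and list `psfs`.
#' @export
psf_stack <- function(system, depths, mask_phase = 0, amplitude = NULL,
                      pad_factor = 2L, psf_size = NULL) {
  psfs <- lapply(depths, function(z) {
    psi <- defocus_coefficient(z, system$z0, system$effective_radius,
                               system$wavelength)
    pupil <- assemble_pupil(system, mask_phase, defocus_phase_map(system, psi),
                            amplitude = amplitude)
    psf_from_pupil(pupil, pad_factor = pad_factor, psf_size = psf_size)
  })
  structure(list(depths = depths, psfs = psfs), class = "psf_stack")
}

#' Export a PSF stack as multi-page 32-bit float TIFF and radial MTF CSV
#'
#' @param stack a [psf_stack()].
#' @param tiff_path path for the multi-page TIFF (one page per depth).
#' @param csv_path optional path for a CSV of radially averaged MTFs
#'   (columns: frequency, one column per depth).
#' @return invisibly, the list of written paths.
#' @export
export_psf_stack <- function(stack, tiff_path, csv_path = NULL) {
  stopifnot(inherits(stack, "psf_stack"))
  pages <- lapply(stack$psfs, function(p) p / max(p))
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  written <- tiff_path
  if (!is.null(csv_path)) {
    mtfs <- lapply(stack$psfs, function(p) mtf_from_psf(p)$radial)
    freq <- mtf_from_psf(stack$psfs[[1]])$frequencies
    df <- data.frame(frequency = freq)
    for (i in seq_along(mtfs)) {
      df[[sprintf("mtf_z%g_um", stack$depths[i] * 1e6)]] <- mtfs[[i]]
    }
    utils::write.csv(df, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}
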