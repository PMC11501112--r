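#' Optical system description for the 4f EDOF microscope
#'
#' Bundles the fixed parameters of the 4f imaging path: design wavelength,
#' tube-lens focal length, in-focus object depth (taken equal to the
#' objective focal length), pupil aperture diameter and the pupil-plane
#' sampling grid on which phase masks are defined.
#'
#' Exactly one of `grid_size` or `sample_pitch` may be omitted: the missing
#' one is derived so that the grid spans the full aperture, with the grid
#' size rounded up to the next even integer (one sample per mask cell).
#'
#' @param wavelength design wavelength in meters (default 550 nm, green).
#' @param tube_focal_length tube-lens focal length f1 in meters.
#' @param z0 in-focus object depth in meters (objective focal length).
#' @param pupil_diameter aperture diameter D in meters.
#' @param grid_size number of samples per pupil side (>= 16).
#' @param sample_pitch pupil-plane sample pitch in meters.
#' @param na numerical aperture of the objective (optional, informational).
#' @return an object of class `optical_system`.
#' @examples
#' sys <- optical_system(z0 = 4e-3, pupil_diameter = 1.07e-3, grid_size = 64)
#' sys$effective_radius  # D / 2
#' @export
optical_system <- function(wavelength = 550e-9,
                           tube_focal_length = 0.2,
                           z0,
                           pupil_diameter,
                           grid_size = NULL,
                           sample_pitch = NULL,
                           na = NULL) {
  stopifnot(wavelength > 0, tube_focal_length > 0, z0 > 0, pupil_diameter > 0)
  if (is.null(grid_size) && is.null(sample_pitch)) {
    stop("supply at least one of `grid_size` or `sample_pitch`")
  }
  if (is.null(grid_size)) {
    grid_size <- ceiling(pupil_diameter / sample_pitch)
    if (grid_size %% 2 == 1) grid_size <- grid_size + 1
  }
  grid_size <- as.integer(grid_size)
  if (is.null(sample_pitch)) sample_pitch <- pupil_diameter / grid_size
  if (grid_size < 16) stop("grid_size must be at least 16")
  if (sample_pitch * grid_size < pupil_diameter * (1 - 1e-12)) {
    stop("pupil grid (sample_pitch * grid_size) does not span the aperture")
  }
  structure(list(
    wavelength = wavelength,
    tube_focal_length = tube_focal_length,
    z0 = z0,
    pupil_diameter = pupil_diameter,
    effective_radius = pupil_diameter / 2,
    grid_size = grid_size,
    sample_pitch = sample_pitch,
    na = na
  ), class = "optical_system")
}

#' @export
print.optical_system <- function(x, ...) {
  cat("<optical_system>\n")
  cat(sprintf("  wavelength     : %.1f nm\n", x$wavelength * 1e9))
  cat(sprintf("  tube focal f1  : %.1f mm\n", x$tube_focal_length * 1e3))
  cat(sprintf("  in-focus z0    : %.3f mm\n", x$z0 * 1e3))
  cat(sprintf("  pupil diameter : %.3f mm (a = %.3f mm)\n",
              x$pupil_diameter * 1e3, x$effective_radius * 1e3))
  cat(sprintf("  grid           : %d x %d, pitch %.3f um\n",
              x$grid_size, x$grid_size, x$sample_pitch * 1e6))
  if (!is.null(x$na)) cat(sprintf("  NA             : %.2f\n", x$na))
  invisible(x)
}

#' Wavenumber of the design wavelength
#' @param wavelength wavelength in meters.
#' @return k = 2 pi / lambda in 1/m.
#' @export
wavenumber <- function(wavelength) 2 * pi / wavelength

#' Depth range specification
#'
#' @param z_min,z_max near and far bounds of the target depth range (m).
#' @param z0 in-focus depth (m), strictly inside the range.
#' @param n_depths number of depth positions M sampled within the range.
#' @return an object of class `depth_spec`.
#' @export
depth_spec <- function(z_min, z_max, z0, n_depths = 5L) {
  stopifnot(z_min > 0, z_max > 0, z0 > 0, n_depths >= 1)
  if (!(z_min < z0 && z0 < z_max)) {
    stop("depth range must satisfy z_min < z0 < z_max")
  }
  structure(list(z_min = z_min, z_max = z_max, z0 = z0,
                 n_depths = as.integer(n_depths)),
            class = "depth_spec")
}

#' Defocus coefficient of a depth plane
#'
#' The dimensionless defocus coefficient
#' psi_z = (pi / lambda) * (1/z - 1/z0) * a^2, where `a` is the effective
#' pupil radius (half the aperture diameter). Its sign indicates whether the
#' plane lies nearer (positive) or farther (negative) than the in-focus
#' depth; its magnitude measures blur severity at the pupil edge in radians.
#'
#' @param z object depth in meters.
#' @param z0 in-focus depth in meters.
#' @param a effective pupil radius in meters.
#' @param wavelength wavelength in meters.
#' @return the dimensionless defocus coefficient (vectorized over `z`).
#' @examples
#' # Mitutoyo 50X style geometry: a = 0.535 mm, z0 = 4 mm
#' defocus_coefficient(3e-3, 4e-3, 0.535e-3, 550e-9)  # ~136.2
#' @export
defocus_coefficient <- function(z, z0, a, wavelength = 550e-9) {
  if (any(z <= 0) || z0 <= 0) stop("depths must be positive")
  stopifnot(a > 0, wavelength > 0)
  (pi / wavelength) * (1 / z - 1 / z0) * a^2
}

#' Maximum absolute defocus over a depth range
#'
#' Because 1/z is convex, |psi| over an interval peaks at one of the two
#' endpoints (the near side for a symmetric range), so only the endpoints
#' are evaluated.
#'
#' @param spec a [depth_spec()].
#' @param a effective pupil radius in meters.
#' @param wavelength wavelength in meters.
#' @return max(|psi(z_min)|, |psi(z_max)|).
#' @export
max_defocus <- function(spec, a, wavelength = 550e-9) {
  stopifnot(inherits(spec, "depth_spec"))
  max(abs(defocus_coefficient(c(spec$z_min, spec$z_max), spec$z0, a,
                              wavelength)))
}

#' Anti-aliasing bound on the phase-mask sample pitch
#'
#' The defocused pupil phase is quadratic with peak slope proportional to
#' psi_max; sampling it without aliasing requires
#' delta_s <= a * pi / (8 * psi_max).
#'
#' @param a effective pupil radius in meters.
#' @param psi_max maximum absolute defocus coefficient (> 0).
#' @return the largest admissible sample pitch in meters.
#' @export
max_sampling_pitch <- function(a, psi_max) {
  stopifnot(a > 0)
  if (psi_max <= 0) {
    stop("psi_max must be positive: with no defocus the pitch is unbounded")
  }
  a * pi / (8 * psi_max)
}

#' Minimum pupil radius supporting a spatial-frequency pair
#'
#' A frequency (kx, ky) reaches the pupil plane at radial position
#' (f1 / k) * sqrt(kx^2 + ky^2); the pupil must be at least that large to
#' transmit it.
#'
#' @param f1 tube-lens focal length in meters.
#' @param k wavenumber 2 pi / lambda in 1/m.
#' @param kx,ky angular spatial frequencies in 1/m.
#' @return the minimum pupil radius in meters.
#' @export
min_pupil_radius <- function(f1, k, kx, ky) {
  stopifnot(f1 > 0, k > 0)
  (f1 / k) * sqrt(kx^2 + ky^2)
}

#' Standard objective presets
#'
#' Catalog parameters for the objectives used throughout: aperture diameter,
#' numerical aperture, objective focal length (taken as the in-focus depth)
#' and matching tube length. RMS objectives assume a 180 mm tube; the
#' Mitutoyo long-working-distance objective assumes a 200 mm tube.
#'
#' @param name one of `"rms4x"`, `"rms20x"`, `"mitutoyo50x"` (case
#'   insensitive), or `NULL` to list all presets.
#' @return a list of preset parameters, or a data.frame of all presets.
#' @export
objective_preset <- function(name = NULL) {
  presets <- list(
    rms4x = list(name = "RMS4X-PF", na = 0.13, pupil_diameter = 3.72e-3,
                 z0 = 45e-3, tube_focal_length = 180e-3),
    rms20x = list(name = "RMS20X-PF", na = 0.40, pupil_diameter = 2.87e-3,
                  z0 = 9e-3, tube_focal_length = 180e-3),
    mitutoyo50x = list(name = "Mitutoyo50X", na = 0.42,
                       pupil_diameter = 1.07e-3, z0 = 4e-3,
                       tube_focal_length = 200e-3)
  )
  if (is.null(name)) {
    return(do.call(rbind, lapply(names(presets), function(n) {
      p <- presets[[n]]
      data.frame(preset = n, objective = p$name, na = p$na,
                 pupil_diameter_mm = p$pupil_diameter * 1e3,
                 z0_mm = p$z0 * 1e3,
                 tube_focal_length_mm = p$tube_focal_length * 1e3)
    })))
  }
  key <- tolower(gsub("[^a-z0-9]", "", tolower(name)))
  if (!key %in% names(presets)) {
    stop(sprintf("unknown objective preset '%s'; known: %s", name,
                 paste(names(presets), collapse = ", ")))
  }
  presets[[key]]
}

#' Design calculator for an objective and target depth range
#'
#' Computes the system-parameter row for a given objective and a symmetric
#' depth range around focus: effective radius, maximum defocus coefficient,
#' and the anti-aliasing bound on the mask sample pitch.
#'
#' @param objective a preset name (see [objective_preset()]) or a list with
#'   fields `pupil_diameter`, `z0` and optionally `na`, `name`,
#'   `tube_focal_length`.
#' @param dof_half_range half-width of the target depth range in meters
#'   (e.g. `100e-6` for a +/- 100 um target).
#' @param wavelength design wavelength in meters.
#' @return a one-row data.frame with columns `objective`, `na`,
#'   `dof_half_range_um`, `pupil_diameter_mm`, `effective_radius_mm`,
#'   `psi_max`, `max_pitch_um`.
#' @examples
#' design_row("mitutoyo50x", 1e-3)   # psi_max ~ 136.2, pitch ~ 1.54 um
#' @export
design_row <- function(objective, dof_half_range, wavelength = 550e-9) {
  if (is.character(objective)) objective <- objective_preset(objective)
  stopifnot(dof_half_range > 0, dof_half_range < objective$z0)
  a <- objective$pupil_diameter / 2
  spec <- depth_spec(objective$z0 - dof_half_range,
                     objective$z0 + dof_half_range, objective$z0)
  psi_max <- max_defocus(spec, a, wavelength)
  data.frame(
    objective = if (!is.null(objective$name)) objective$name else "custom",
    na = if (!is.null(objective$na)) objective$na else NA_real_,
    dof_half_range_um = dof_half_range * 1e6,
    pupil_diameter_mm = objective$pupil_diameter * 1e3,
    effective_radius_mm = a * 1e3,
    psi_max = psi_max,
    max_pitch_um = max_sampling_pitch(a, psi_max) * 1e6
  )
}
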