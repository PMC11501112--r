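# Phase-mask parameterizations for the pupil plane.
#
# Three fabricable mask families share one contract: `mask_phase(mask,
# system)` returns a phase map (radians) on the pupil grid, directly
# consumable by assemble_pupil(). A fourth, free-phase parameterization
# carries the learnable phase during end-to-end training and is exported
# to a height or radius map afterwards.

#' Diffractive optical element (height-map) mask
#'
#' Surface-relief phase plate: local height h sets local phase delay
#' phi = k (n - 1) h at the design wavelength.
#'
#' @param height_map matrix of unit-cell heights in meters (all >= 0).
#' @param refractive_index material index (> 1); 1.5 for the standard
#'   polymer at 550 nm.
#' @return an object of class `doe_mask`.
#' @export
doe_mask <- function(height_map, refractive_index = 1.5) {
  stopifnot(is.matrix(height_map), refractive_index > 1)
  if (any(height_map < 0)) stop("DOE heights must be non-negative")
  structure(list(height_map = height_map,
                 refractive_index = refractive_index),
            class = c("doe_mask", "phase_mask_base"))
}

#' Phase imparted by a DOE height map
#' @param mask a [doe_mask()].
#' @param k wavenumber 2 pi / lambda in 1/m.
#' @return phase matrix in radians; linear (hence differentiable) in the
#'   height map with constant slope k (n - 1).
#' @export
doe_phase <- function(mask, k) {
  stopifnot(inherits(mask, "doe_mask"), k > 0)
  k * (mask$refractive_index - 1) * mask$height_map
}

#' Phase-radius lookup table for metalens nanopillars
#'
#' Tabulated meta-atom response: phase (and transmission) imparted by a
#' nanopillar as a function of its radius, as obtained from full-wave
#' simulation of the unit cell. Radii must be strictly increasing and the
#' phase must span at least 2 pi so any target phase is realizable.
#'
#' @param radii strictly increasing nanopillar radii in meters.
#' @param phases imparted phase in radians (monotone non-decreasing).
#' @param transmissions amplitude transmission in `[0, 1]` (default 1).
#' @return an object of class `phase_radius_lut`.
#' @export
phase_radius_lut <- function(radii, phases, transmissions = NULL) {
  if (is.null(transmissions)) transmissions <- rep(1, length(radii))
  stopifnot(length(radii) == length(phases),
            length(radii) == length(transmissions))
  if (any(diff(radii) <= 0)) stop("LUT radii must be strictly increasing")
  if (any(diff(phases) < 0)) stop("LUT phases must be monotone non-decreasing")
  if (diff(range(phases)) < 2 * pi - 1e-9) {
    stop("LUT phase coverage must span at least 2 pi")
  }
  if (any(transmissions < 0) || any(transmissions > 1)) {
    stop("LUT transmissions must lie in [0, 1]")
  }
  structure(list(radii = radii, phases = phases,
                 transmissions = transmissions),
            class = "phase_radius_lut")
}

#' Synthetic default lookup table
#'
#' Placeholder meta-atom response used when no simulated table is
#' available: phase linear in radius from `r_min` to the largest
#' fabricable radius (pillar diameter 50 nm below the cell pitch),
#' covering exactly 0 to 2 pi with unit transmission. Real simulated
#' tables can be loaded with [read_lut_csv()].
#'
#' @param sample_pitch metalens unit-cell pitch in meters.
#' @param r_min smallest fabricable pillar radius in meters (default 40 nm).
#' @param n_points number of tabulated points.
#' @return a [phase_radius_lut()].
#' @export
default_lut <- function(sample_pitch, r_min = 40e-9, n_points = 64L) {
  r_max <- (sample_pitch - 50e-9) / 2
  if (r_max <= r_min) stop("sample_pitch too small for the default LUT")
  radii <- seq(r_min, r_max, length.out = n_points)
  phase_radius_lut(radii, seq(0, 2 * pi, length.out = n_points))
}

#' Read / write a phase-radius LUT as CSV
#'
#' CSV columns: `radius_nm`, `phase_rad`, `transmission`.
#' @param path CSV file path.
#' @return for read: a [phase_radius_lut()]; for write: the path,
#'   invisibly.
#' @export
read_lut_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("radius_nm", "phase_rad", "transmission")
  if (!all(need %in% names(df))) {
    stop("LUT CSV must have columns: ", paste(need, collapse = ", "))
  }
  phase_radius_lut(df$radius_nm * 1e-9, df$phase_rad, df$transmission)
}

#' @rdname read_lut_csv
#' @param lut a [phase_radius_lut()].
#' @export
write_lut_csv <- function(lut, path) {
  utils::write.csv(data.frame(radius_nm = lut$radii * 1e9,
                              phase_rad = lut$phases,
                              transmission = lut$transmissions),
                   path, row.names = FALSE)
  invisible(path)
}

#' Metalens mask (nanopillar radius map)
#'
#' @param radius_map matrix of nanopillar radii in meters, one per mask
#'   cell; all within the LUT range and with diameter at most
#'   `cell_pitch - 50 nm`.
#' @param lut a [phase_radius_lut()].
#' @param cell_pitch the metalens unit-cell pitch in meters.
#' @return an object of class `metalens_mask`.
#' @export
metalens_mask <- function(radius_map, lut, cell_pitch) {
  stopifnot(is.matrix(radius_map), inherits(lut, "phase_radius_lut"),
            cell_pitch > 0)
  max_diameter <- cell_pitch - 50e-9
  bad <- radius_map < min(lut$radii) - 1e-15 |
    radius_map > max(lut$radii) + 1e-15
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("radius at cell (%d, %d) outside the LUT range", ij[1], ij[2]))
  }
  if (any(2 * radius_map > max_diameter + 1e-15)) {
    stop("nanopillar diameters must stay 50 nm below the cell pitch")
  }
  structure(list(radius_map = radius_map, lut = lut,
                 cell_pitch = cell_pitch, max_diameter = max_diameter),
            class = c("metalens_mask", "phase_mask_base"))
}

#' Interpolate mask phase from a radius map
#'
#' Monotone linear interpolation of the LUT; exact at the knots and
#' differentiable in the radii (piecewise-constant slope).
#'
#' @param radius_map matrix of radii in meters.
#' @param lut a [phase_radius_lut()].
#' @return phase matrix in radians.
#' @export
radius_to_phase <- function(radius_map, lut) {
  bad <- radius_map < min(lut$radii) - 1e-15 |
    radius_map > max(lut$radii) + 1e-15
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("radius at cell (%d, %d) outside the LUT range", ij[1], ij[2]))
  }
  ph <- stats::approx(lut$radii, lut$phases, xout = as.numeric(radius_map),
                      rule = 2)$y
  matrix(ph, nrow(radius_map), ncol(radius_map))
}

#' Invert a phase map to a nanopillar radius map
#'
#' Wraps each phase into `[0, 2 pi)` (values at exactly 2 pi map to 0),
#' then inverts the LUT by monotone interpolation over its principal
#' 0-to-2 pi branch.
#'
#' @param phase_map matrix of phases in radians (any real values).
#' @param lut a [phase_radius_lut()].
#' @return matrix of radii in meters, all within the LUT range.
#' @export
phase_to_radius <- function(phase_map, lut) {
  if (any(diff(lut$phases) < 0)) stop("LUT phases must be monotone")
  wrapped <- phase_map %% (2 * pi)
  # restrict to the branch covering [0, 2pi]
  p0 <- lut$phases - lut$phases[1]
  hi <- which(p0 >= 2 * pi - 1e-9)[1]
  r <- stats::approx(p0[1:hi], lut$radii[1:hi], xout = as.numeric(wrapped),
                     rule = 2)$y
  matrix(r, nrow(phase_map), ncol(phase_map))
}

#' Cubic phase mask
#'
#' Classical wavefront-coding mask
#' phi(x, y) = mod(alpha / N^3 * (x^3 + y^3), 2 pi) on integer grid
#' coordinates centered at the optical axis; `alpha` sets the number of
#' 2 pi transitions across the aperture.
#'
#' @param alpha cubic strength in radians (>= 0); see
#'   [cubic_alpha_for_dof()] for the presets matched to depth targets.
#' @param grid_size samples per side N (>= 2).
#' @return an object of class `cubic_mask`.
#' @export
cubic_mask <- function(alpha, grid_size) {
  stopifnot(alpha >= 0, grid_size >= 2)
  structure(list(alpha = alpha, grid_size = as.integer(grid_size)),
            class = c("cubic_mask", "phase_mask_base"))
}

#' Cubic strength preset for a depth-of-field target
#'
#' Strengths matched (by MTF inspection across depth) to the three target
#' ranges: 6 pi for a 200 um full range, 200 pi for 2 mm, 360 pi for 3 mm.
#'
#' @param dof_range full depth-of-field range in meters.
#' @return alpha in radians.
#' @export
cubic_alpha_for_dof <- function(dof_range) {
  presets <- c(`200` = 6 * pi, `2000` = 200 * pi, `3000` = 360 * pi)
  um <- dof_range * 1e6
  key <- names(presets)[which.min(abs(as.numeric(names(presets)) - um))]
  presets[[key]]
}

#' Evaluate the cubic mask phase
#' @param mask a [cubic_mask()].
#' @return phase matrix with values in `[0, 2 pi)`; the raw (pre-wrap)
#'   cubic is odd in the grid coordinates and zero at the origin.
#' @export
cubic_phase <- function(mask) {
  n <- mask$grid_size
  x <- seq_len(n) - (floor(n / 2) + 1)
  raw <- mask$alpha / n^3 * outer(x^3, rep(1, n)) +
    mask$alpha / n^3 * outer(rep(1, n), x^3)
  raw %% (2 * pi)
}

#' Free (directly learnable) pupil phase
#'
#' Carries the phase map itself as the trainable parameter during
#' end-to-end optimization; conversion to a fabricable representation
#' (height map or radius map) happens at export time.
#'
#' @param phase matrix of phases in radians.
#' @return an object of class `free_phase_mask`.
#' @export
free_phase_mask <- function(phase) {
  stopifnot(is.matrix(phase))
  structure(list(phase = phase),
            class = c("free_phase_mask", "phase_mask_base"))
}

#' Mask phase on the pupil grid
#'
#' S3 generic dispatching on the mask family; every mask yields a phase
#' map on the shared pupil grid, consumable by [assemble_pupil()].
#'
#' @param mask a mask object.
#' @param system the [optical_system()] providing grid and wavelength.
#' @return phase matrix in radians.
#' @export
mask_phase <- function(mask, system) UseMethod("mask_phase")

#' @export
mask_phase.doe_mask <- function(mask, system) {
  check_mask_grid(mask$height_map, system)
  doe_phase(mask, wavenumber(system$wavelength))
}

#' @export
mask_phase.metalens_mask <- function(mask, system) {
  check_mask_grid(mask$radius_map, system)
  radius_to_phase(mask$radius_map, mask$lut)
}

#' @export
mask_phase.cubic_mask <- function(mask, system) {
  if (mask$grid_size != system$grid_size) {
    stop("cubic mask grid does not match the pupil grid")
  }
  cubic_phase(mask)
}

#' @export
mask_phase.free_phase_mask <- function(mask, system) {
  check_mask_grid(mask$phase, system)
  mask$phase
}

check_mask_grid <- function(m, system) {
  if (!all(dim(m) == c(system$grid_size, system$grid_size))) {
    stop("mask grid does not match the pupil grid")
  }
  invisible(TRUE)
}

#' Pupil amplitude contributed by a mask
#'
#' Metalens cells transmit according to the LUT transmission at their
#' radius; DOE and cubic masks are modeled as lossless (unit amplitude).
#'
#' @inheritParams mask_phase
#' @return amplitude matrix in `[0, 1]`, or NULL for unit amplitude.
#' @export
mask_amplitude <- function(mask, system) UseMethod("mask_amplitude")

#' @export
mask_amplitude.default <- function(mask, system) NULL

#' @export
mask_amplitude.metalens_mask <- function(mask, system) {
  if (all(mask$lut$transmissions == 1)) return(NULL)
  tr <- stats::approx(mask$lut$radii, mask$lut$transmissions,
                      xout = as.numeric(mask$radius_map), rule = 2)$y
  matrix(tr, nrow(mask$radius_map), ncol(mask$radius_map))
}

#' Fabrication-error perturbation of a mask
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma`
#' (meters) to every fabricated quantity -- DOE unit-cell heights or
#' metalens nanopillar radii -- then clips to the physical bounds
#' (non-negative heights; radii within the LUT range and pitch limit).
#' Reproducible for a fixed seed; `sigma = 0` returns the mask unchanged.
#'
#' @param mask a [doe_mask()] or [metalens_mask()].
#' @param sigma noise standard deviation in meters (>= 0).
#' @param seed integer seed.
#' @return a perturbed mask of the same class.
#' @export
perturb_mask <- function(mask, sigma, seed) UseMethod("perturb_mask")

#' @export
perturb_mask.doe_mask <- function(mask, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mask)
  h <- mask$height_map + with_local_seed(seed, {
    matrix(stats::rnorm(length(mask$height_map), 0, sigma),
           nrow(mask$height_map))
  })
  mask$height_map <- pmax(h, 0)
  mask
}

#' @export
perturb_mask.metalens_mask <- function(mask, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mask)
  r <- mask$radius_map + with_local_seed(seed, {
    matrix(stats::rnorm(length(mask$radius_map), 0, sigma),
           nrow(mask$radius_map))
  })
  r <- pmin(pmax(r, min(mask$lut$radii)),
            min(max(mask$lut$radii), mask$max_diameter / 2))
  mask$radius_map <- r
  mask
}

#' Export a mask's fabricated map as 32-bit TIFF + CSV with sidecar metadata
#'
#' Writes the height map (DOE) or radius map (metalens) in meters as a
#' single-page 32-bit float TIFF (scaled by the value recorded in the
#' sidecar) and as CSV, plus a JSON sidecar with the pitch, wavelength and
#' an LUT content hash where applicable.
#'
#' @param mask a [doe_mask()] or [metalens_mask()].
#' @param path_prefix output path without extension.
#' @param system optional [optical_system()] for pitch/wavelength metadata.
#' @return invisibly, the written file paths.
#' @export
export_mask <- function(mask, path_prefix, system = NULL) {
  if (inherits(mask, "doe_mask")) {
    map <- mask$height_map; what <- "height_m"
  } else if (inherits(mask, "metalens_mask")) {
    map <- mask$radius_map; what <- "radius_m"
  } else stop("only DOE and metalens masks have a fabricated map")
  scale <- max(map, 1e-12)
  tiff::writeTIFF(map / scale, paste0(path_prefix, ".tiff"),
                  bits.per.sample = 32L)
  utils::write.csv(map, paste0(path_prefix, ".csv"), row.names = FALSE)
  meta <- list(quantity = what, tiff_scale_m = scale,
               sample_pitch_m = if (!is.null(system)) system$sample_pitch,
               wavelength_m = if (!is.null(system)) system$wavelength,
               lut_hash = if (inherits(mask, "metalens_mask"))
                 content_hash(mask$lut))
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(paste0(path_prefix, c(".tiff", ".csv", ".json")))
}

#' Convert a learned phase profile to a fabricable mask
#'
#' Wraps the phase into `[0, 2 pi)` and realizes it either as a DOE
#' height map (h = phi / (k (n - 1)), one 2 pi step of material) or as a
#' metalens nanopillar radius map through a phase-radius LUT.
#'
#' @param mask a [free_phase_mask()] (or any mask with a phase).
#' @param system the [optical_system()] (wavelength, grid).
#' @param refractive_index DOE material index.
#' @return a [doe_mask()].
#' @export
as_doe_mask <- function(mask, system, refractive_index = 1.5) {
  phase <- mask_phase(mask, system) %% (2 * pi)
  doe_mask(phase / (wavenumber(system$wavelength) * (refractive_index - 1)),
           refractive_index)
}

#' @rdname as_doe_mask
#' @param lut a [phase_radius_lut()]; defaults to the synthetic linear
#'   table for the system's sample pitch.
#' @return a [metalens_mask()].
#' @export
as_metalens_mask <- function(mask, system, lut = NULL) {
  if (is.null(lut)) lut <- default_lut(system$sample_pitch)
  phase <- mask_phase(mask, system)
  metalens_mask(phase_to_radius(phase, lut), lut, system$sample_pitch)
}
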