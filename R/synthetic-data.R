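# Synthetic grayscale textures standing in for the mixed training corpus
# (fluorescence micrographs, histopathology, natural images): Gaussian
# random fields band-limited at several octaves, anisotropic blobs and
# filament strokes give controllable multi-scale content so every stage
# of the pipeline is testable without downloads.

#' Texture generation specification
#'
#' @param kind one of `"blobs"`, `"filaments"`, `"tissue"`, `"mixed"`.
#' @param image_size image side in pixels (>= 256; default 1000).
#' @param feature_scale_range interval of feature scales in pixels.
#' @param contrast target intensity quantile interval after stretching.
#' @param seed integer seed.
#' @return a `texture_spec` list.
#' @export
texture_spec <- function(kind = c("mixed", "blobs", "filaments", "tissue"),
                         image_size = 1000L,
                         feature_scale_range = c(4, 64),
                         contrast = c(0, 1), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(image_size >= 256, all(feature_scale_range >= 1),
            feature_scale_range[1] <= feature_scale_range[2])
  structure(list(kind = kind, image_size = as.integer(image_size),
                 feature_scale_range = feature_scale_range,
                 contrast = contrast, seed = as.integer(seed)),
            class = "texture_spec")
}

# Band-limited Gaussian random field with correlation length `scale` px.
gaussian_field <- function(n, scale) {
  wn <- matrix(stats::rnorm(n * n), n)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  r2 <- outer(f^2, f^2, "+")
  filt <- exp(-r2 * (pi * scale)^2 / 2)
  g <- Re(stats::fft(stats::fft(wn) * filt, inverse = TRUE)) / n^2
  g / max(stats::sd(g), 1e-12)
}

stamp_blobs <- function(img, n_blobs, scale_range) {
  n <- nrow(img)
  for (b in seq_len(n_blobs)) {
    sx <- stats::runif(1, scale_range[1], scale_range[2]) / 2
    sy <- sx * stats::runif(1, 0.5, 2)           # anisotropy
    cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
    amp <- stats::runif(1, 0.3, 1) * sample(c(1, -1), 1, prob = c(0.8, 0.2))
    ext <- ceiling(3 * max(sx, sy))
    ix <- max(1, floor(cx - ext)):min(n, ceiling(cx + ext))
    iy <- max(1, floor(cy - ext)):min(n, ceiling(cy + ext))
    gx <- exp(-(ix - cx)^2 / (2 * sx^2))
    gy <- exp(-(iy - cy)^2 / (2 * sy^2))
    img[ix, iy] <- img[ix, iy] + amp * outer(gx, gy)
  }
  img
}

stamp_filaments <- function(img, n_paths, width) {
  n <- nrow(img)
  canvas <- matrix(0, n, n)
  for (p in seq_len(n_paths)) {
    len <- round(stats::runif(1, n / 4, n))
    pos <- stats::runif(2, 1, n)
    ang <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.4, 1)
    for (s in seq_len(len)) {
      ang <- ang + stats::rnorm(1, 0, 0.15)
      pos <- pos + c(cos(ang), sin(ang))
      ij <- ((round(pos) - 1) %% n) + 1       # wrap at borders
      canvas[ij[1], ij[2]] <- canvas[ij[1], ij[2]] + amp
    }
  }
  # soften strokes to the requested width with a Gaussian kernel
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  r2 <- outer(f^2, f^2, "+")
  filt <- exp(-r2 * (pi * width)^2 / 2)
  img + Re(stats::fft(stats::fft(canvas) * filt, inverse = TRUE)) / n^2
}

stretch01 <- function(x, lo_q = 0.01, hi_q = 0.99) {
  q <- stats::quantile(x, c(lo_q, hi_q), names = FALSE)
  if (q[2] - q[1] < 1e-12) return(matrix(0.5, nrow(x), ncol(x)))
  clip01((x - q[1]) / (q[2] - q[1]))
}

#' Generate one synthetic grayscale image
#'
#' Deterministic for a fixed spec (seed included); output values span at
#' least half the `[0, 1]` range, and the `"mixed"` kind carries energy in
#' three or more octave-spaced frequency bands.
#'
#' @param spec a [texture_spec()].
#' @return `image_size` x `image_size` matrix in `[0, 1]`.
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "texture_spec"))
  n <- spec$image_size
  sr <- spec$feature_scale_range
  with_local_seed(spec$seed, {
    img <- switch(spec$kind,
      blobs = {
        dens <- n^2 / (40 * mean(sr)^2)
        stamp_blobs(matrix(0, n, n), max(10, round(dens)), sr)
      },
      filaments = {
        base <- 0.15 * gaussian_field(n, max(sr))
        stamp_filaments(base, max(6, round(n / 80)), max(1.5, sr[1] / 2))
      },
      tissue = {
        cells <- gaussian_field(n, mean(sr) / 2)
        lobes <- gaussian_field(n, max(sr))
        1 / (1 + exp(-2 * cells)) + 0.6 * lobes +
          0.15 * gaussian_field(n, sr[1])
      },
      mixed = {
        # octave ladder of fields between the two scale bounds
        n_oct <- max(3, ceiling(log2(sr[2] / sr[1])) + 1)
        scales <- sr[1] * 2^(seq(0, log2(sr[2] / sr[1]),
                                 length.out = n_oct))
        acc <- matrix(0, n, n)
        for (i in seq_along(scales)) {
          acc <- acc + gaussian_field(n, scales[i]) / sqrt(i)
        }
        acc <- acc / stats::sd(acc)
        acc <- stamp_blobs(acc * 0.8, max(10, round(n^2 / (60 * mean(sr)^2))),
                           sr)
        stamp_filaments(acc, max(4, round(n / 150)), max(1.5, sr[1] / 2))
      })
    stretch01(img)
  })
}

#' Generate a train/validation/test dataset on disk
#'
#' Writes 8-bit PNGs plus a CSV manifest (filename, split, kind, seed).
#' Each split draws from a disjoint seed stream derived from the base
#' seed, so splits are independent and regeneration is exact.
#'
#' @param dir output directory (created if missing).
#' @param n_train,n_val,n_test split sizes; the full-scale corpus uses
#'   1500/150/150.
#' @param seed base seed.
#' @param image_size image side in pixels.
#' @param kinds kinds to cycle through within each split.
#' @return a `dataset_handle`: `dir`, `manifest` (data.frame).
#' @export
generate_split <- function(dir, n_train, n_val, n_test, seed = 1L,
                           image_size = 1000L,
                           kinds = c("mixed", "blobs", "tissue")) {
  stopifnot(n_train >= 0, n_val >= 0, n_test >= 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  counts <- c(train = n_train, val = n_val, test = n_test)
  for (split in names(counts)) {
    for (i in seq_len(counts[[split]])) {
      sd_i <- derive_seed(seed, split, i)
      kind <- kinds[((i - 1) %% length(kinds)) + 1]
      fn <- sprintf("%s_%04d.png", split, i)
      img <- generate_image(texture_spec(kind, image_size, seed = sd_i))
      png::writePNG(img, file.path(dir, fn))
      rows[[length(rows) + 1]] <- data.frame(filename = fn, split = split,
                                             kind = kind, seed = sd_i)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filename = character(), split = character(),
               kind = character(), seed = integer())
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  structure(list(dir = dir, manifest = manifest), class = "dataset_handle")
}

#' Load one split of a generated dataset into memory
#'
#' @param handle a `dataset_handle` from [generate_split()] or a dataset
#'   directory containing `manifest.csv`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return list of image matrices in `[0, 1]`.
#' @export
load_split <- function(handle, split = "train") {
  if (is.character(handle)) {
    handle <- structure(list(
      dir = handle,
      manifest = utils::read.csv(file.path(handle, "manifest.csv"))
    ), class = "dataset_handle")
  }
  rows <- handle$manifest[handle$manifest$split == split, ]
  lapply(rows$filename, function(fn) read_image(file.path(handle$dir, fn)))
}
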