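# Independent oracles used across the suite: an O(N^4) direct DFT, a
# nested-loop linear convolution, and the autocorrelation of an aperture
# disc. These deliberately share no code with the package's FFT paths.

# Direct (slow) 2-D DFT intensity of a complex field, origin at (1, 1).
brute_dft_intensity <- function(p) {
  n1 <- nrow(p); n2 <- ncol(p)
  out <- matrix(0, n1, n2)
  for (u in 0:(n1 - 1)) for (v in 0:(n2 - 1)) {
    s <- 0 + 0i
    for (x in 0:(n1 - 1)) for (y in 0:(n2 - 1)) {
      s <- s + p[x + 1, y + 1] * exp(-2i * pi * (u * x / n1 + v * y / n2))
    }
    out[u + 1, v + 1] <- Mod(s)^2
  }
  out
}

# Direct nested-loop linear convolution with a centered kernel, "same"
# output, zero boundary.
brute_conv_same <- function(img, k) {
  n1 <- nrow(img); n2 <- ncol(img)
  kc <- floor(dim(k) / 2) + 1
  out <- matrix(0, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    acc <- 0
    for (a in 1:nrow(k)) for (b in 1:ncol(k)) {
      ii <- i - (a - kc[1]); jj <- j - (b - kc[2])
      if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2) {
        acc <- acc + img[ii, jj] * k[a, b]
      }
    }
    out[i, j] <- acc
  }
  out
}

# Autocorrelation of a binary aperture, computed by direct shifting.
brute_autocorrelation <- function(a) {
  n <- nrow(a)
  out <- matrix(0, 2 * n - 1, 2 * n - 1)
  for (di in -(n - 1):(n - 1)) for (dj in -(n - 1):(n - 1)) {
    s <- 0
    for (i in 1:n) for (j in 1:n) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n) s <- s + a[i, j] * a[ii, jj]
    }
    out[di + n, dj + n] <- s
  }
  out
}

# Small reference system on the 50X long-working-distance geometry.
toy_system <- function(grid_size = 16L) {
  p <- objective_preset("mitutoyo50x")
  optical_system(z0 = p$z0, pupil_diameter = p$pupil_diameter,
                 tube_focal_length = p$tube_focal_length,
                 grid_size = grid_size, na = p$na)
}

# Deterministic multi-scale test images via the generator's own
# machinery, center-cropped below the generator's minimum size when a
# smaller fixture is enough.
toy_images <- function(n = 3, size = 256L, seed = 42L) {
  lapply(seq_len(n), function(i) {
    img <- generate_image(texture_spec("mixed", max(size, 256L),
                                       seed = derive_seed(seed, i)))
    crop_center(img, size)
  })
}
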