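# Deblurring U-Net (D-CNN) with a residual output head.
#
# Layer tally (the "23 convolution layers"): 5 encoder levels x 2
# three-by-three convolutions (10) + 4 decoder levels x 2 (8) + 4
# two-by-two transposed convolutions + the final 1x1 projection = 23,
# with feature channels 32, 64, 128, 256, 512 across the 5 levels.
# Each 3x3 convolution is followed by a ReLU and batch normalization;
# 2x2 max-pooling downscales between encoder levels and skip connections
# concatenate encoder features into the decoder. The 1x1 head produces a
# residual bounded to [-1, 1] by tanh, which is added to the sensor image
# and clamped to [0, 1].

#' Network architecture specification
#'
#' @param base_channels channels at the first level (32).
#' @param levels number of resolution levels (5).
#' @param input_multiple required divisor of input sides (16, from the
#'   four 2x2 poolings).
#' @return a `network_spec` list including the implied convolution-layer
#'   count and channel range.
#' @export
network_spec <- function(base_channels = 32L, levels = 5L,
                         input_multiple = 16L) {
  channels <- base_channels * 2^(0:(levels - 1))
  structure(list(
    base_channels = as.integer(base_channels),
    levels = as.integer(levels),
    channels = as.integer(channels),
    channel_min = as.integer(min(channels)),
    channel_max = as.integer(max(channels)),
    n_conv_layers = as.integer(2L * levels + 2L * (levels - 1L) +
                                 (levels - 1L) + 1L),
    input_multiple = as.integer(input_multiple)
  ), class = "network_spec")
}

init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -sqrt(1 / fan_in), sqrt(1 / fan_in)), nr, nc)
}

#' Build the deblurring network
#'
#' Constructs all parameters (uniform fan-in initialization, deterministic
#' per seed) plus the running batch-normalization statistics.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the initialization.
#' @return an object of class `edof_net` with elements `params` (flat
#'   named list of weight arrays), `stats` (running BN statistics),
#'   `spec`, `seed` and `training_stage`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  ch <- spec$channels
  L <- spec$levels
  params <- list(); stats <- list()
  with_local_seed(seed, {
    for (l in seq_len(L)) {
      cin <- if (l == 1) 1L else ch[l - 1]
      params[[sprintf("enc%d.c1.W", l)]] <- init_mat(9 * cin, ch[l], 9 * cin)
      params[[sprintf("enc%d.c1.b", l)]] <- numeric(ch[l])
      params[[sprintf("enc%d.c2.W", l)]] <- init_mat(9 * ch[l], ch[l], 9 * ch[l])
      params[[sprintf("enc%d.c2.b", l)]] <- numeric(ch[l])
      for (j in 1:2) {
        params[[sprintf("enc%d.n%d.g", l, j)]] <- rep(1, ch[l])
        params[[sprintf("enc%d.n%d.b", l, j)]] <- numeric(ch[l])
        stats[[sprintf("enc%d.n%d.mean", l, j)]] <- numeric(ch[l])
        stats[[sprintf("enc%d.n%d.var", l, j)]] <- rep(1, ch[l])
      }
    }
    for (l in (L - 1):1) {
      up <- array(stats::runif(4 * ch[l + 1] * ch[l],
                               -sqrt(1 / ch[l + 1]), sqrt(1 / ch[l + 1])),
                  c(4, ch[l + 1], ch[l]))
      params[[sprintf("dec%d.up.W", l)]] <- up
      params[[sprintf("dec%d.up.b", l)]] <- numeric(ch[l])
      params[[sprintf("dec%d.c1.W", l)]] <- init_mat(9 * 2 * ch[l], ch[l],
                                                     9 * 2 * ch[l])
      params[[sprintf("dec%d.c1.b", l)]] <- numeric(ch[l])
      params[[sprintf("dec%d.c2.W", l)]] <- init_mat(9 * ch[l], ch[l],
                                                     9 * ch[l])
      params[[sprintf("dec%d.c2.b", l)]] <- numeric(ch[l])
      for (j in 1:2) {
        params[[sprintf("dec%d.n%d.g", l, j)]] <- rep(1, ch[l])
        params[[sprintf("dec%d.n%d.b", l, j)]] <- numeric(ch[l])
        stats[[sprintf("dec%d.n%d.mean", l, j)]] <- numeric(ch[l])
        stats[[sprintf("dec%d.n%d.var", l, j)]] <- rep(1, ch[l])
      }
    }
    params[["final.W"]] <- init_mat(ch[1], 1, ch[1])
    params[["final.b"]] <- 0
  })
  structure(list(params = params, stats = stats, spec = spec,
                 seed = as.integer(seed), training_stage = "stage1"),
            class = "edof_net")
}

#' @export
print.edof_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<edof_net> %d conv layers, channels %d-%d, %.2fM parameters, stage %s\n",
              x$spec$n_conv_layers, x$spec$channel_min, x$spec$channel_max,
              np / 1e6, x$training_stage))
  invisible(x)
}

conv_block_fwd <- function(x, net, prefix, training) {
  p <- net$params; s <- net$stats
  cc <- list()
  c1 <- conv3_fwd(x, p[[paste0(prefix, ".c1.W")]], p[[paste0(prefix, ".c1.b")]])
  r1 <- relu_fwd(c1$out)
  n1 <- bn_fwd(r1$out, p[[paste0(prefix, ".n1.g")]], p[[paste0(prefix, ".n1.b")]],
               training, s[[paste0(prefix, ".n1.mean")]],
               s[[paste0(prefix, ".n1.var")]])
  c2 <- conv3_fwd(n1$out, p[[paste0(prefix, ".c2.W")]], p[[paste0(prefix, ".c2.b")]])
  r2 <- relu_fwd(c2$out)
  n2 <- bn_fwd(r2$out, p[[paste0(prefix, ".n2.g")]], p[[paste0(prefix, ".n2.b")]],
               training, s[[paste0(prefix, ".n2.mean")]],
               s[[paste0(prefix, ".n2.var")]])
  list(out = n2$out, cache = list(c1 = c1, r1 = r1, n1 = n1,
                                  c2 = c2, r2 = r2, n2 = n2))
}

conv_block_bwd <- function(cache, net, prefix, dout, grads) {
  p <- net$params
  b2 <- bn_bwd(cache$n2, p[[paste0(prefix, ".n2.g")]], dout)
  grads[[paste0(prefix, ".n2.g")]] <- b2$dgamma
  grads[[paste0(prefix, ".n2.b")]] <- b2$dbeta
  d <- relu_bwd(cache$r2, b2$dx)
  cb2 <- conv3_bwd(cache$c2, p[[paste0(prefix, ".c2.W")]], d)
  grads[[paste0(prefix, ".c2.W")]] <- cb2$dW
  grads[[paste0(prefix, ".c2.b")]] <- cb2$db
  b1 <- bn_bwd(cache$n1, p[[paste0(prefix, ".n1.g")]], cb2$dx)
  grads[[paste0(prefix, ".n1.g")]] <- b1$dgamma
  grads[[paste0(prefix, ".n1.b")]] <- b1$dbeta
  d <- relu_bwd(cache$r1, b1$dx)
  cb1 <- conv3_bwd(cache$c1, p[[paste0(prefix, ".c1.W")]], d)
  grads[[paste0(prefix, ".c1.W")]] <- cb1$dW
  grads[[paste0(prefix, ".c1.b")]] <- cb1$db
  list(dx = cb1$dx, grads = grads)
}

#' Full forward pass with cache
#'
#' Internal-facing: [deblur()] is the user entry point. Returns the output
#' image plus everything needed for [net_backward()]. When `training` is
#' TRUE, batch statistics are used and running statistics updated (the
#' updated values are in the cache under `new_stats`).
#'
#' @param net an `edof_net`.
#' @param x input image matrix (values in `[0, 1]`, sides multiples of 16).
#' @param training logical; batch vs running BN statistics.
#' @return list with `out` (matrix) and `cache`.
#' @export
net_forward <- function(net, x, training = FALSE) {
  spec <- net$spec
  L <- spec$levels
  d <- dim(x)
  if (any(d %% spec$input_multiple != 0)) {
    stop(sprintf("input sides (%dx%d) must be multiples of %d",
                 d[1], d[2], spec$input_multiple))
  }
  a <- array(x, c(d, 1))
  enc <- vector("list", L); pools <- vector("list", L - 1)
  for (l in seq_len(L)) {
    blk <- conv_block_fwd(a, net, sprintf("enc%d", l), training)
    enc[[l]] <- blk
    if (l < L) {
      pools[[l]] <- maxpool_fwd(blk$out)
      a <- pools[[l]]$out
    }
  }
  a <- enc[[L]]$out
  dec <- vector("list", L - 1); ups <- vector("list", L - 1)
  for (l in (L - 1):1) {
    up <- tconv_fwd(a, net$params[[sprintf("dec%d.up.W", l)]],
                    net$params[[sprintf("dec%d.up.b", l)]])
    ups[[l]] <- up
    skip <- enc[[l]]$out
    cat_in <- array(0, c(dim(up$out)[1:2], dim(up$out)[3] + dim(skip)[3]))
    cat_in[, , seq_len(dim(up$out)[3])] <- up$out
    cat_in[, , dim(up$out)[3] + seq_len(dim(skip)[3])] <- skip
    blk <- conv_block_fwd(cat_in, net, sprintf("dec%d", l), training)
    dec[[l]] <- blk
    a <- blk$out
  }
  fin <- conv1_fwd(a, net$params[["final.W"]], net$params[["final.b"]])
  resid <- tanh(fin$out[, , 1])
  pre <- x + resid
  out <- clip01(pre)
  cache <- list(enc = enc, pools = pools, ups = ups, dec = dec, fin = fin,
                resid = resid, pre = pre, x = x, training = training)
  if (training) {
    new_stats <- net$stats
    walk <- function(prefix, blk) {
      for (j in 1:2) {
        nj <- blk$cache[[paste0("n", j)]]
        new_stats[[sprintf("%s.n%d.mean", prefix, j)]] <<- nj$rmean
        new_stats[[sprintf("%s.n%d.var", prefix, j)]] <<- nj$rvar
      }
    }
    for (l in seq_len(L)) walk(sprintf("enc%d", l), enc[[l]])
    for (l in seq_len(L - 1)) walk(sprintf("dec%d", l), dec[[l]])
    cache$new_stats <- new_stats
  }
  list(out = out, cache = cache)
}

#' Backward pass of the network
#'
#' Propagates the gradient of a scalar loss with respect to the output
#' back to every parameter and to the input image (through both the
#' residual-add shortcut and the convolutional path), enabling joint
#' optimization of upstream optics.
#'
#' @param net an `edof_net`.
#' @param cache cache from [net_forward()].
#' @param dout gradient matrix with respect to the output.
#' @return list with `grads` (named like `net$params`) and `dx` (matrix).
#' @export
net_backward <- function(net, cache, dout) {
  L <- net$spec$levels
  grads <- list()
  dpre <- dout * (cache$pre > 0 & cache$pre < 1)
  dx_direct <- dpre
  dresid <- dpre * (1 - cache$resid^2)
  dfin <- array(dresid, c(dim(dresid), 1))
  fb <- conv1_bwd(cache$fin, net$params[["final.W"]], dfin)
  grads[["final.W"]] <- fb$dW
  grads[["final.b"]] <- fb$db
  da <- fb$dx
  denc_out <- vector("list", L)  # gradients flowing into encoder outputs
  for (l in seq_len(L - 1)) {
    bb <- conv_block_bwd(cache$dec[[l]]$cache, net, sprintf("dec%d", l),
                         da, grads)
    grads <- bb$grads
    dcat <- bb$dx
    cup <- dim(cache$ups[[l]]$out)[3]
    dup <- dcat[, , seq_len(cup), drop = FALSE]
    denc_out[[l]] <- dcat[, , cup + seq_len(dim(dcat)[3] - cup), drop = FALSE]
    ub <- tconv_bwd(cache$ups[[l]], net$params[[sprintf("dec%d.up.W", l)]], dup)
    grads[[sprintf("dec%d.up.W", l)]] <- ub$dW
    grads[[sprintf("dec%d.up.b", l)]] <- ub$db
    da <- ub$dx
  }
  # da now reaches the bottleneck (enc L) output; shallower levels also
  # receive the skip-connection gradient collected above
  for (l in L:1) {
    dblk <- if (l == L) da
            else maxpool_bwd(cache$pools[[l]], da) + denc_out[[l]]
    bb <- conv_block_bwd(cache$enc[[l]]$cache, net, sprintf("enc%d", l),
                         dblk, grads)
    grads <- bb$grads
    da <- bb$dx
  }
  dx <- dx_direct + da[, , 1]
  list(grads = grads, dx = dx)
}

#' Deblur a sensor image
#'
#' Runs the network in evaluation mode (frozen batch-normalization
#' statistics). Output equals the input plus a tanh-bounded residual,
#' clamped to `[0, 1]`; with the final projection zeroed the network is
#' the identity on clipped inputs.
#'
#' @param net an `edof_net`.
#' @param sensor a `sensor_image` from [render_sensor()] or a plain matrix
#'   in `[0, 1]` with sides multiples of 16.
#' @return deblurred matrix in `[0, 1]`, same shape as the input.
#' @export
deblur <- function(net, sensor) {
  x <- if (inherits(sensor, "sensor_image")) sensor$image else sensor
  stopifnot(is.matrix(x))
  net_forward(net, x, training = FALSE)$out
}

#' Save / load a network checkpoint
#'
#' Single-file archive holding the architecture spec, all weights and
#' running statistics, the initialization seed, the training stage and a
#' format version.
#'
#' @param net an `edof_net`.
#' @param path file path (RDS archive).
#' @param mask optional mask object trained jointly with the network.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: a
#'   list with `net` and (possibly NULL) `mask`.
#' @export
save_checkpoint <- function(net, path, mask = NULL) {
  saveRDS(list(version = 1L, net = net, mask = mask), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version > 1L) {
    stop("unsupported checkpoint version")
  }
  list(net = ck$net, mask = ck$mask)
}
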