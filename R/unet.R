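#' 3D U-Net configuration
#'
#' Declarative description of the segmentation network: a contracting and
#' an expanding path with `n_levels` resolution levels.  Each level applies
#' two 3x3x3 convolutions, each followed by a ReLU and a batch
#' normalization; 2x2x2 max pooling (stride 2) connects encoder levels and
#' nearest-neighbour 2x upsampling plus skip concatenation connects decoder
#' levels.  A final 1x1x1 convolution maps to `n_classes` channels followed
#' by a voxel-wise SoftMax.  Channels start at `base_channels` and multiply
#' by `channel_growth` per level; the defaults (4 levels, 16 base channels,
#' doubling) give roughly 1.46 million trainable parameters.
#'
#' @param n_levels Number of resolution levels (>= 1).
#' @param base_channels Channels of the first level.
#' @param channel_growth Channel multiplier per level.
#' @param n_classes Output classes (background + structures; default 9).
#' @param conv_kernel Convolution kernel edge (odd; default 3).
#' @param pool_kernel Pooling kernel/stride (default 2).
#' @return A `unet_config` object.
#' @export
unet_config <- function(n_levels = 4, base_channels = 16, channel_growth = 2,
                        n_classes = 9, conv_kernel = 3, pool_kernel = 2) {
  stopifnot(n_levels >= 1, n_classes >= 2, base_channels >= 1,
            conv_kernel %% 2 == 1)
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 n_classes = as.integer(n_classes),
                 conv_kernel = as.integer(conv_kernel),
                 pool_kernel = as.integer(pool_kernel)),
            class = "unet_config")
}

level_channels <- function(config, l) {
  as.integer(round(config$base_channels * config$channel_growth^(l - 1)))
}

# Shapes of every trainable array, keyed by "enc{l}.c{1,2}.{W,b,gamma,beta}",
# "dec{l}...." and "head.{W,b}".  Parameter count is therefore a pure
# function of the configuration.
unet_param_shapes <- function(config) {
  K <- config$conv_kernel
  L <- config$n_levels
  shapes <- list()
  conv_block <- function(prefix, cin, cout) {
    for (cv in c("c1", "c2")) {
      shapes[[paste0(prefix, ".", cv, ".W")]] <<- c(K, K, K, cin, cout)
      shapes[[paste0(prefix, ".", cv, ".b")]] <<- cout
      shapes[[paste0(prefix, ".", cv, ".gamma")]] <<- cout
      shapes[[paste0(prefix, ".", cv, ".beta")]] <<- cout
      cin <- cout
    }
  }
  cin <- 1L
  for (l in seq_len(L)) {
    conv_block(paste0("enc", l), cin, level_channels(config, l))
    cin <- level_channels(config, l)
  }
  if (L > 1) {
    for (l in seq(L - 1, 1)) {
      conv_block(paste0("dec", l),
                 level_channels(config, l) + level_channels(config, l + 1),
                 level_channels(config, l))
    }
  }
  shapes[["head.W"]] <- c(level_channels(config, 1), config$n_classes)
  shapes[["head.b"]] <- config$n_classes
  shapes
}

#' Build a 3D U-Net model
#'
#' Instantiates the network described by a [unet_config()] with
#' He-initialized convolution weights, zero biases and unit-scale batch
#' normalization, reproducibly from `seed`.  Batch size is a single 3D
#' volume throughout the package, so batch normalization uses the current
#' instance's spatial statistics (instance-norm behaviour) both in
#' training and inference.
#'
#' @param config A `unet_config`.
#' @param seed Integer seed for the weight initialization.
#' @param head_bias Optional length-`n_classes` numeric used as the final
#'   1x1x1 convolution's bias.  Training sets it to the log class priors of
#'   the training labels, so the untrained network already predicts the
#'   empirical label distribution instead of spending its first iterations
#'   re-learning it.
#' @return A `unet_model` object (config, flat parameter list, seed).
#' @export
build_unet <- function(config, seed = 1L, head_bias = NULL) {
  stopifnot(inherits(config, "unet_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  shapes <- unet_param_shapes(config)
  params <- lapply(names(shapes), function(nm) {
    shp <- shapes[[nm]]
    if (endsWith(nm, ".W")) {
      fan_in <- if (length(shp) > 2) prod(shp[-length(shp)]) else shp[1]
      array(rnorm(prod(shp), 0, sqrt(2 / fan_in)), dim = shp)
    } else if (endsWith(nm, ".gamma")) {
      rep(1, shp)
    } else {
      rep(0, shp)
    }
  })
  names(params) <- names(shapes)
  if (!is.null(head_bias)) {
    stopifnot(length(head_bias) == config$n_classes)
    params[["head.b"]] <- as.numeric(head_bias)
  }
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "unet_model")
}

#' Count trainable parameters
#'
#' @param x A `unet_model` or `unet_config`.
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "unet_model")) x <- x$config
  stopifnot(inherits(x, "unet_config"))
  sum(vapply(unet_param_shapes(x), prod, 1))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %d levels, %d base channels, %d classes, %s parameters\n",
              x$config$n_levels, x$config$base_channels, x$config$n_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

bn_eps <- 1e-5

as_chan <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

# column-wise scalar expansion without aperm/sweep overhead
colrep <- function(v, V) rep(v, each = V)

bn_fwd <- function(r, gamma, beta) {
  d <- dim(r); V <- prod(d[1:3]); C <- d[4]
  out <- .bn_fwd(r, V, C, gamma, beta, bn_eps)
  dim(out$y) <- d
  list(y = out$y, xhat = out$xhat, s = out$s)
}

bn_bwd <- function(gy, xhat, s, gamma) {
  d <- dim(gy); V <- prod(d[1:3]); C <- d[4]
  out <- .bn_bwd(gy, xhat, s, gamma, V, C)
  dim(out$gx) <- d
  list(gx = out$gx, dgamma = out$dgamma, dbeta = out$dbeta)
}

upsample_nn <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample_nn_bwd <- function(g) {
  d <- dim(g)
  g <- g[seq(1, d[1], 2), , , , drop = FALSE] +
    g[seq(2, d[1], 2), , , , drop = FALSE]
  g <- g[, seq(1, d[2], 2), , , drop = FALSE] +
    g[, seq(2, d[2], 2), , , drop = FALSE]
  g[, , seq(1, d[3], 2), , drop = FALSE] +
    g[, , seq(2, d[3], 2), , drop = FALSE]
}

# conv -> batch norm -> ReLU per convolution (the nnU-Net block layout
# this architecture family derives from)
conv_block_fwd <- function(params, prefix, x, train) {
  cache <- if (train) list() else NULL
  for (cv in c("c1", "c2")) {
    W <- params[[paste0(prefix, ".", cv, ".W")]]
    b <- params[[paste0(prefix, ".", cv, ".b")]]
    z <- .conv3d_fwd(x, dim(x), W, dim(W), b)
    bn <- bn_fwd(z, params[[paste0(prefix, ".", cv, ".gamma")]],
                 params[[paste0(prefix, ".", cv, ".beta")]])
    y <- bn$y * (bn$y > 0)
    if (train) {
      cache[[cv]] <- list(x = x, mask = bn$y > 0, xhat = bn$xhat, s = bn$s)
    }
    x <- y
  }
  list(y = x, cache = cache)
}

conv_block_bwd <- function(params, prefix, g, cache, grads) {
  for (cv in c("c2", "c1")) {
    cc <- cache[[cv]]
    gamma <- params[[paste0(prefix, ".", cv, ".gamma")]]
    bb <- bn_bwd(g * cc$mask, cc$xhat, cc$s, gamma)
    grads[[paste0(prefix, ".", cv, ".gamma")]] <- bb$dgamma
    grads[[paste0(prefix, ".", cv, ".beta")]] <- bb$dbeta
    gz <- bb$gx
    W <- params[[paste0(prefix, ".", cv, ".W")]]
    gw <- .conv3d_bwd_w(cc$x, dim(cc$x), gz, dim(W))
    grads[[paste0(prefix, ".", cv, ".W")]] <- gw$W
    grads[[paste0(prefix, ".", cv, ".b")]] <- gw$b
    g <- .conv3d_bwd_x(gz, dim(gz), W, dim(W))
  }
  list(g = g, grads = grads)
}

check_divisible <- function(d, config) {
  need <- config$pool_kernel^(config$n_levels - 1)
  if (any(d[1:3] %% need != 0)) {
    pad <- (need - d[1:3] %% need) %% need
    stop(sprintf(
      "spatial shape %s not divisible by %d; pad by (%s) voxels (predict_labels does this automatically)",
      paste(d[1:3], collapse = "x"), need, paste(pad, collapse = ",")),
      call. = FALSE)
  }
}

# Forward pass.  x: 3D volume or (X,Y,Z,1) array.  Returns logits as a
# (X,Y,Z,n_classes) array plus (in training mode) the caches needed for
# backpropagation.
unet_forward <- function(model, x, train = FALSE) {
  cfg <- model$config; P <- model$params; L <- cfg$n_levels
  x <- as_chan(x)
  check_divisible(dim(x), cfg)
  cache <- list(enc = vector("list", L), dec = vector("list", max(L - 1, 0)))
  skips <- vector("list", max(L - 1, 0))
  h <- x
  for (l in seq_len(L)) {
    blk <- conv_block_fwd(P, paste0("enc", l), h, train)
    h <- blk$y
    if (train) cache$enc[[l]] <- list(block = blk$cache)
    if (l < L) {
      skips[[l]] <- h
      mp <- .maxpool_fwd(h, dim(h))
      if (train) {
        cache$enc[[l]]$argmax <- mp$argmax
        cache$enc[[l]]$pre_pool_dim <- dim(h)
      }
      h <- mp$y
    }
  }
  if (L > 1) {
    for (l in seq(L - 1, 1)) {
      up <- upsample_nn(h)
      cs <- dim(skips[[l]])[4]
      h2 <- array(c(skips[[l]], up), dim = c(dim(up)[1:3], cs + dim(up)[4]))
      blk <- conv_block_fwd(P, paste0("dec", l), h2, train)
      if (train) cache$dec[[l]] <- list(block = blk$cache, n_skip = cs,
                                        up_dim = dim(up))
      h <- blk$y
    }
  }
  d <- dim(h); V <- prod(d[1:3])
  hf <- matrix(h, V, d[4])
  logits <- hf %*% P[["head.W"]] + colrep(P[["head.b"]], V)
  if (train) cache$head_in <- hf
  dim(logits) <- c(d[1:3], cfg$n_classes)
  list(logits = logits, cache = if (train) cache else NULL)
}

# Backpropagation from a gradient on the logits.  Returns the flat list of
# parameter gradients (same names/shapes as model$params).
unet_backward <- function(model, cache, glogits) {
  cfg <- model$config; P <- model$params; L <- cfg$n_levels
  d <- dim(glogits); V <- prod(d[1:3])
  grads <- list()
  gm <- matrix(glogits, V, d[4])
  grads[["head.W"]] <- crossprod(cache$head_in, gm)
  grads[["head.b"]] <- colSums(gm)
  g <- gm %*% t(P[["head.W"]])
  dim(g) <- c(d[1:3], ncol(cache$head_in))

  gskip <- vector("list", max(L - 1, 0))
  if (L > 1) {
    for (l in seq_len(L - 1)) {       # reverse of decoder forward order
      cd <- cache$dec[[l]]
      bb <- conv_block_bwd(P, paste0("dec", l), g, cd$block, grads)
      grads <- bb$grads
      gx <- bb$g
      cs <- cd$n_skip
      gskip[[l]] <- gx[, , , seq_len(cs), drop = FALSE]
      gup <- gx[, , , cs + seq_len(dim(gx)[4] - cs), drop = FALSE]
      g <- upsample_nn_bwd(gup)
    }
  }
  for (l in seq(L, 1)) {
    if (l < L) {
      ce <- cache$enc[[l]]
      gpool <- .maxpool_bwd(g, ce$argmax, ce$pre_pool_dim)
      g <- gpool + gskip[[l]]
    }
    bb <- conv_block_bwd(P, paste0("enc", l), g, cache$enc[[l]]$block, grads)
    grads <- bb$grads
    g <- bb$g
  }
  grads
}

softmax_channels <- function(logits) {
  d <- dim(logits); V <- prod(d[1:3])
  m <- matrix(logits, V, d[4])
  mx <- m[cbind(seq_len(V), max.col(m, ties.method = "first"))]
  m <- exp(m - mx)       # mx recycles down each column
  p <- m / rowSums(m)
  dim(p) <- d
  p
}

#' Predict a label map for one volume
#'
#' Runs the network on a (normalized) 3D volume and takes the per-voxel
#' argmax over the SoftMax channels.  Volumes whose extents are not
#' divisible by `pool_kernel^(n_levels-1)` are symmetrically zero-padded
#' and the prediction cropped back.  Inference is deterministic.
#'
#' @param model A `unet_model`.
#' @param volume 3D numeric array (intensity-normalized).
#' @return 3D integer array of labels in `0..n_classes-1`.
#' @export
predict_labels <- function(model, volume) {
  stopifnot(inherits(model, "unet_model"), length(dim(volume)) == 3)
  d <- dim(volume)
  need <- model$config$pool_kernel^(model$config$n_levels - 1)
  pad <- (need - d %% need) %% need
  lo <- pad %/% 2; hi <- pad - lo
  if (any(pad > 0)) {
    padded <- array(0, d + pad)
    padded[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]),
           lo[3] + seq_len(d[3])] <- volume
    volume <- padded
  }
  probs <- softmax_channels(unet_forward(model, volume)$logits)
  dd <- dim(probs)
  lab <- array(max.col(matrix(probs, prod(dd[1:3]), dd[4]),
                       ties.method = "first") - 1L, dd[1:3])
  if (any(pad > 0)) {
    lab <- lab[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]),
               lo[3] + seq_len(d[3]), drop = FALSE]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Save / load a trained model
#'
#' Checkpoints carry the network configuration, all parameters and the
#' training seed.
#'
#' @param model A `unet_model`.
#' @param path File path (`.rds`).
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "unet_model"))
  m
}
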