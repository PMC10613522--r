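# Hand oracle for the parameter count of a given channel progression:
# each conv carries K^3*Cin*Cout weights + Cout biases + 2*Cout batch-norm
# scalars; the head is a 1x1x1 conv.
count_by_hand <- function(channels, n_classes, K = 3) {
  total <- 0
  cin <- 1
  for (c in channels) {                     # encoder (last = bottleneck)
    total <- total + (K^3 * cin * c + c + 2 * c) + (K^3 * c * c + c + 2 * c)
    cin <- c
  }
  L <- length(channels)
  if (L > 1) {
    for (l in seq(L - 1, 1)) {              # decoder
      cc <- channels[l]
      cin <- channels[l + 1] + cc
      total <- total + (K^3 * cin * cc + cc + 2 * cc) +
        (K^3 * cc * cc + cc + 2 * cc)
    }
  }
  total + channels[1] * n_classes + n_classes
}

test_that("default architecture lands near 1.5 million parameters", {
  n <- count_parameters(unet_config())
  expect_equal(unet_config()$n_classes, 9)
  expect_lt(abs(n - 1.5e6) / 1.5e6, 0.10)
  expect_identical(n, count_by_hand(c(16, 32, 64, 128), 9))
})

test_that("parameter count matches the layer-by-layer oracle on small configs", {
  cases <- list(
    list(cfg = unet_config(n_levels = 1, base_channels = 2, n_classes = 2),
         channels = 2),
    list(cfg = unet_config(n_levels = 2, base_channels = 3, n_classes = 5),
         channels = c(3, 6)),
    list(cfg = unet_config(n_levels = 3, base_channels = 4, n_classes = 9),
         channels = c(4, 8, 16)))
  for (cs in cases) {
    expect_identical(count_parameters(cs$cfg),
                     count_by_hand(cs$channels, cs$cfg$n_classes))
    # counting a built model gives the same number, twice
    m <- build_unet(cs$cfg, seed = 3)
    expect_identical(count_parameters(m), count_parameters(m))
    expect_identical(count_parameters(m), count_parameters(cs$cfg))
    expect_identical(sum(lengths(m$params)), as.integer(count_parameters(m)))
  }
})

test_that("forward pass produces per-voxel SoftMax over n_classes channels", {
  net <- unet_config(n_levels = 2, base_channels = 2, n_classes = 9)
  m <- build_unet(net, seed = 1)
  x <- array(rnorm(8^3), c(8, 8, 8))
  logits <- cineheart:::unet_forward(m, x)$logits
  expect_equal(dim(logits), c(8, 8, 8, 9))
  p <- cineheart:::softmax_channels(logits)
  sums <- apply(p, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(p >= 0))
})

# Double-precision reference convolution for the kernel gradient oracle
ref_conv3d <- function(x, W, b) {
  d <- dim(x); Co <- dim(W)[5]
  xp <- array(0, c(d[1:3] + 2, d[4]))
  xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
  y <- array(0, c(d[1:3], Co))
  for (co in 1:Co) {
    acc <- array(b[co], d[1:3])
    for (ci in 1:d[4]) for (kz in 1:3) for (ky in 1:3) for (kx in 1:3) {
      acc <- acc + W[kx, ky, kz, ci, co] *
        xp[(kx - 1) + 1:d[1], (ky - 1) + 1:d[2], (kz - 1) + 1:d[3], ci]
    }
    y[, , , co] <- acc
  }
  y
}

test_that("convolution forward and both gradients match a double-precision oracle", {
  set.seed(3)
  X <- 6; Ci <- 2; Co <- 3
  x <- array(rnorm(X^3 * Ci), c(X, X, X, Ci))
  g <- array(rnorm(X^3 * Co), c(X, X, X, Co))
  W <- array(rnorm(27 * Ci * Co), c(3, 3, 3, Ci, Co))
  b <- rnorm(Co)
  expect_equal(cineheart:::.conv3d_fwd(x, dim(x), W, dim(W), b),
               ref_conv3d(x, W, b), tolerance = 1e-5, ignore_attr = TRUE)
  gw <- cineheart:::.conv3d_bwd_w(x, dim(x), g, dim(W))
  gx <- cineheart:::.conv3d_bwd_x(g, dim(g), W, dim(W))
  eps <- 1e-4
  for (i in sample(length(W), 8)) {
    Wp <- W; Wp[i] <- Wp[i] + eps
    Wm <- W; Wm[i] <- Wm[i] - eps
    fd <- (sum(g * ref_conv3d(x, Wp, b)) - sum(g * ref_conv3d(x, Wm, b))) /
      (2 * eps)
    expect_equal(gw$W[i], fd, tolerance = 1e-4)
  }
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (sum(g * ref_conv3d(xp, W, b)) - sum(g * ref_conv3d(xm, W, b))) /
      (2 * eps)
    expect_equal(gx[i], fd, tolerance = 1e-4)
  }
  expect_equal(gw$b, apply(g, 4, sum), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("instance batch-norm backward matches its closed form", {
  set.seed(8)
  V <- 50; C <- 3
  r <- array(rnorm(V * C), c(V, 1, 1, C))
  gamma <- runif(C, 0.5, 1.5); beta <- rnorm(C)
  fwd <- cineheart:::bn_fwd(r, gamma, beta)
  m <- matrix(r, V, C)
  mu <- colMeans(m); s <- sqrt(colMeans(m * m) - mu^2 + 1e-5)
  expect_equal(fwd$s, s, tolerance = 1e-12)
  expect_equal(matrix(fwd$y, V, C),
               t((t(m) - mu) / s * gamma + beta), tolerance = 1e-12)
  gy <- array(rnorm(V * C), c(V, 1, 1, C))
  bwd <- cineheart:::bn_bwd(gy, fwd$xhat, fwd$s, gamma)
  gm <- matrix(gy, V, C); xh <- matrix(fwd$xhat, V, C)
  gx_ref <- t(t(gm - rep(1, V) %o% colMeans(gm) -
                  xh * (rep(1, V) %o% colMeans(gm * xh))) * (gamma / s))
  expect_equal(matrix(bwd$gx, V, C), gx_ref, tolerance = 1e-12)
  expect_equal(bwd$dgamma, colSums(gm * xh), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(bwd$dbeta, colSums(gm), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("end-to-end gradient points along the finite-difference direction", {
  # the exact component gradients are verified above; end-to-end agreement
  # with finite differences is limited by the density of ReLU kinks, so
  # only directional consistency is asserted here
  set.seed(42)
  net <- unet_config(n_levels = 2, base_channels = 2, n_classes = 3)
  m <- build_unet(net, seed = 7)
  x <- array(rnorm(8^3), c(8, 8, 8))
  y <- array(sample(0:2, 8^3, TRUE), c(8, 8, 8))
  w <- c(1, 1.5, 0.5)
  lossfn <- function(model) {
    fw <- cineheart:::unet_forward(model, x, train = TRUE)
    V <- 8^3
    p <- matrix(cineheart:::softmax_channels(fw$logits), V, 3)
    yy <- as.integer(y) + 1L
    wv <- w[yy]
    list(loss = -sum(wv * log(p[cbind(seq_len(V), yy)])) / sum(wv), fw = fw)
  }
  l0 <- lossfn(m)
  V <- 8^3
  p <- matrix(cineheart:::softmax_channels(l0$fw$logits), V, 3)
  yy <- as.integer(y) + 1L
  wv <- w[yy]
  iy <- cbind(seq_len(V), yy)
  G <- p; G[iy] <- G[iy] - 1; G <- G * (wv / sum(wv))
  dim(G) <- dim(l0$fw$logits)
  gr <- cineheart:::unet_backward(m, l0$fw$cache, G)
  v <- lapply(m$params, function(p) {
    a <- rnorm(length(p)); dim(a) <- dim(p); a
  })
  dot <- sum(mapply(function(g, vv) sum(g * vv), gr[names(m$params)], v))
  eps <- 1e-3
  mp <- m; mm <- m
  for (nm in names(m$params)) {
    mp$params[[nm]] <- m$params[[nm]] + eps * v[[nm]]
    mm$params[[nm]] <- m$params[[nm]] - eps * v[[nm]]
  }
  num <- (lossfn(mp)$loss - lossfn(mm)$loss) / (2 * eps)
  expect_lt(abs(num - dot) / abs(num), 0.15)
  expect_gt(sign(num) * sign(dot), 0)
})

test_that("prediction is deterministic and honours the label vocabulary", {
  net <- unet_config(n_levels = 2, base_channels = 2, n_classes = 4)
  m <- build_unet(net, seed = 5)
  x <- array(rnorm(12^3), c(12, 12, 12))
  a <- predict_labels(m, x)
  b <- predict_labels(m, x)
  expect_identical(a, b)
  expect_true(all(a %in% 0:3))

  # a head biased hard towards class 0 predicts all background
  m0 <- m
  m0$params[["head.W"]][] <- 0
  m0$params[["head.b"]] <- c(10, rep(-10, 3))
  expect_true(all(predict_labels(m0, x) == 0L))
})

test_that("indivisible shapes are padded at prediction and rejected in training", {
  net <- unet_config(n_levels = 2, base_channels = 2, n_classes = 3)
  m <- build_unet(net, seed = 2)
  x <- array(rnorm(9 * 10 * 11), c(9, 10, 11))
  lab <- predict_labels(m, x)      # auto pad + crop
  expect_equal(dim(lab), c(9, 10, 11))
  expect_error(cineheart:::unet_forward(m, x), "divisible")
})

test_that("weight initialization is reproducible from the seed", {
  net <- tiny_net()
  expect_identical(build_unet(net, 11)$params, build_unet(net, 11)$params)
  expect_false(identical(build_unet(net, 11)$params,
                         build_unet(net, 12)$params))
})

test_that("a model can overfit a single annotated volume", {
  ph <- small_phantom()
  s <- normalize_intensity(ph$series)
  t_ed <- s$ed_index + 1L
  subj <- list(series = s, labels = ph$labels, frames = s$ed_index)
  cfg <- train_config(learning_rate = 2e-3, n_iterations = 600,
                      augmentation = NULL, seed = 3)
  m <- train_on_frames(list(subj), unet_config(n_levels = 2,
                                               base_channels = 6), cfg)
  pred <- predict_labels(m, s$frames[[t_ed]])
  dt <- dice_table(list(pred), list(ph$labels[[t_ed]]))
  expect_gt(mean(dt$dice), 0.85)
  expect_true(all(dt$dice > 0.6))
})

test_that("model checkpoints round-trip through save/load", {
  m <- build_unet(tiny_net(), seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  expect_identical(m2$seed, m$seed)
})
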