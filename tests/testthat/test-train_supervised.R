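test_that("class weights invert pooled frequencies and normalize to n_classes", {
  # 900 vs 100 voxels -> weights (0.2, 1.8)
  lab <- array(c(rep(0L, 900), rep(1L, 100)), c(10, 10, 10))
  expect_equal(class_frequency_weights(list(lab), 2), c(0.2, 1.8))

  # equal frequencies -> all ones
  lab2 <- toy_labels(c(6, 6, 6), 0:2)
  expect_equal(class_frequency_weights(list(lab2), 3), rep(1, 3))

  # 800/150/50 -> proportional to (1/0.8, 1/0.15, 1/0.05), sum 3
  lab3 <- array(c(rep(0L, 800), rep(1L, 150), rep(2L, 50)), c(10, 10, 10))
  w <- class_frequency_weights(list(lab3), 3)
  raw <- 1 / c(0.8, 0.15, 0.05)
  expect_equal(w, raw * 3 / sum(raw))
  # w_c * f_c constant across classes
  expect_equal(diff(range(w * c(0.8, 0.15, 0.05))), 0, tolerance = 1e-12)

  # absent class floored with warning
  expect_warning(w4 <- class_frequency_weights(list(lab), 3), "absent")
  expect_true(all(w4 > 0))
})

test_that("augmentation with zero ranges is the identity", {
  ph <- small_phantom()
  vol <- ph$series$frames[[1]]
  lab <- ph$labels[[1]]
  cfg <- augment_config(rotation_deg = 0, shear = 0, translation_vox = 0,
                        intensity_scale = 0, intensity_shift = 0,
                        noise_sd = 0, flip_lr_prob = 0, flip_ap_prob = 0)
  out <- augment(vol, lab, cfg, draw_seed = 3)
  expect_equal(out$volume, vol, ignore_attr = TRUE)
  expect_equal(as.integer(out$labels), as.integer(lab))
})

test_that("a left-right flip is an involution on image and labels", {
  ph <- small_phantom()
  vol <- ph$series$frames[[2]]
  lab <- ph$labels[[2]]
  once <- apply_affine(vol, lab, flip = c(TRUE, FALSE, FALSE))
  twice <- apply_affine(once$volume, once$labels, flip = c(TRUE, FALSE, FALSE))
  expect_equal(twice$volume, vol, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(as.integer(twice$labels), as.integer(lab))
  expect_false(isTRUE(all.equal(once$volume, vol, check.attributes = FALSE)))
})

test_that("an exact 90-degree rotation permutes voxels, preserving label counts", {
  ph <- small_phantom()
  lab <- ph$labels[[1]]
  vol <- ph$series$frames[[1]]
  rot <- apply_affine(vol, lab, rotation_deg = c(0, 0, 90))
  before <- tabulate(as.integer(lab) + 1L, nbins = 9)
  after <- tabulate(as.integer(rot$labels) + 1L, nbins = 9)
  expect_identical(after, before)
})

test_that("identical geometric transforms are applied to image and labels", {
  ph <- small_phantom()
  vol <- ph$series$frames[[1]]
  lab <- ph$labels[[1]]
  out <- apply_affine(vol, lab, translation = c(2, 0, 0))
  # blood pool (bright) should follow the labels
  fg_mean <- mean(out$volume[out$labels > 0])
  bg_mean <- mean(out$volume[out$labels == 0])
  expect_gt(fg_mean, bg_mean * 2)
})

test_that("augment draws are reproducible and leave the caller RNG alone", {
  ph <- small_phantom()
  vol <- ph$series$frames[[1]]
  lab <- ph$labels[[1]]
  cfg <- augment_config()
  a <- augment(vol, lab, cfg, draw_seed = 99)
  set.seed(1); r1 <- runif(1)
  b <- augment(vol, lab, cfg, draw_seed = 99)
  set.seed(1); r2 <- runif(1)
  expect_identical(a$volume, b$volume)
  expect_identical(r1, r2)
})

test_that("training reduces the loss and is bit-reproducible from the seed", {
  ph <- small_phantom()
  s <- normalize_intensity(ph$series)
  subj <- list(series = s, labels = ph$labels,
               frames = c(s$ed_index, s$es_index))
  net <- tiny_net()
  cfg <- train_config(learning_rate = 1e-3, n_iterations = 60, seed = 21,
                      augmentation = augment_config(rotation_deg = 5,
                                                    shear = 0.05,
                                                    translation_vox = 1,
                                                    flip_lr_prob = 0,
                                                    flip_ap_prob = 0,
                                                    noise_sd = 0.01))
  m1 <- train_on_frames(list(subj), net, cfg)
  m2 <- train_on_frames(list(subj), net, cfg)
  tr1 <- attr(m1, "loss_trace")
  expect_identical(tr1, attr(m2, "loss_trace"))
  expect_identical(m1$params, m2$params)
  expect_lt(mean(tail(tr1, 10)), tr1[1])

  expect_error(train_on_frames(list(list(series = s,
                                         labels = vector("list", 30))),
                               net, cfg), "no labeled frames")
})

test_that("frame accounting reproduces the pooled training-set arithmetic", {
  # 74 subjects x 30 frames, 2 annotated each
  acct <- frame_accounting(74, 30, 2)
  expect_identical(acct$n_pseudo, 2072L)
  expect_identical(acct$n_total, 2220L)
  # degenerate: ED/ES only
  expect_identical(frame_accounting(1, 2, 2)$n_pseudo, 0L)
  # 3 subjects, F=10 -> 30 pooled, 24 pseudo
  acct3 <- frame_accounting(3, 10, 2)
  expect_identical(acct3$n_total, 30L)
  expect_identical(acct3$n_pseudo, 24L)
})

test_that("all-frames baseline pools hard pseudo-labels for every frame", {
  cfg_ph <- phantom_config(grid_size = 16, n_frames = 5, seed = 31)
  ph <- generate_phantom(cfg_ph)
  s <- normalize_intensity(ph$series)
  keep <- c(s$ed_index, s$es_index)
  labs <- vector("list", 5)
  labs[keep + 1L] <- ph$labels[keep + 1L]
  subj <- list(series = s, labels = labs, frames = keep)
  cfg <- train_config(learning_rate = 1e-3, n_iterations = 40,
                      augmentation = NULL, seed = 2)
  m <- train_all_frames_baseline(list(subj), tiny_net(), cfg)
  acct <- attr(m, "accounting")
  expect_identical(acct$n_pseudo, 3L)
  expect_identical(acct$n_total, 5L)
  pl <- attr(m, "pseudo_labels")[[1]]
  expect_length(pl, 5)
  expect_false(any(vapply(pl, is.null, TRUE)))
  for (l in pl) expect_true(all(l %in% 0:8))
})

test_that("with a single certainty level the sampling law collapses to uniform", {
  # matches the all-frames baseline's equal-probability selection
  F <- 10
  states <- lapply(seq_len(F) - 1L, function(t) {
    list(frame_index = t, label = array(0L, c(2, 2, 2)),
         provenance = "manual", level = 1L)
  })
  dataset <- list(list(states = states), list(states = states),
                  list(states = states))
  pol <- sampling_policy(frames_per_iteration = 1)
  expect_equal(frame_probabilities(states, pol), rep(1 / F, F))
  set.seed(77)
  draws <- t(vapply(1:10000, function(i) {
    b <- sample_batch(dataset, pol)
    c(b$subject, b$frames[1])
  }, c(0, 0)))
  expect_gt(chisq.test(tabulate(draws[, 1], 3))$p.value, 0.01)
  expect_gt(chisq.test(tabulate(draws[, 2] + 1, F))$p.value, 0.01)
})
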