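#' Inverted class-frequency loss weights
#'
#' Computes per-class weights for the weighted cross-entropy loss as the
#' inverse of the pooled voxel frequency of each class, normalized so the
#' weights sum to `n_classes`; small structures therefore receive larger
#' weights.  A class absent from the training labels (which genuinely
#' happens in congenital heart disease, e.g. single-ventricle anatomy) has
#' its count floored at one voxel, with a warning.
#'
#' @param labelmaps List of integer label arrays (values `0..n_classes-1`).
#' @param n_classes Number of classes.
#' @return Numeric vector of `n_classes` positive weights (class 0 first).
#' @export
class_frequency_weights <- function(labelmaps, n_classes) {
  counts <- numeric(n_classes)
  for (lm in labelmaps) {
    tab <- tabulate(as.integer(lm) + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  if (any(counts == 0)) {
    warning("classes absent from training labels: ",
            paste(which(counts == 0) - 1L, collapse = ", "),
            "; flooring their frequency at one voxel")
    counts[counts == 0] <- 1
  }
  f <- counts / sum(counts)
  w <- 1 / f
  w * n_classes / sum(w)
}

#' Augmentation configuration
#'
#' Random affine transformations (rotation, shearing, translation),
#' left-right and anteroposterior flips, intensity scaling, constant
#' intensity shifts and additive Gaussian noise.  The identical geometric
#' transform is applied to the image (trilinear) and its label map
#' (nearest-neighbour, preserving the label vocabulary).
#'
#' @param rotation_deg Max rotation magnitude per axis, degrees.
#' @param shear Max shear coefficient per plane.
#' @param translation_vox Max translation per axis, voxels.
#' @param intensity_scale Max relative intensity scaling.
#' @param intensity_shift Max constant intensity shift.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param flip_lr_prob,flip_ap_prob Probabilities of a left-right (x) and
#'   anteroposterior (y) flip.
#' @return An `augment_config` object.
#' @export
augment_config <- function(rotation_deg = 10, shear = 0.1,
                           translation_vox = 5, intensity_scale = 0.1,
                           intensity_shift = 0.1, noise_sd = 0.02,
                           flip_lr_prob = 0.5, flip_ap_prob = 0.5) {
  stopifnot(flip_lr_prob >= 0, flip_lr_prob <= 1,
            flip_ap_prob >= 0, flip_ap_prob <= 1)
  structure(list(rotation_deg = rotation_deg, shear = shear,
                 translation_vox = translation_vox,
                 intensity_scale = intensity_scale,
                 intensity_shift = intensity_shift, noise_sd = noise_sd,
                 flip_lr_prob = flip_lr_prob, flip_ap_prob = flip_ap_prob),
            class = "augment_config")
}

rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Apply a deterministic spatial transform to a volume and label map
#'
#' Builds the affine map `out = M (in - c) + c + t` (rotation, shear, axis
#' flips about the volume centre `c`, then translation `t`) and resamples
#' both inputs on the output grid: trilinear interpolation for the image,
#' nearest-neighbour for the labels, zero fill outside.
#'
#' @param volume 3D numeric array.
#' @param labels Optional 3D integer array of the same shape.
#' @param rotation_deg Length-3 rotation angles (degrees, about x/y/z).
#' @param shear Length-3 shear coefficients (xy, xz, yz).
#' @param translation Length-3 translation in voxels.
#' @param flip Length-3 logical (flip along x, y, z).
#' @return List with `volume` and `labels` (or `NULL`).
#' @export
apply_affine <- function(volume, labels = NULL, rotation_deg = c(0, 0, 0),
                         shear = c(0, 0, 0), translation = c(0, 0, 0),
                         flip = c(FALSE, FALSE, FALSE)) {
  d <- dim(volume)
  M <- rotation_matrix(rotation_deg)
  Sh <- rbind(c(1, shear[1], shear[2]), c(0, 1, shear[3]), c(0, 0, 1))
  Fl <- diag(ifelse(flip, -1, 1))
  M <- M %*% Sh %*% Fl
  ctr <- (d - 1) / 2
  Minv <- solve(M)
  offset <- ctr - Minv %*% (ctr + translation)
  A <- c(as.numeric(Minv), as.numeric(offset))
  out_vol <- .affine_resample(volume, d, A, d, FALSE, 0)
  out_lab <- NULL
  if (!is.null(labels)) {
    out_lab <- .affine_resample(as.numeric(labels) + 0, dim(labels), A, d,
                                TRUE, 0)
    storage.mode(out_lab) <- "integer"
    dim(out_lab) <- d
  }
  list(volume = out_vol, labels = out_lab)
}

#' Randomly augment one training sample
#'
#' Samples transform parameters uniformly within the configured ranges,
#' applies the identical geometric transform to image and labels, then
#' applies intensity scaling, a constant shift and additive Gaussian noise
#' to the image only.  Fully reproducible from `draw_seed`; the caller's
#' RNG state is untouched.
#'
#' @param volume 3D numeric array.
#' @param labels 3D integer array (same shape) or `NULL`.
#' @param config An `augment_config`.
#' @param draw_seed Integer seed for this draw.
#' @return List with `volume` and `labels`.
#' @export
augment <- function(volume, labels, config, draw_seed) {
  stopifnot(inherits(config, "augment_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(draw_seed)
  rot <- runif(3, -1, 1) * config$rotation_deg
  sh <- runif(3, -1, 1) * config$shear
  tr <- runif(3, -1, 1) * config$translation_vox
  fl <- c(runif(1) < config$flip_lr_prob, runif(1) < config$flip_ap_prob,
          FALSE)
  geom_identity <- all(rot == 0) && all(sh == 0) && all(tr == 0) && !any(fl)
  if (geom_identity) {
    out <- list(volume = volume, labels = labels)
  } else {
    out <- apply_affine(volume, labels, rotation_deg = rot, shear = sh,
                        translation = tr, flip = fl)
  }
  scale <- 1 + runif(1, -1, 1) * config$intensity_scale
  shift <- runif(1, -1, 1) * config$intensity_shift
  v <- out$volume * scale + shift
  if (config$noise_sd > 0)
    v <- v + array(rnorm(length(v), 0, config$noise_sd), dim(v))
  list(volume = v, labels = out$labels)
}

#' Training configuration
#'
#' @param learning_rate AMSGrad learning rate (default 3e-4).
#' @param n_iterations Optimizer steps for the main training runs.
#' @param propagator_iterations Steps per propagator network during label
#'   propagation (its training set is tiny, so fewer steps suffice);
#'   defaults to `n_iterations`.
#' @param propagator_warm_start If `TRUE`, propagators of steps >= 2 start
#'   from the previous step's parameters and train for half the budget;
#'   the default `FALSE` re-initializes every step.
#' @param loss_weights Optional per-class weights; computed by
#'   [class_frequency_weights()] from the training labels when `NULL`.
#' @param augmentation An [augment_config()]; `NULL` disables augmentation.
#' @param validation_interval Every how many iterations to score the
#'   validation subjects (0 disables checkpoint selection).
#' @param seed Integer seed controlling initialization, sampling and
#'   augmentation.
#' @param beta1,beta2,epsilon AMSGrad moment parameters.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 3e-4, n_iterations = 600,
                         propagator_iterations = NULL,
                         propagator_warm_start = FALSE,
                         loss_weights = NULL,
                         augmentation = augment_config(),
                         validation_interval = 0, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(learning_rate > 0, n_iterations >= 1)
  structure(list(learning_rate = learning_rate,
                 n_iterations = as.integer(n_iterations),
                 propagator_iterations =
                   as.integer(propagator_iterations %||% n_iterations),
                 propagator_warm_start = isTRUE(propagator_warm_start),
                 loss_weights = loss_weights, augmentation = augmentation,
                 validation_interval = as.integer(validation_interval),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon),
            class = "train_config")
}

amsgrad_init <- function(params) {
  zero <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zero, v = zero, vhat = zero, t = 0L)
}

amsgrad_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc <- 1 - cfg$beta1^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
    params[[nm]] <- params[[nm]] - cfg$learning_rate * (state$m[[nm]] / bc) /
      (sqrt(state$vhat[[nm]]) + cfg$epsilon)
  }
  list(params = params, state = state)
}

# One weighted cross-entropy optimizer step on a single (volume, labels)
# pair.  Returns the updated model/optimizer state and the loss value.
train_step <- function(model, opt, volume, labels, class_w, cfg) {
  fw <- unet_forward(model, volume, train = TRUE)
  d <- dim(fw$logits); V <- prod(d[1:3]); nc <- d[4]
  p <- matrix(softmax_channels(fw$logits), V, nc)
  y <- as.integer(labels) + 1L
  wv <- class_w[y]
  wsum <- sum(wv)
  iy <- cbind(seq_len(V), y)
  loss <- -sum(wv * log(pmax(p[iy], 1e-12))) / wsum
  G <- p
  G[iy] <- G[iy] - 1
  G <- G * (wv / wsum)
  dim(G) <- d
  grads <- unet_backward(model, fw$cache, G)
  st <- amsgrad_step(model$params, grads, opt, cfg)
  model$params <- st$params
  list(model = model, opt = st$state, loss = loss)
}

# pooled label distribution, floored at one voxel per class
label_priors <- function(labelmaps, n_classes) {
  counts <- numeric(n_classes)
  for (lm in labelmaps)
    counts <- counts + tabulate(as.integer(lm) + 1L, nbins = n_classes)
  counts[counts == 0] <- 1
  counts / sum(counts)
}

subject_labeled_frames <- function(subject) {
  if (!is.null(subject$frames)) return(as.integer(subject$frames))
  which(!vapply(subject$labels, is.null, TRUE)) - 1L
}

mean_subject_dice <- function(model, subject, structures = heart_structures()) {
  fr <- subject_labeled_frames(subject)
  mean(vapply(fr, function(t) {
    pred <- predict_labels(model, subject$series$frames[[t + 1]])
    mean_dice(vapply(structures, function(s) {
      dice_score(pred == s, subject$labels[[t + 1]] == s)
    }, 1), n_expected = length(structures))
  }, 1))
}

#' Train the network on annotated frames
#'
#' The supervised training loop: per iteration one subject is drawn
#' uniformly, one of its labeled frames uniformly, the sample is augmented,
#' and a single AMSGrad step is taken on the weighted cross-entropy loss
#' over one whole 3D volume (batch of one).  Loss weights default to the
#' inverted class frequencies of the training labels.  Reproducible
#' bit-for-bit from `cfg$seed`.
#'
#' @param subjects List of subjects; each is a list with `series` (a
#'   normalized `cine_series`), `labels` (length-F list of label arrays,
#'   `NULL` where unlabeled) and optionally `frames` (0-based labeled frame
#'   indices; derived from `labels` when missing).
#' @param net A `unet_config`.
#' @param cfg A `train_config`.
#' @param n_iterations Override of `cfg$n_iterations` (used by the
#'   propagation loop).
#' @param validation Optional list of subjects scored every
#'   `cfg$validation_interval` iterations; the best-mean-Dice checkpoint is
#'   returned.
#' @param init_model Optional `unet_model` whose parameters seed the
#'   optimization (fresh optimizer state); by default a freshly
#'   initialized network is trained.
#' @return A `unet_model` with attribute `loss_trace` (numeric vector) and,
#'   when validation is used, `val_trace`.
#' @export
train_on_frames <- function(subjects, net, cfg, n_iterations = NULL,
                            validation = NULL, init_model = NULL) {
  stopifnot(inherits(net, "unet_config"), inherits(cfg, "train_config"))
  frames <- lapply(subjects, subject_labeled_frames)
  if (sum(lengths(frames)) == 0)
    stop("no labeled frames to train on", call. = FALSE)
  n_iter <- n_iterations %||% cfg$n_iterations

  maps <- unlist(lapply(subjects, function(s) {
    s$labels[subject_labeled_frames(s) + 1L]
  }), recursive = FALSE)
  class_w <- cfg$loss_weights %||% class_frequency_weights(maps,
                                                          net$n_classes)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  model <- build_unet(net, seed = sample.int(.Machine$integer.max, 1),
                      head_bias = log(label_priors(maps, net$n_classes)))
  if (!is.null(init_model)) {
    stopifnot(identical(init_model$config, net))
    model$params <- init_model$params
  }
  opt <- amsgrad_init(model$params)
  trace <- numeric(n_iter)
  val_trace <- NULL
  best <- -Inf; best_params <- NULL

  for (it in seq_len(n_iter)) {
    si <- sample.int(length(subjects), 1)
    fr <- frames[[si]]
    t <- fr[sample.int(length(fr), 1)]
    vol <- subjects[[si]]$series$frames[[t + 1]]
    lab <- subjects[[si]]$labels[[t + 1]]
    if (!is.null(cfg$augmentation)) {
      aug <- augment(vol, lab, cfg$augmentation,
                     draw_seed = sample.int(.Machine$integer.max, 1))
      vol <- aug$volume; lab <- aug$labels
    }
    st <- train_step(model, opt, vol, lab, class_w, cfg)
    model <- st$model; opt <- st$opt
    trace[it] <- st$loss
    if (!is.null(validation) && cfg$validation_interval > 0 &&
        (it %% cfg$validation_interval == 0 || it == n_iter)) {
      vd <- mean(vapply(validation, function(s) mean_subject_dice(model, s), 1))
      val_trace <- c(val_trace, vd)
      if (vd > best) { best <- vd; best_params <- model$params }
    }
  }
  if (!is.null(best_params)) model$params <- best_params
  attr(model, "loss_trace") <- trace
  attr(model, "val_trace") <- val_trace
  attr(model, "class_weights") <- class_w
  model
}

#' Frame accounting for the all-frames baseline
#'
#' Pure arithmetic of the two-stage baseline: with `n_subjects` cines of
#' `n_frames` frames and `n_labeled` manual annotations each, stage 2
#' predicts `n_subjects * (n_frames - n_labeled)` pseudo-label frames and
#' the pooled stage-3 training set has `n_subjects * n_frames` frames.
#'
#' @param n_subjects,n_frames,n_labeled Integers.
#' @return List with `n_pseudo` and `n_total`.
#' @export
frame_accounting <- function(n_subjects, n_frames, n_labeled = 2) {
  list(n_pseudo = as.integer(n_subjects * (n_frames - n_labeled)),
       n_total = as.integer(n_subjects * n_frames))
}

#' All-frames supervised baseline
#'
#' Stage 1 trains on the manually annotated ED/ES frames; stage 2 uses that
#' model to predict hard-argmax pseudo-labels for every unlabeled frame of
#' every training subject; stage 3 trains a re-initialized network on the
#' pooled set with uniform frame sampling and loss weights re-inverted over
#' all frames.  Unlike the propagation method, the pseudo-labels all come
#' from the single stage-1 model, so errors far from ED/ES are never
#' corrected.
#'
#' @inheritParams train_on_frames
#' @param stage1 Optionally a `unet_model` already trained on the annotated
#'   frames with the same configuration (the stage-1 training is exactly the
#'   ED/ES-supervised method, so an existing supervised model can stand in);
#'   trained from scratch when `NULL`.
#' @return The stage-3 `unet_model`, with attributes `accounting` (see
#'   [frame_accounting()]), `stage1_model` and `pseudo_labels` (per-subject
#'   length-F lists).
#' @export
train_all_frames_baseline <- function(subjects, net, cfg, validation = NULL,
                                      stage1 = NULL) {
  if (is.null(stage1))
    stage1 <- train_on_frames(subjects, net, cfg, validation = validation)
  F <- n_frames(subjects[[1]]$series)
  n_lab <- 0L
  pooled <- lapply(subjects, function(s) {
    labeled <- subject_labeled_frames(s)
    n_lab <<- n_lab + length(labeled)
    labs <- s$labels
    for (t in setdiff(seq_len(n_frames(s$series)) - 1L, labeled)) {
      labs[[t + 1]] <- predict_labels(stage1, s$series$frames[[t + 1]])
    }
    list(series = s$series, labels = labs)
  })
  acct <- list(n_pseudo = sum(vapply(subjects, function(s)
    n_frames(s$series), 1L)) - n_lab,
    n_total = sum(vapply(pooled, function(s) length(s$labels), 1L)))
  cfg3 <- cfg
  cfg3$seed <- cfg$seed + 1L
  cfg3$loss_weights <- NULL  # re-inverted over the pooled labels
  model <- train_on_frames(pooled, net, cfg3, validation = validation)
  attr(model, "accounting") <- acct
  attr(model, "stage1_model") <- stage1
  attr(model, "pseudo_labels") <- lapply(pooled, `[[`, "labels")
  model
}
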