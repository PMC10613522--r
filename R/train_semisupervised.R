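#' Certainty-weighted sampling policy
#'
#' Frames propagated later in the schedule carry less reliable labels, so
#' they are sampled less often during training.  The default level weight
#' is `w(i) = 2^(1-i)`: level-1 (manual ED/ES) frames weigh 1, level-2
#' frames 1/2, and so on — strictly decreasing in level.
#'
#' @param level_weights Either `NULL` (the default `2^(1-i)` rule) or a
#'   numeric vector of positive weights indexed by level, strictly
#'   decreasing.
#' @param frames_per_iteration Number of frames sampled (without
#'   replacement) from the chosen subject per training iteration
#'   (default 2).
#' @return A `sampling_policy` object.
#' @export
sampling_policy <- function(level_weights = NULL, frames_per_iteration = 2) {
  if (!is.null(level_weights)) {
    stopifnot(all(level_weights > 0))
    if (length(level_weights) > 1 && any(diff(level_weights) >= 0))
      stop("level weights must be strictly decreasing in level", call. = FALSE)
  }
  structure(list(level_weights = level_weights,
                 frames_per_iteration = as.integer(frames_per_iteration)),
            class = "sampling_policy")
}

policy_weight <- function(policy, level) {
  if (is.null(policy$level_weights)) 2^(1 - level)
  else policy$level_weights[level]
}

#' Per-frame sampling probabilities
#'
#' `p(t) = w(level(t)) / sum_u w(level(u))` over the frames of one subject.
#'
#' @param states A `frame_label_states` object (or list of states with a
#'   `level` entry).
#' @param policy A `sampling_policy`.
#' @return Numeric probability vector (sums to 1), ordered by frame.
#' @export
frame_probabilities <- function(states, policy = sampling_policy()) {
  if (length(states) == 0) stop("no frames", call. = FALSE)
  lv <- vapply(states, `[[`, 1, "level")
  w <- policy_weight(policy, lv)
  w / sum(w)
}

#' Sample one training batch
#'
#' Draws a subject uniformly, then `frames_per_iteration` distinct frames
#' from it according to [frame_probabilities()].  Uses (and advances) the
#' caller's RNG state, so batches are reproducible under `set.seed()`.
#'
#' @param dataset List of subjects, each a list with `series` and `states`
#'   (a `frame_label_states` covering every frame).
#' @param policy A `sampling_policy`.
#' @return List with `subject` (index) and `frames` (0-based frame
#'   indices).
#' @export
sample_batch <- function(dataset, policy = sampling_policy()) {
  si <- sample.int(length(dataset), 1)
  states <- dataset[[si]]$states
  if (length(states) < policy$frames_per_iteration)
    stop("subject has fewer frames than frames_per_iteration", call. = FALSE)
  p <- frame_probabilities(states, policy)
  pos <- sample.int(length(states), policy$frames_per_iteration,
                    replace = FALSE, prob = p)
  list(subject = si, positions = pos,
       frames = vapply(states[pos], function(st) as.integer(st$frame_index),
                       1L))
}

#' Certainty-weighted semi-supervised training
#'
#' Trains the final segmentation network on fully propagated subjects.
#' Loss weights are re-inverted class frequencies over ALL frames' labels
#' (manual and pseudo).  Per iteration a subject is drawn uniformly and
#' `frames_per_iteration` frames are drawn by certainty-weighted sampling;
#' each sampled frame is augmented and used for one single-volume AMSGrad
#' step, preserving the instance-normalization behaviour of batch size
#' one.
#'
#' @param dataset List of subjects, each a list with `series` (normalized
#'   `cine_series`) and `states` (complete `frame_label_states`).
#' @param net A `unet_config`.
#' @param cfg A `train_config`.
#' @param policy A `sampling_policy`.
#' @param validation Optional validation subjects (see [train_on_frames()]).
#' @return A `unet_model` with attribute `loss_trace`.
#' @export
train_semisupervised <- function(dataset, net, cfg,
                                 policy = sampling_policy(),
                                 validation = NULL) {
  stopifnot(inherits(net, "unet_config"), inherits(cfg, "train_config"),
            inherits(policy, "sampling_policy"))
  for (s in dataset) {
    if (any(vapply(s$states, function(st) is.null(st$label), TRUE)))
      stop("dataset contains unpropagated frames; run propagate_labels first",
           call. = FALSE)
  }

  maps <- unlist(lapply(dataset, function(s) lapply(s$states, `[[`, "label")),
                 recursive = FALSE)
  class_w <- cfg$loss_weights %||% class_frequency_weights(maps,
                                                           net$n_classes)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  model <- build_unet(net, seed = sample.int(.Machine$integer.max, 1),
                      head_bias = log(label_priors(maps, net$n_classes)))
  opt <- amsgrad_init(model$params)
  trace <- numeric(0)
  val_trace <- NULL
  best <- -Inf; best_params <- NULL

  for (it in seq_len(cfg$n_iterations)) {
    b <- sample_batch(dataset, policy)
    subj <- dataset[[b$subject]]
    for (pos in b$positions) {
      state <- subj$states[[pos]]
      vol <- subj$series$frames[[state$frame_index + 1L]]
      lab <- state$label
      if (!is.null(cfg$augmentation)) {
        aug <- augment(vol, lab, cfg$augmentation,
                       draw_seed = sample.int(.Machine$integer.max, 1))
        vol <- aug$volume; lab <- aug$labels
      }
      st <- train_step(model, opt, vol, lab, class_w, cfg)
      model <- st$model; opt <- st$opt
      trace <- c(trace, st$loss)
    }
    if (!is.null(validation) && cfg$validation_interval > 0 &&
        (it %% cfg$validation_interval == 0 || it == cfg$n_iterations)) {
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
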