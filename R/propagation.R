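#' Schedule configuration for cyclic label propagation
#'
#' @param n_frames Number of frames F in the cine.
#' @param ed_index,es_index 0-based ED/ES frame indices (the anchors).
#' @param k First-step radius: the k nearest cyclic neighbours on each side
#'   of both anchors are segmented by the first propagator (default 3).
#' @param step Per-iteration extension of the radius afterwards (default 2).
#' @return A `schedule_config` object.
#' @export
schedule_config <- function(n_frames, ed_index, es_index, k = 3, step = 2) {
  n_frames <- as.integer(n_frames); ed_index <- as.integer(ed_index)
  es_index <- as.integer(es_index); k <- as.integer(k); step <- as.integer(step)
  if (ed_index < 0 || ed_index >= n_frames || es_index < 0 ||
      es_index >= n_frames || ed_index == es_index)
    stop("invalid ED/ES indices for ", n_frames, " frames", call. = FALSE)
  stopifnot(k >= 1, step >= 1)
  structure(list(n_frames = n_frames, ed_index = ed_index,
                 es_index = es_index, k = k, step = step),
            class = "schedule_config")
}

cyclic_distance <- function(a, b, F) {
  d <- abs(a - b) %% F
  pmin(d, F - d)
}

#' Build the label-propagation schedule
#'
#' Frame indices are cyclic (the cardiac cycle wraps around).  Every
#' non-anchor frame is claimed by the anchor (ED or ES) at smaller cyclic
#' distance (ties go to ED).  Step 1 predicts all frames within distance
#' `k` of their anchor; step `s >= 2` predicts frames at distance in
#' `(k + (s-2)*step, k + (s-1)*step]`; steps continue until every frame is
#' assigned.  The propagator for step `s` trains on the anchors plus all
#' frames predicted by earlier steps.  Certainty levels: 1 for the anchors,
#' `1 + s` for frames predicted at step `s`.
#'
#' @param cfg A `schedule_config`.
#' @return A `propagation_schedule`: list with `steps` (each a list with
#'   0-based `train_frames` and `predict_frames`), `levels` (length-F
#'   integer vector) and `config`.
#' @export
build_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "schedule_config"))
  F <- cfg$n_frames
  all_t <- seq_len(F) - 1L
  d_ed <- cyclic_distance(all_t, cfg$ed_index, F)
  d_es <- cyclic_distance(all_t, cfg$es_index, F)
  dist <- pmin(d_ed, d_es)          # distance to the claiming anchor
  anchors <- c(cfg$ed_index, cfg$es_index)

  levels <- integer(F)
  levels[anchors + 1L] <- 1L
  steps <- list()
  labeled <- anchors
  s <- 0L
  while (length(labeled) < F) {
    s <- s + 1L
    r_lo <- if (s == 1L) 0L else cfg$k + (s - 2L) * cfg$step
    r_hi <- cfg$k + (s - 1L) * cfg$step
    pred <- all_t[dist > r_lo & dist <= r_hi & !(all_t %in% labeled)]
    if (length(pred) == 0 && r_hi >= max(dist)) break
    if (length(pred) > 0) {
      # order: ED-side ascending forward neighbours first, mirroring the
      # figure convention (+1, +2, ..., -1, -2, ... per anchor); purely
      # cosmetic since each step's set is trained/predicted jointly
      pred <- pred[order(d_es[pred + 1L] <= d_ed[pred + 1L], dist[pred + 1L])]
      steps[[s]] <- list(train_frames = sort(labeled),
                         predict_frames = pred)
      levels[pred + 1L] <- s + 1L
      labeled <- c(labeled, pred)
    }
  }
  structure(list(steps = steps, levels = levels, config = cfg),
            class = "propagation_schedule")
}

#' @export
print.propagation_schedule <- function(x, ...) {
  cat(sprintf("<propagation_schedule> F=%d, ED=%d, ES=%d, %d steps, %d levels\n",
              x$config$n_frames, x$config$ed_index, x$config$es_index,
              length(x$steps), max(x$levels)))
  for (s in seq_along(x$steps)) {
    cat(sprintf("  step %d: train %d frames -> predict {%s}\n", s,
                length(x$steps[[s]]$train_frames),
                paste(x$steps[[s]]$predict_frames, collapse = ",")))
  }
  invisible(x)
}

#' Propagate ED/ES labels to every frame of one subject
#'
#' Implements the iterative propagator loop: for each schedule step a
#' propagator network is trained on all currently labeled frames of this
#' subject, then predicts hard-argmax pseudo-labels for the step's frames,
#' which join the training set of the next step.  Each propagator trains
#' for `cfg$propagator_iterations` steps; with
#' `cfg$propagator_warm_start = TRUE` the networks of later steps continue
#' from the previous step's parameters at half the step budget, which at
#' small iteration budgets yields markedly better pseudo-labels than
#' re-initializing against a growing training set.
#'
#' @param series A normalized `cine_series`.
#' @param ed_label,es_label Integer label arrays for the ED/ES frames.
#' @param schedule A `propagation_schedule` consistent with the series.
#' @param net A `unet_config`.
#' @param cfg A `train_config`.
#' @return A `frame_label_states` object: length-F list of states, each
#'   with `frame_index` (0-based), `label`, `provenance`
#'   (`"manual"`/`"pseudo"`) and `level`.
#' @export
propagate_labels <- function(series, ed_label, es_label, schedule, net, cfg) {
  stopifnot(inherits(series, "cine_series"),
            inherits(schedule, "propagation_schedule"))
  F <- n_frames(series)
  sc <- schedule$config
  if (sc$n_frames != F || sc$ed_index != series$ed_index ||
      sc$es_index != series$es_index)
    stop("schedule inconsistent with the cine series", call. = FALSE)

  labels <- vector("list", F)
  labels[[sc$ed_index + 1L]] <- ed_label
  labels[[sc$es_index + 1L]] <- es_label

  prop <- NULL
  for (s in seq_along(schedule$steps)) {
    st <- schedule$steps[[s]]
    subj <- list(series = series, labels = labels, frames = st$train_frames)
    step_cfg <- cfg
    step_cfg$seed <- cfg$seed + s
    warm <- isTRUE(cfg$propagator_warm_start) && s > 1L
    prop <- train_on_frames(
      list(subj), net, step_cfg,
      n_iterations = if (warm) ceiling(cfg$propagator_iterations / 2)
                     else cfg$propagator_iterations,
      init_model = if (warm) prop else NULL)
    for (t in st$predict_frames) {
      labels[[t + 1L]] <- predict_labels(prop, series$frames[[t + 1L]])
    }
  }

  states <- lapply(seq_len(F) - 1L, function(t) {
    list(frame_index = t, label = labels[[t + 1L]],
         provenance = if (schedule$levels[t + 1L] == 1L) "manual" else "pseudo",
         level = schedule$levels[t + 1L])
  })
  structure(states, class = "frame_label_states")
}

#' Write propagated labels as NIfTI plus a YAML provenance file
#'
#' @param states A `frame_label_states` object.
#' @param dir Output directory.
#' @param spacing_mm Voxel spacing for the NIfTI headers.
#' @return `dir`, invisibly.
#' @export
write_propagated_labels <- function(states, dir, spacing_mm = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- lapply(states, function(st) {
    lm <- RNifti::asNifti(array(as.integer(st$label), dim = dim(st$label)),
                          pixdim = spacing_mm)
    RNifti::writeNifti(lm, label_file(dir, st$frame_index),
                       datatype = "int16")
    list(frame = st$frame_index, provenance = st$provenance,
         level = st$level)
  })
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
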