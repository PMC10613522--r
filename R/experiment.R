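#' Desk-scale experiment configuration
#'
#' Bundles every knob of an end-to-end phantom experiment: data generation,
#' network, training, propagation schedule and sampling policy.  The
#' defaults define the package's reference desk-scale study: 6 training and
#' 2 test phantom subjects of 24^3 voxels and 30 frames, a tiny two-level
#' U-Net, and 250 training iterations per stage.
#'
#' @param arm One of `"supervised"`, `"semi"`, `"all_frames"`.
#' @param n_train,n_test Numbers of phantom subjects.
#' @param phantom Base [phantom_config()] for the population.
#' @param net A [unet_config()].
#' @param train A [train_config()].
#' @param k,step Propagation schedule parameters (defaults 3 and 2).
#' @param policy A [sampling_policy()].
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional artifact directory.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(arm = c("semi", "supervised", "all_frames"),
                              n_train = 6, n_test = 2,
                              phantom = phantom_config(grid_size = 24),
                              net = unet_config(n_levels = 2,
                                                base_channels = 6),
                              train = desk_train_config(),
                              k = 3, step = 2,
                              policy = sampling_policy(),
                              seed = 1L, out_dir = NULL) {
  arm <- match.arg(arm)
  structure(list(arm = arm, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), phantom = phantom, net = net,
                 train = train, k = as.integer(k), step = as.integer(step),
                 policy = policy, seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Desk-scale training configuration
#'
#' The [train_config()] used by the phantom experiments: 250 optimizer
#' iterations per main stage, a 140-step budget for each subject's first
#' propagator with warm-started later steps, learning rate 2e-3, and mild
#' augmentation (no flips: the phantom population has a fixed situs, so
#' mirrored samples would only slow the tiny network down; on clinical CHD
#' data flips should be re-enabled).
#'
#' @param n_iterations,propagator_iterations Step budgets.
#' @param learning_rate AMSGrad learning rate.
#' @param seed Integer seed.
#' @param ... Passed on to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(n_iterations = 250,
                              propagator_iterations = 140,
                              learning_rate = 2e-3, seed = 1L, ...) {
  train_config(learning_rate = learning_rate,
               n_iterations = n_iterations,
               propagator_iterations = propagator_iterations,
               propagator_warm_start = TRUE,
               augmentation = augment_config(rotation_deg = 5, shear = 0.05,
                                             translation_vox = 2,
                                             intensity_scale = 0.05,
                                             intensity_shift = 0.05,
                                             noise_sd = 0.01,
                                             flip_lr_prob = 0,
                                             flip_ap_prob = 0),
               seed = seed, ...)
}

prepare_phantom_subjects <- function(n_train, n_test, phantom, seed) {
  pop <- phantom_population(n_train + n_test, phantom, seed = seed)
  subjects <- lapply(pop, function(p) {
    list(series = normalize_intensity(p$series), labels = p$labels,
         config = p$config)
  })
  list(train = subjects[seq_len(n_train)],
       test = subjects[n_train + seq_len(n_test)])
}

# ED/ES-only view of a fully labeled subject
edes_subject <- function(s) {
  keep <- c(s$series$ed_index, s$series$es_index)
  labs <- vector("list", n_frames(s$series))
  labs[keep + 1L] <- s$labels[keep + 1L]
  list(series = s$series, labels = labs, frames = keep)
}

# Mean Dice over all structures and all frames of the test subjects
test_mean_dice <- function(model, test_subjects) {
  mean(vapply(test_subjects, function(s) {
    preds <- lapply(s$series$frames, function(f) predict_labels(model, f))
    dt <- dice_table(preds, s$labels, subject = s$series$subject_id)
    mean(dt$dice)
  }, 1))
}

# Pseudo-label Dice against ground truth, per certainty level
pseudo_label_dice_by_level <- function(states_list, subjects) {
  rows <- list()
  for (i in seq_along(states_list)) {
    for (st in states_list[[i]]) {
      if (st$provenance != "pseudo") next
      dt <- dice_table(list(st$label),
                       list(subjects[[i]]$labels[[st$frame_index + 1L]]))
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, frame = st$frame_index, level = st$level,
        mean_dice = mean(dt$dice))
    }
  }
  do.call(rbind, rows)
}

#' Run one experimental arm end-to-end on phantom data
#'
#' Generates the phantom population, trains the configured arm
#' (ED/ES-only supervised, label-propagation + certainty-weighted
#' semi-supervised, or the all-frames pseudo-label baseline), evaluates it
#' on the held-out test subjects, and (when `out_dir` is set) writes the
#' model checkpoint, a metrics report (CSV + JSON) and a reproducibility
#' manifest.
#'
#' @param config An `experiment_config`.
#' @return List with `model`, `mean_test_dice`, `reports` (per test
#'   subject), `propagation` (level-wise pseudo-label Dice, for the semi
#'   arm) and `accounting` (for the all-frames arm).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  data <- prepare_phantom_subjects(config$n_train, config$n_test,
                                   config$phantom, config$seed)
  cfg <- config$train
  cfg$seed <- config$seed * 101L
  out <- list(arm = config$arm)

  if (config$arm == "supervised") {
    model <- train_on_frames(lapply(data$train, edes_subject), config$net, cfg)
  } else if (config$arm == "all_frames") {
    model <- train_all_frames_baseline(lapply(data$train, edes_subject),
                                       config$net, cfg)
    out$accounting <- attr(model, "accounting")
  } else {
    propagated <- lapply(seq_along(data$train), function(i) {
      s <- data$train[[i]]
      sched <- build_schedule(schedule_config(n_frames(s$series),
                                              s$series$ed_index,
                                              s$series$es_index,
                                              k = config$k,
                                              step = config$step))
      pcfg <- cfg
      pcfg$seed <- cfg$seed + 13L * i
      # translation-centric augmentation: the propagator must track the
      # heart's cyclic displacement, not memorize anchor-frame positions
      pcfg$augmentation <- augment_config(rotation_deg = 0, shear = 0,
                                          translation_vox = 2,
                                          intensity_scale = 0.05,
                                          intensity_shift = 0.05,
                                          noise_sd = 0.01,
                                          flip_lr_prob = 0,
                                          flip_ap_prob = 0)
      states <- propagate_labels(s$series,
                                 s$labels[[s$series$ed_index + 1L]],
                                 s$labels[[s$series$es_index + 1L]],
                                 sched, config$net, pcfg)
      list(series = s$series, states = states)
    })
    out$propagation <- pseudo_label_dice_by_level(
      lapply(propagated, `[[`, "states"), data$train)
    model <- train_semisupervised(propagated, config$net, cfg,
                                  policy = config$policy)
  }

  out$model <- model
  out$mean_test_dice <- test_mean_dice(model, data$test)
  out$reports <- lapply(data$test, function(s) {
    preds <- lapply(s$series$frames, function(f) predict_labels(model, f))
    metrics_report(preds, s$labels, s$series)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(config$out_dir, "model.rds"))
    dice_all <- do.call(rbind, lapply(out$reports, `[[`, "dice"))
    utils::write.csv(dice_all, file.path(config$out_dir, "dice.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(arm = config$arm, seed = config$seed,
           mean_test_dice = out$mean_test_dice,
           function_indices = lapply(out$reports, `[[`, "function_indices")),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest <- list(package = "cineheart",
                     version = as.character(utils::packageVersion("cineheart")),
                     arm = config$arm, seed = config$seed,
                     n_train = config$n_train, n_test = config$n_test,
                     grid_size = config$phantom$grid_size,
                     n_frames = config$phantom$n_frames,
                     net = unclass(config$net),
                     n_iterations = config$train$n_iterations,
                     propagator_iterations = config$train$propagator_iterations,
                     learning_rate = config$train$learning_rate,
                     k = config$k, step = config$step)
    if (!is.null(out$accounting)) manifest$accounting <- out$accounting
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  out
}

#' Compare the three training arms on one phantom split
#'
#' Runs the ED/ES-only supervised arm, the semi-supervised arm and the
#' all-frames baseline on the same phantom population and seed, and
#' returns their mean test Dice (over 8 structures, all frames of the
#' held-out subjects) plus the level-wise pseudo-label quality of the
#' propagation.  This is the package's desk-scale restatement of the
#' clinical comparison.
#'
#' @param seed Master seed for the split.
#' @param arms Which arms to run.  The supervised model doubles as stage 1
#'   of the all-frames baseline (they are the same training), so running
#'   both costs one training less than two independent runs.
#' @param ... Overrides passed to [experiment_config()].
#' @return List with `dice` (named numeric per arm) and `propagation`
#'   (data.frame of per-frame pseudo-label Dice with certainty levels).
#' @export
compare_arms <- function(seed = 1L,
                         arms = c("supervised", "semi", "all_frames"), ...) {
  config <- experiment_config(arm = "semi", seed = seed, ...)
  data <- prepare_phantom_subjects(config$n_train, config$n_test,
                                   config$phantom, config$seed)
  cfg <- config$train
  cfg$seed <- config$seed * 101L
  res <- list(dice = numeric(0), propagation = NULL)
  supervised <- NULL

  if (any(c("supervised", "all_frames") %in% arms)) {
    supervised <- train_on_frames(lapply(data$train, edes_subject),
                                  config$net, cfg)
  }
  if ("supervised" %in% arms)
    res$dice[["supervised"]] <- test_mean_dice(supervised, data$test)

  if ("semi" %in% arms) {
    propagated <- lapply(seq_along(data$train), function(i) {
      s <- data$train[[i]]
      sched <- build_schedule(schedule_config(n_frames(s$series),
                                              s$series$ed_index,
                                              s$series$es_index,
                                              k = config$k,
                                              step = config$step))
      pcfg <- cfg
      pcfg$seed <- cfg$seed + 13L * i
      # translation-centric augmentation: the propagator must track the
      # heart's cyclic displacement, not memorize anchor-frame positions
      pcfg$augmentation <- augment_config(rotation_deg = 0, shear = 0,
                                          translation_vox = 2,
                                          intensity_scale = 0.05,
                                          intensity_shift = 0.05,
                                          noise_sd = 0.01,
                                          flip_lr_prob = 0,
                                          flip_ap_prob = 0)
      states <- propagate_labels(s$series,
                                 s$labels[[s$series$ed_index + 1L]],
                                 s$labels[[s$series$es_index + 1L]],
                                 sched, config$net, pcfg)
      list(series = s$series, states = states)
    })
    res$propagation <- pseudo_label_dice_by_level(
      lapply(propagated, `[[`, "states"), data$train)
    semi <- train_semisupervised(propagated, config$net, cfg,
                                 policy = config$policy)
    res$dice[["semi"]] <- test_mean_dice(semi, data$test)
  }

  if ("all_frames" %in% arms) {
    baseline <- train_all_frames_baseline(lapply(data$train, edes_subject),
                                          config$net, cfg,
                                          stage1 = supervised)
    res$dice[["all_frames"]] <- test_mean_dice(baseline, data$test)
  }
  res
}
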