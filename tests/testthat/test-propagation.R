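test_that("the 30-frame reference schedule reproduces the published frame plan", {
  sched <- build_schedule(schedule_config(30, ed_index = 28, es_index = 13,
                                          k = 3, step = 2))
  expect_length(sched$steps, 3)
  expect_setequal(sched$steps[[1]]$predict_frames,
                  c(29, 0, 1, 27, 26, 25, 14, 15, 16, 12, 11, 10))
  expect_length(sched$steps[[1]]$predict_frames, 12)
  expect_setequal(sched$steps[[2]]$predict_frames,
                  c(2, 3, 24, 23, 17, 18, 9, 8))
  expect_setequal(sched$steps[[3]]$predict_frames,
                  c(4, 5, 22, 21, 19, 20, 7, 6))
  # four certainty sets: anchors + one per step
  expect_equal(sort(unique(sched$levels)), 1:4)
  expect_equal(sum(sched$levels == 1), 2)
  expect_equal(sum(sched$levels == 2), 12)
  expect_equal(sum(sched$levels == 3), 8)
  expect_equal(sum(sched$levels == 4), 8)
  # the first propagator trains on the anchors only
  expect_setequal(sched$steps[[1]]$train_frames, c(28, 13))
})

test_that("a short cycle with k=1 resolves in a single step", {
  sched <- build_schedule(schedule_config(4, ed_index = 0, es_index = 2,
                                          k = 1, step = 2))
  expect_length(sched$steps, 1)
  expect_setequal(sched$steps[[1]]$predict_frames, c(1, 3))
  expect_equal(sort(unique(sched$levels)), 1:2)
})

test_that("schedules partition the cycle for arbitrary geometries", {
  set.seed(8)
  for (rep in 1:25) {
    F <- sample(4:40, 1)
    ed <- sample(0:(F - 1), 1)
    es <- sample(setdiff(0:(F - 1), ed), 1)
    k <- sample(1:4, 1)
    step <- sample(1:3, 1)
    sched <- build_schedule(schedule_config(F, ed, es, k, step))
    pred <- unlist(lapply(sched$steps, `[[`, "predict_frames"))
    # disjoint predict sets covering everything but the anchors
    expect_equal(length(pred), length(unique(pred)))
    expect_setequal(c(pred, ed, es), 0:(F - 1))
    expect_false(ed %in% pred)
    expect_false(es %in% pred)
    # monotone certainty in cyclic distance from the nearest anchor
    d <- pmin(cineheart:::cyclic_distance(0:(F - 1), ed, F),
              cineheart:::cyclic_distance(0:(F - 1), es, F))
    expect_true(all(diff(sched$levels[order(d)]) >= 0))
    # train-set growth: each step trains on anchors + all earlier predictions
    n_train <- vapply(sched$steps, function(s) length(s$train_frames), 1L)
    n_pred <- vapply(sched$steps, function(s) length(s$predict_frames), 1L)
    if (length(sched$steps) > 1) {
      expect_equal(n_train[-1], (2L + cumsum(n_pred))[-length(n_pred)])
    }
    expect_equal(n_train[1], 2L)
  }
})

test_that("ties between anchors are claimed by ED", {
  # F=6, ed=0, es=3: frames 1,2,4,5 .. distances to ED/ES: frame 1 -> (1,2),
  # frame 2 -> (2,1); no tie.  F=4, ed=0, es=2: frames 1,3 tie at distance 1.
  sched <- build_schedule(schedule_config(4, 0, 2, k = 1, step = 1))
  expect_setequal(sched$steps[[1]]$predict_frames, c(1, 3))
  # both tied frames must still be predicted exactly once
  expect_equal(sum(sched$levels == 2), 2)
})

test_that("propagation on a zero-motion phantom cannot degrade pseudo-labels", {
  # frozen heart, no noise: all frames are bit-identical, so every
  # pseudo-label is exactly the propagator's own prediction of the anchor
  # anatomy and quality cannot vary with cyclic distance
  cfg_ph <- phantom_config(grid_size = 16, n_frames = 6,
                           motion_amplitude = 0, noise_sd = 0, seed = 19)
  ph <- generate_phantom(cfg_ph)
  s <- normalize_intensity(ph$series)
  sched <- build_schedule(schedule_config(6, s$ed_index, s$es_index,
                                          k = 1, step = 1))
  expect_length(sched$steps, 1)
  cfg <- train_config(learning_rate = 2e-3, n_iterations = 400,
                      propagator_iterations = 400, augmentation = NULL,
                      seed = 5)
  states <- propagate_labels(s, ph$labels[[s$ed_index + 1]],
                             ph$labels[[s$es_index + 1]], sched,
                             unet_config(n_levels = 2, base_channels = 4),
                             cfg)
  expect_s3_class(states, "frame_label_states")
  expect_length(states, 6)
  expect_equal(sum(vapply(states, `[[`, "", "provenance") == "manual"), 2)

  dice_by_frame <- vapply(states, function(st) {
    mean(dice_table(list(st$label), list(ph$labels[[st$frame_index + 1]]))$dice)
  }, 1)
  pseudo <- vapply(states, `[[`, "", "provenance") == "pseudo"
  # identical inputs give identical predictions: no spread across frames
  expect_lte(diff(range(dice_by_frame[pseudo])), 0.02)
  expect_true(all(dice_by_frame[pseudo] > 0.6))
})

test_that("propagated states carry the schedule's levels and full coverage", {
  cfg_ph <- phantom_config(grid_size = 16, n_frames = 6, seed = 23)
  ph <- generate_phantom(cfg_ph)
  s <- normalize_intensity(ph$series)
  sched <- build_schedule(schedule_config(6, s$ed_index, s$es_index,
                                          k = 1, step = 1))
  cfg <- train_config(learning_rate = 1e-3, n_iterations = 60,
                      propagator_iterations = 60, augmentation = NULL,
                      seed = 6)
  states <- propagate_labels(s, ph$labels[[s$ed_index + 1]],
                             ph$labels[[s$es_index + 1]], sched, tiny_net(),
                             cfg)
  expect_false(any(vapply(states, function(st) is.null(st$label), TRUE)))
  expect_equal(vapply(states, `[[`, 1L, "level"), sched$levels)

  # provenance file round-trip
  dir <- withr::local_tempdir()
  write_propagated_labels(states, dir, s$spacing_mm)
  prov <- yaml::read_yaml(file.path(dir, "provenance.yaml"))
  expect_length(prov, 6)
  expect_equal(vapply(prov, `[[`, 1L, "level"), sched$levels)

  # schedule/series mismatch is rejected
  bad <- build_schedule(schedule_config(8, 0, 4, k = 1, step = 1))
  expect_error(propagate_labels(s, ph$labels[[1]], ph$labels[[2]], bad,
                                tiny_net(), cfg), "inconsistent")
})
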