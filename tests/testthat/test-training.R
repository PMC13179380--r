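test_that("cosine schedule hits its endpoints, midpoint, and symmetry", {
  cfg <- schedule_config()
  expect_equal(lr_at_epoch(0, cfg), 1e-3)
  expect_equal(lr_at_epoch(100, cfg), 1e-6)
  expect_equal(lr_at_epoch(50, cfg), (1e-3 + 1e-6) / 2) # 5.005e-4
  expect_equal(lr_at_epoch(50, cfg), 5.005e-4)
  for (t in c(0, 10, 33, 50)) {
    expect_equal(lr_at_epoch(t, cfg) + lr_at_epoch(100 - t, cfg),
                 cfg$eta_min + cfg$eta_max)
  }
  expect_error(lr_at_epoch(101, cfg), class = "stressfuse_schedule_error")
  expect_error(schedule_config(eta_min = 1e-2, eta_max = 1e-3),
               class = "stressfuse_error")
})

test_that("label-smoothed loss: uniform prediction, perfect limit, L2 term", {
  cfg <- loss_config(smoothing = 0.1, l2_lambda = 0)
  for (lab in 1:3) {
    expect_equal(smoothed_loss(rep(1 / 3, 3), lab, cfg), log(3),
                 tolerance = 1e-12)
  }
  cfg0 <- loss_config(smoothing = 0, l2_lambda = 0)
  expect_equal(smoothed_loss(c(1, 0, 0), 1, cfg0), 0, tolerance = 1e-9)

  cfgL <- loss_config(l2_lambda = 0.5)
  base <- smoothed_loss(c(0.7, 0.2, 0.1), 1, cfgL)
  expect_equal(smoothed_loss(c(0.7, 0.2, 0.1), 1, cfgL,
                             weights = numeric(10)), base)
  expect_gt(smoothed_loss(c(0.7, 0.2, 0.1), 1, cfgL, weights = rep(1, 4)),
            base)
  expect_error(smoothed_loss(c(0.5, 0.2, 0.2), 1),
               class = "stressfuse_prob_error")
})

test_that("smoothed CE is bounded below by the smoothed-target entropy", {
  cfg <- loss_config(smoothing = 0.1, l2_lambda = 0)
  y <- stressfuse:::smooth_targets(1, cfg)[1, ]
  entropy <- -sum(y * log(y))
  set.seed(6)
  for (k in 1:50) {
    p <- stats::runif(3)
    p <- p / sum(p)
    expect_gte(smoothed_loss(p, 1, cfg), entropy - 1e-12)
  }
  expect_equal(smoothed_loss(y, 1, cfg), entropy, tolerance = 1e-12)
})

test_that("augmentation: identity config, degenerate noise, warp arithmetic", {
  p <- fixture_profile()
  seg <- generate_eeg(p, condition_presets()$baseline, 10)
  off <- augmentation_config(noise_sigma_frac = 0, warp_range = c(1, 1),
                             scale_range = c(1, 1),
                             channel_shuffle = FALSE)
  expect_equal(augment(seg, off, seed = 3)$data, seg$data)

  zero <- matrix(0, 1, 7000)
  noise_only <- augmentation_config(noise_sigma_frac = 0.05,
                                    warp_range = c(1, 1),
                                    scale_range = c(1, 1),
                                    channel_shuffle = FALSE)
  az <- augment(zero, noise_only, seed = 3, modality = "ECG")
  expect_equal(stats::sd(az), 0) # 0.05 x sd(0) = 0

  warp_fixed <- augmentation_config(noise_sigma_frac = 0,
                                    warp_range = c(1.1, 1.1),
                                    scale_range = c(1, 1),
                                    channel_shuffle = FALSE)
  aw <- augment(seg, warp_fixed, seed = 3)
  expect_equal(attr(aw, "warp_resample_length"), 6364) # round(7000/1.1)
  expect_equal(ncol(aw$data), 7000) # length restored
})

test_that("channel shuffling only moves mutually non-adjacent channels", {
  p <- fixture_profile()
  seg <- generate_eeg(p, condition_presets()$baseline, 10)
  adj <- montage_adjacency()
  shuf <- augmentation_config(noise_sigma_frac = 0, warp_range = c(1, 1),
                              scale_range = c(1, 1),
                              channel_shuffle = TRUE)
  for (s in 1:10) {
    a <- augment(seg, shuf, seed = s)
    moved <- which(vapply(1:14, function(k) {
      !identical(a$data[k, ], seg$data[k, ])
    }, logical(1)))
    if (length(moved) >= 2) {
      pairs <- utils::combn(moved, 2)
      expect_false(any(adj[t(pairs)]))
    }
  }
})

test_that("splits reproduce 28/4/3 and partition subjects deterministically", {
  ids <- sprintf("P%02d", 1:35)
  plan <- make_split(ids, c(0.8, 0.1, 0.1), seed = 5)
  expect_equal(as.integer(table(plan$split)[c("train", "val", "test")]),
               c(28L, 4L, 3L))
  expect_setequal(plan$subject_id, ids)
  expect_equal(anyDuplicated(plan$subject_id), 0)

  plan2 <- make_split(ids, c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(plan, plan2)
  plan3 <- make_split(ids, c(0.8, 0.1, 0.1), seed = 6)
  expect_false(identical(plan$subject_id, plan3$subject_id))
  expect_equal(table(plan3$split), table(plan$split))

  expect_error(make_split(ids, c(0.7, 0.1, 0.1)),
               class = "stressfuse_split_error")

  # split leakage: subject sets are pairwise disjoint by construction
  for (w in c("train", "val", "test")) {
    others <- setdiff(c("train", "val", "test"), w)
    for (o in others) {
      expect_length(intersect(split_subjects(plan, w),
                              split_subjects(plan, o)), 0)
    }
  }
})

test_that("training decreases the loss and logs the schedule", {
  prep <- easy_prep()
  plan <- make_split(unique(prep$subject_ids), seed = 1)
  passes <- 0
  for (seed in 1:3) {
    m <- build_full_model(model_config(profile = "test", seed = seed))
    fit <- train_model(m, prep, plan,
                       training_config(epochs = 5, seed = seed))
    expect_equal(fit$history$lr[1],
                 lr_at_epoch(0, schedule_config(t_max = 5)))
    drops <- sum(diff(fit$history$train_loss) < 0)
    if (drops >= 3 &&
        fit$history$train_loss[5] < fit$history$train_loss[1]) {
      passes <- passes + 1
    }
  }
  expect_gte(passes, 2)
})

test_that("augmentation is confined to training subjects", {
  coh <- generate_cohort(4, per_condition_segments = 1, seed = 11,
                         ecg_duration = 20)
  subs <- cohort_subjects(coh)
  aug <- augment_cohort(coh, subjects = subs[1:2], copies = 1, seed = 2)
  calls <- attr(aug, "augment_calls")
  expect_true(all(calls[subs[1:2]] > 0))
  expect_true(all(calls[subs[3:4]] == 0))
  n_aug <- sum(vapply(aug$records, function(r) isTRUE(r$augmented),
                      logical(1)))
  expect_equal(n_aug, 2 * 3) # 2 subjects x 3 conditions x 1 copy

  # an augmented record attributed to a validation subject is rejected
  prep <- easy_prep()
  prep_bad <- prep
  plan <- make_split(unique(prep$subject_ids), seed = 1)
  val_subj <- split_subjects(plan, "val")[1]
  prep_bad$augmented[which(prep_bad$subject_ids == val_subj)[1]] <- TRUE
  m <- build_full_model(model_config(profile = "test", seed = 1))
  expect_error(train_model(m, prep_bad, plan,
                           training_config(epochs = 1)),
               class = "stressfuse_leakage_error")
})
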