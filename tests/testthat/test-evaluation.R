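test_that("metrics match hand computations and a brute-force oracle", {
  perfect <- compute_metrics(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)

  # confusion [[5,0,0],[0,0,5],[0,0,5]]: baseline perfect, stress always
  # predicted as amusement, amusement correct
  labels <- rep(1:3, each = 5)
  preds <- c(rep(1, 5), rep(3, 5), rep(3, 5))
  rep_ <- compute_metrics(preds, labels)
  expect_equal(rep_$accuracy, 10 / 15)
  expect_equal(unname(rep_$per_class["stress", "recall"]), 0)
  expect_equal(unname(rep_$per_class["stress", "precision"]), 0)

  # order invariance
  o <- sample(15)
  rep_o <- compute_metrics(preds[o], labels[o])
  expect_equal(rep_o$confusion, rep_$confusion)
  expect_equal(rep_o$macro_f1, rep_$macro_f1)

  expect_error(compute_metrics(integer(0), integer(0)),
               class = "stressfuse_metric_error")
  expect_error(compute_metrics(c("happy"), c("stress")),
               class = "stressfuse_metric_error")
  # "rest" is accepted as the baseline alias
  expect_equal(compute_metrics("rest", "baseline")$accuracy, 1)

  # brute-force oracle over random prediction sets
  set.seed(13)
  for (k in 1:100) {
    n <- sample(5:40, 1)
    y <- sample(1:3, n, replace = TRUE)
    p <- sample(1:3, n, replace = TRUE)
    r <- compute_metrics(p, y)
    acc <- sum(p == y) / n
    expect_equal(r$accuracy, acc, tolerance = 1e-12)
    f1s <- vapply(1:3, function(cl) {
      tp <- sum(p == cl & y == cl)
      prec <- if (sum(p == cl) == 0) 0 else tp / sum(p == cl)
      rec <- if (sum(y == cl) == 0) 0 else tp / sum(y == cl)
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1))
    expect_equal(r$macro_f1, mean(f1s), tolerance = 1e-12)
  }
})

test_that("eval reports serialize losslessly through JSON", {
  skip_if_not_installed("jsonlite")
  set.seed(14)
  r <- compute_metrics(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(r), f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$accuracy, r$accuracy, tolerance = 1e-12)
  expect_equal(back$macro_f1, r$macro_f1, tolerance = 1e-12)
  expect_equal(matrix(unlist(back$confusion), 3), unname(r$confusion))
})

test_that("ablation specs parse to model configurations", {
  expect_equal(ablation_spec("full")$variant, "full")
  expect_equal(ablation_spec("late_fusion_average")$variant,
               "late_fusion_average")
  sp <- ablation_spec("eeg_only_EfficientNetB0")
  expect_equal(sp$variant, "eeg_only")
  expect_equal(sp$eeg_backbone, "EfficientNetB0")
  spd <- ablation_spec("drop_ResNeXt50_32x4d")
  expect_equal(spd$variant, "drop_backbone")
  expect_equal(spd$drop, "ResNeXt50_32x4d")
  expect_error(ablation_spec("eeg_only_LeNet"),
               class = "stressfuse_variant_error")
})

test_that("cohorts round-trip through the portable container", {
  coh <- generate_cohort(3, per_condition_segments = 1, seed = 21,
                         ecg_duration = 15)
  dir <- file.path(tempdir(), "cohort_rt")
  save_cohort(coh, dir)
  back <- load_cohort(dir)
  expect_length(back$records, length(coh$records))
  for (i in seq_along(coh$records)) {
    expect_equal(back$records[[i]]$eeg$data, unname(coh$records[[i]]$eeg$data),
                 tolerance = 1e-12)
    expect_equal(back$records[[i]]$ecg$data, unname(coh$records[[i]]$ecg$data),
                 tolerance = 1e-12)
    expect_identical(back$records[[i]]$label, coh$records[[i]]$label)
    expect_identical(back$records[[i]]$subject_id,
                     coh$records[[i]]$subject_id)
    expect_equal(back$records[[i]]$r_indices, coh$records[[i]]$r_indices)
  }
  unlink(dir, recursive = TRUE)
})

test_that("the loader validates channels and rejects unknown labels", {
  coh <- generate_cohort(3, per_condition_segments = 1, seed = 22,
                         ecg_duration = 15)
  dir <- file.path(tempdir(), "cohort_bad")
  save_cohort(coh, dir)

  # corrupt one EEG file down to 13 channels -> itemized error
  mf <- utils::read.csv(file.path(dir, "manifest.csv"))
  eeg_file <- mf$file[mf$modality == "EEG"][1]
  df <- utils::read.csv(file.path(dir, eeg_file), check.names = FALSE)
  utils::write.csv(df[, 1:13], file.path(dir, eeg_file),
                   row.names = FALSE)
  err <- tryCatch(load_cohort(dir), error = function(e) e)
  expect_s3_class(err, "stressfuse_load_error")
  expect_match(conditionMessage(err), "13")
  expect_match(conditionMessage(err), eeg_file)

  # restore, then poison one record's label -> rejected with a report
  utils::write.csv(df, file.path(dir, eeg_file), row.names = FALSE)
  mf$label[mf$record == 2] <- "boredom"
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  back <- load_cohort(dir)
  rep_ <- attr(back, "load_report")
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$record, 2)
  expect_length(back$records, length(coh$records) - 1)
  unlink(dir, recursive = TRUE)
})

test_that("cross-cohort evaluation reuses the training standardizers", {
  skip_if_not_installed("jsonlite") # keep runtime symmetrical across files
  coh_a <- generate_cohort(4, per_condition_segments = 1, seed = 31,
                           difficulty = "easy")
  coh_b <- generate_cohort(3, per_condition_segments = 1, seed = 32,
                           difficulty = "easy")
  rep_ <- cross_cohort_eval(coh_a, coh_b,
                            train_config = training_config(epochs = 2))
  expect_s3_class(rep_, "eval_report")
  expect_equal(attr(rep_, "standardizer_provenance"), "train")
  expect_equal(rep_$n, length(coh_b$records))
  expect_equal(sum(rep_$confusion), rep_$n)
})
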