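normalize_labels <- function(x) {
  x <- tolower(as.character(x))
  x[x == "rest"] <- "baseline" # "Rest" is the head's alias for baseline
  x
}

#' Classification metrics report
#'
#' Confusion matrix (rows = true condition, columns = predicted), overall
#' accuracy, per-class precision/recall/F1 with 0/0 defined as 0, and both
#' macro (unweighted class mean, the headline) and support-weighted
#' averages.
#'
#' @param predictions,labels Aligned vectors of condition labels (factor,
#'   character, or 1-based integer index into baseline/stress/amusement;
#'   "rest" is accepted as an alias for baseline).
#' @return An object of class `eval_report`.
#' @export
compute_metrics <- function(predictions, labels) {
  sf_assert(length(predictions) == length(labels) && length(labels) > 0,
            "predictions and labels must be aligned and non-empty",
            class = "stressfuse_metric_error")
  lv <- condition_levels()
  to_factor <- function(x) {
    if (is.numeric(x)) factor(lv[x], levels = lv)
    else factor(normalize_labels(x), levels = lv)
  }
  p <- to_factor(predictions)
  y <- to_factor(labels)
  sf_assert(!any(is.na(p)) && !any(is.na(y)),
            "labels outside the condition vocabulary",
            class = "stressfuse_metric_error")
  confusion <- table(true = y, predicted = p)
  acc <- sum(diag(confusion)) / sum(confusion)
  per_class <- t(vapply(lv, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1,
      support = sum(confusion[cl, ]))
  }, numeric(4)))
  w <- per_class[, "support"] / sum(per_class[, "support"])
  structure(list(
    confusion = unclass(confusion),
    accuracy = acc,
    per_class = per_class,
    macro_precision = mean(per_class[, "precision"]),
    macro_recall = mean(per_class[, "recall"]),
    macro_f1 = mean(per_class[, "f1"]),
    weighted_precision = sum(w * per_class[, "precision"]),
    weighted_recall = sum(w * per_class[, "recall"]),
    weighted_f1 = sum(w * per_class[, "f1"]),
    n = length(y)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d  accuracy %.3f  macro P/R/F1 %.3f/%.3f/%.3f\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  if (!is.null(x$alpha_summary)) {
    cat("mean alpha_EEG by condition:\n")
    print(round(x$alpha_summary, 3))
  }
  invisible(x)
}

#' Evaluate a trained model on a subset of a prepared dataset
#'
#' @param model A trained `stress_model`.
#' @param data Prepared tensors (already standardized with the training
#'   standardizers).
#' @param idx Row indices to evaluate (default all).
#' @return An `eval_report` with an `alpha_summary` field (mean and SD of
#'   alpha_EEG per condition) when the model exposes gate weights.
#' @export
evaluate_model <- function(model, data, idx = seq_along(data$labels)) {
  out <- model_forward(model, list(
    scalogram = data$scalogram[idx, , , , drop = FALSE],
    ecg = data$ecg[idx, , , drop = FALSE],
    hrv = data$hrv[idx, , drop = FALSE]), training = FALSE)
  rep <- compute_metrics(max.col(out$probs), data$labels[idx])
  if (!is.null(out$alpha_eeg)) {
    rep$alpha_summary <- do.call(rbind, lapply(
      condition_levels(), function(cl) {
        sel <- data$labels[idx] == cl
        c(mean = mean(out$alpha_eeg[sel]), sd = stats::sd(out$alpha_eeg[sel]))
      }))
    rownames(rep$alpha_summary) <- condition_levels()
  }
  rep$predictions <- max.col(out$probs)
  rep
}

#' Parse an ablation variant name
#'
#' Accepts: full, no_attention, late_fusion_average, early_fusion,
#' ecg_only_hrv, ecg_only_raw, eeg_only_<Backbone>, drop_<Backbone>.
#'
#' @param variant Variant string.
#' @return List with `variant`, `eeg_backbone`, `drop` suitable for
#'   [model_config()].
#' @export
ablation_spec <- function(variant) {
  if (grepl("^eeg_only_", variant)) {
    bb <- sub("^eeg_only_", "", variant)
    sf_assert(bb %in% backbone_names(),
              sprintf("unknown backbone in variant '%s'", variant),
              class = "stressfuse_variant_error")
    return(list(variant = "eeg_only", eeg_backbone = bb, drop = NULL))
  }
  if (grepl("^drop_", variant)) {
    bb <- sub("^drop_", "", variant)
    sf_assert(bb %in% backbone_names(),
              sprintf("unknown backbone in variant '%s'", variant),
              class = "stressfuse_variant_error")
    return(list(variant = "drop_backbone", eeg_backbone = "VGG16",
                drop = bb))
  }
  list(variant = variant, eeg_backbone = "VGG16", drop = NULL)
}

#' Train and evaluate one ablation variant on a synthetic cohort
#'
#' Builds the requested model variant, trains it on the cohort's training
#' subjects, and reports metrics on the held-out test subjects.
#'
#' @param variant Variant name; see [ablation_spec()].
#' @param cohort A `stress_cohort`.
#' @param profile A [model_profile()] (test profile by default).
#' @param train_config A [training_config()].
#' @param split_seed Seed for the subject split.
#' @param seed Seed for weight initialization.
#' @param prepared Optional precomputed [prepare_cohort()] tensors (avoids
#'   re-running the signal pipeline when comparing variants on one cohort).
#' @return An `eval_report` with attributes `history` and `model`.
#' @export
run_ablation <- function(variant, cohort, profile = model_profile("test"),
                         train_config = training_config(),
                         split_seed = 1L, seed = 1L, prepared = NULL) {
  sp <- ablation_spec(variant)
  data <- prepared %||% prepare_cohort(cohort, profile)
  plan <- make_split(unique(data$subject_ids), seed = split_seed)
  cfg <- model_config(profile = profile, variant = sp$variant,
                      eeg_backbone = sp$eeg_backbone, drop = sp$drop,
                      seed = seed)
  model <- build_full_model(cfg)
  fit <- train_model(model, data, plan, train_config)
  test_idx <- which(data$subject_ids %in% split_subjects(plan, "test") &
                      !data$augmented)
  data_std <- apply_input_standardizers(data, fit$standardizers)
  rep <- evaluate_model(fit$model, data_std, test_idx)
  attr(rep, "history") <- fit$history
  attr(rep, "model") <- fit$model
  attr(rep, "plan") <- plan
  rep
}

#' Cross-cohort evaluation
#'
#' Trains on every subject of the training cohort and evaluates on every
#' subject of the test cohort, applying the training cohort's input
#' standardizers without refitting.
#'
#' @param train_cohort,test_cohort `stress_cohort` objects sharing the
#'   condition vocabulary.
#' @param profile A [model_profile()].
#' @param train_config A [training_config()].
#' @param seed Weight-initialization seed.
#' @param prepared_train,prepared_test Optional precomputed tensors.
#' @return An `eval_report`; `attr(, "standardizer_provenance")` records
#'   that the standardizers came from the training cohort.
#' @export
cross_cohort_eval <- function(train_cohort, test_cohort,
                              profile = model_profile("test"),
                              train_config = training_config(),
                              seed = 1L, prepared_train = NULL,
                              prepared_test = NULL) {
  data_a <- prepared_train %||% prepare_cohort(train_cohort, profile)
  data_b <- prepared_test %||% prepare_cohort(test_cohort, profile)
  sf_assert(identical(levels(data_a$labels), levels(data_b$labels)),
            "cohorts must share one label vocabulary",
            class = "stressfuse_label_error")
  subs <- unique(data_a$subject_ids)
  plan <- structure(data.frame(subject_id = subs, split = "train",
                               stringsAsFactors = FALSE),
                    class = c("split_plan", "data.frame"))
  model <- build_full_model(model_config(profile = profile,
                                         variant = "full", seed = seed))
  fit <- train_model(model, data_a, plan, train_config)
  data_b_std <- apply_input_standardizers(data_b, fit$standardizers)
  rep <- evaluate_model(fit$model, data_b_std)
  attr(rep, "standardizer_provenance") <- fit$standardizers$provenance
  attr(rep, "history") <- fit$history
  rep
}

## ---- portable container -----------------------------------------------

#' Write a cohort to a portable on-disk container
#'
#' One CSV per segment (samples x channels, with channel-name header) plus
#' a `manifest.csv` with columns file, record, subject_id, modality, label,
#' fs, rep. Ground-truth R-peak indices, when present, are stored alongside
#' as `rpeaks_<record>.csv`.
#'
#' @param cohort A `stress_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  sf_assert(inherits(cohort, "stress_cohort"), "stress_cohort required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(cohort$records)) {
    r <- cohort$records[[i]]
    for (mod in c("eeg", "ecg")) {
      seg <- r[[mod]]
      fn <- sprintf("%s_%03d.csv", mod, i)
      df <- as.data.frame(t(seg$data))
      names(df) <- seg$channel_names
      utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        file = fn, record = i, subject_id = seg$subject_id,
        modality = seg$modality, label = seg$label, fs = seg$fs,
        rep = r$rep, stringsAsFactors = FALSE)
    }
    if (!is.null(r$r_indices)) {
      utils::write.csv(data.frame(sample_index = r$r_indices),
                       file.path(dir, sprintf("rpeaks_%03d.csv", i)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load segments from a portable container directory
#'
#' The general-purpose loader behind the external-dataset adapters:
#' validates channel counts (14 for EEG, 1 for ECG) and sampling rates at
#' load time, resamples to `target_fs` with a polyphase filter when rates
#' differ, maps labels into the three-class vocabulary via `label_map`, and
#' rejects records with unmappable labels (reported, not fatal). Structural
#' violations -- wrong channel counts, missing files -- raise an itemized
#' error.
#'
#' @param dir Directory containing `manifest.csv` and segment CSVs.
#' @param label_map Optional named character vector mapping source labels
#'   to baseline/stress/amusement.
#' @param target_fs Target sampling rate (Hz).
#' @return A `stress_cohort`; rejected records are listed in
#'   `attr(, "load_report")`.
#' @export
load_cohort <- function(dir, label_map = NULL, target_fs = 700) {
  mf_path <- file.path(dir, "manifest.csv")
  sf_assert(file.exists(mf_path), sprintf("no manifest.csv in %s", dir),
            class = "stressfuse_load_error")
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  problems <- character(0)
  rejected <- data.frame()
  records <- list()
  for (rec_id in unique(mf$record)) {
    sub <- mf[mf$record == rec_id, ]
    lab <- normalize_labels(sub$label[1])
    if (!is.null(label_map) && lab %in% names(label_map)) {
      lab <- label_map[[lab]]
    }
    if (!lab %in% condition_levels()) {
      rejected <- rbind(rejected, data.frame(
        record = rec_id, label = sub$label[1],
        reason = "label outside vocabulary", stringsAsFactors = FALSE))
      next
    }
    rec <- list(label = lab, subject_id = sub$subject_id[1],
                rep = sub$rep[1])
    for (j in seq_len(nrow(sub))) {
      fn <- file.path(dir, sub$file[j])
      if (!file.exists(fn)) {
        problems <- c(problems, sprintf("record %d: missing file %s",
                                        rec_id, sub$file[j]))
        next
      }
      df <- utils::read.csv(fn, check.names = FALSE)
      ch_names <- colnames(df)
      x <- t(as.matrix(df))
      dimnames(x) <- NULL
      want <- if (sub$modality[j] == "EEG") 14 else 1
      if (nrow(x) != want) {
        problems <- c(problems, sprintf(
          "record %d (%s): expected %d channels, found %d",
          rec_id, sub$file[j], want, nrow(x)))
        next
      }
      fs <- sub$fs[j]
      if (fs != target_fs) {
        x <- t(apply(x, 1, function(ch) {
          signal::resample(ch, target_fs, fs)
        }))
        dimnames(x) <- NULL
        fs <- target_fs
      }
      seg <- signal_segment(x, fs, ch_names, sub$modality[j], lab,
                            sub$subject_id[1])
      rec[[tolower(sub$modality[j])]] <- seg
    }
    rp <- file.path(dir, sprintf("rpeaks_%03d.csv", rec_id))
    if (file.exists(rp)) {
      rec$r_indices <- utils::read.csv(rp)$sample_index
    }
    records[[length(records) + 1]] <- rec
  }
  if (length(problems) > 0) {
    sf_stop(paste0("container validation failed:\n  ",
                   paste(problems, collapse = "\n  ")),
            class = "stressfuse_load_error")
  }
  subs <- unique(vapply(records, `[[`, "", "subject_id"))
  out <- structure(list(records = records,
                        profiles = as.list(subs),
                        conditions = condition_presets(),
                        seed = NA_integer_, difficulty = "loaded"),
                   class = "stress_cohort")
  attr(out, "load_report") <- rejected
  out
}
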