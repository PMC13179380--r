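#' Cosine annealing schedule configuration
#'
#' @param eta_min,eta_max Learning-rate endpoints (defaults 1e-6 and 1e-3).
#' @param t_max Number of epochs over which the half-cosine decays
#'   (default 100).
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(eta_min = 1e-6, eta_max = 1e-3, t_max = 100) {
  sf_assert(eta_min > 0 && eta_min < eta_max,
            "need 0 < eta_min < eta_max")
  sf_assert(t_max >= 1, "t_max must be >= 1")
  structure(list(eta_min = eta_min, eta_max = eta_max, t_max = t_max),
            class = "schedule_config")
}

#' Learning rate at a given epoch under cosine annealing
#'
#' eta_t = eta_min + (eta_max - eta_min) (1 + cos(pi t / T_max)) / 2,
#' so eta(0) = eta_max and eta(T_max) = eta_min.
#'
#' @param t_cur Current epoch, in `[0, t_max]`.
#' @param cfg A [schedule_config()].
#' @return Learning rate.
#' @export
lr_at_epoch <- function(t_cur, cfg = schedule_config()) {
  sf_assert(t_cur >= 0 && t_cur <= cfg$t_max,
            sprintf("t_cur must lie in [0, %d]", cfg$t_max),
            class = "stressfuse_schedule_error")
  cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) *
    (1 + cos(pi * t_cur / cfg$t_max))
}

#' Loss configuration: label smoothing and L2 regularization
#'
#' @param smoothing Label smoothing epsilon (default 0.1).
#' @param l2_lambda L2 penalty strength on trainable weights (default 1e-4;
#'   biases and batch-norm parameters are excluded).
#' @param n_classes Number of classes (3).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(smoothing = 0.1, l2_lambda = 1e-4, n_classes = 3) {
  sf_assert(smoothing >= 0 && smoothing < 1, "smoothing must be in [0, 1)")
  sf_assert(l2_lambda >= 0, "l2_lambda must be >= 0")
  structure(list(smoothing = smoothing, l2_lambda = l2_lambda,
                 n_classes = n_classes), class = "loss_config")
}

smooth_targets <- function(labels_idx, cfg) {
  n <- length(labels_idx)
  y <- matrix(cfg$smoothing / cfg$n_classes, n, cfg$n_classes)
  y[cbind(seq_len(n), labels_idx)] <-
    y[cbind(seq_len(n), labels_idx)] + (1 - cfg$smoothing)
  y
}

#' Label-smoothed cross-entropy with L2 penalty
#'
#' Targets are (1 - eps) * onehot + eps / C; the loss is the cross-entropy
#' of the predicted probabilities against these smoothed targets plus
#' lambda times the squared L2 norm of the supplied weights.
#'
#' @param probs Probability vector (or one-row matrix) over the classes.
#' @param label 1-based class index.
#' @param cfg A [loss_config()].
#' @param weights Optional numeric vector of trainable weights entering the
#'   L2 penalty.
#' @return Scalar loss.
#' @export
smoothed_loss <- function(probs, label, cfg = loss_config(),
                          weights = NULL) {
  probs <- as.numeric(probs)
  sf_assert(length(probs) == cfg$n_classes &&
              all(probs >= 0) && abs(sum(probs) - 1) < 1e-6,
            "probs must be a probability vector over the classes",
            class = "stressfuse_prob_error")
  y <- smooth_targets(label, cfg)[1, ]
  ce <- -sum(y * log(pmax(probs, 1e-12)))
  pen <- if (is.null(weights)) 0 else cfg$l2_lambda * sum(weights^2)
  ce + pen
}

#' Augmentation configuration
#'
#' Defaults follow the training protocol: Gaussian noise with SD equal to
#' 0.05 x the per-channel signal SD; random time warping with factor in
#' 0.9-1.1 (resample then crop/pad to the original length); amplitude
#' scaling in 0.8-1.2; and, for EEG only, random permutation of mutually
#' non-adjacent channels under the fixed montage adjacency.
#'
#' @param noise_sigma_frac Noise SD as a fraction of the signal SD.
#' @param warp_range Time-warp factor range.
#' @param scale_range Amplitude scale factor range.
#' @param channel_shuffle Permute non-adjacent EEG channels.
#' @param adjacency Channel adjacency matrix (defaults to the montage's).
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(noise_sigma_frac = 0.05,
                                warp_range = c(0.9, 1.1),
                                scale_range = c(0.8, 1.2),
                                channel_shuffle = TRUE,
                                adjacency = montage_adjacency()) {
  structure(list(noise_sigma_frac = noise_sigma_frac,
                 warp_range = warp_range, scale_range = scale_range,
                 channel_shuffle = channel_shuffle, adjacency = adjacency),
            class = "augmentation_config")
}

time_warp <- function(x, factor) {
  L <- ncol(x)
  new_len <- round(L / factor)
  y <- t(apply(x, 1, function(ch) {
    stats::approx(seq_len(L), ch, xout = seq(1, L, length.out = new_len))$y
  }))
  if (new_len >= L) {
    off <- (new_len - L) %/% 2
    y <- y[, off + seq_len(L), drop = FALSE]
  } else {
    pad <- matrix(y[, new_len], nrow(y), L - new_len)
    y <- cbind(y, pad)
  }
  attr(y, "warp_resample_length") <- new_len
  y
}

nonadjacent_permutation <- function(n_ch, adjacency) {
  # greedy independent set in random order, then a random permutation
  # within it: only mutually non-adjacent channels move
  ord <- sample(n_ch)
  chosen <- integer(0)
  for (k in ord) {
    if (!any(adjacency[k, chosen])) chosen <- c(chosen, k)
  }
  perm <- seq_len(n_ch)
  if (length(chosen) > 1) perm[chosen] <- sample(chosen)
  perm
}

#' Apply the training augmentations to one segment
#'
#' Order of operations: time warp, additive noise, amplitude scaling, and
#' (EEG only) non-adjacent channel shuffling. Deterministic under `seed`.
#'
#' @param sample A `signal_segment`, or a channels x samples matrix (then
#'   `modality` must be given).
#' @param cfg An [augmentation_config()].
#' @param seed Integer seed.
#' @param modality "EEG" or "ECG" when `sample` is a bare matrix.
#' @return Augmented object of the same type, with the internal warp
#'   resample length in `attr(, "warp_resample_length")`.
#' @export
augment <- function(sample, cfg = augmentation_config(), seed = 1L,
                    modality = NULL) {
  seg <- inherits(sample, "signal_segment")
  x <- if (seg) sample$data else sample
  modality <- if (seg) sample$modality else modality
  sf_assert(!is.null(modality), "modality required for matrix input")
  with_seed(mix_seed(seed, "augment"), {
    warp_len <- ncol(x)
    if (diff(cfg$warp_range) > 0 || any(cfg$warp_range != 1)) {
      f <- stats::runif(1, cfg$warp_range[1], cfg$warp_range[2])
      x <- time_warp(x, f)
      warp_len <- attr(x, "warp_resample_length")
    }
    if (cfg$noise_sigma_frac > 0) {
      sds <- apply(x, 1, stats::sd)
      x <- x + matrix(stats::rnorm(length(x)), nrow(x)) *
        (cfg$noise_sigma_frac * sds)
    }
    if (any(cfg$scale_range != 1)) {
      x <- x * stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    }
    if (modality == "EEG" && isTRUE(cfg$channel_shuffle)) {
      x <- x[nonadjacent_permutation(nrow(x), cfg$adjacency), ,
             drop = FALSE]
    }
    if (seg) {
      attr(x, "warp_resample_length") <- NULL
      out <- sample
      out$data <- x
      attr(out, "warp_resample_length") <- warp_len
      out
    } else {
      attr(x, "warp_resample_length") <- warp_len
      x
    }
  })
}

#' Subject-independent split plan
#'
#' Assigns every subject to exactly one of train/validation/test. Counts
#' follow largest-remainder apportionment with ties broken in (train, val,
#' test) order, which reproduces the canonical 28/4/3 partition of 35
#' subjects at fractions 0.8/0.1/0.1. Optional stratification keys spread
#' strata across splits before quota filling.
#'
#' @param subject_ids Character vector of unique subject ids (>= 3).
#' @param fractions Length-3 numeric summing to 1 (train, val, test).
#' @param seed Integer seed (shuffling is deterministic under it).
#' @param strat_keys Optional named vector (by subject id) of stratum
#'   labels.
#' @return An object of class `split_plan`: data.frame with columns
#'   `subject_id` and `split`.
#' @export
make_split <- function(subject_ids, fractions = c(0.8, 0.1, 0.1),
                       seed = 1L, strat_keys = NULL) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  sf_assert(n >= 3, "need at least 3 subjects")
  sf_assert(abs(sum(fractions) - 1) < 1e-9,
            "fractions must sum to 1",
            class = "stressfuse_split_error")
  quota <- n * fractions
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- quota - counts
    order_pref <- order(-frac, seq_along(frac)) # ties: train, val, test
    counts[order_pref[seq_len(rem)]] <- counts[order_pref[seq_len(rem)]] + 1
  }
  # every requested split gets at least one subject (small cohorts)
  for (k in which(fractions > 0 & counts == 0)) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1
    counts[k] <- counts[k] + 1
  }
  ord <- with_seed(mix_seed(seed, "split"), {
    if (is.null(strat_keys)) {
      sample(subject_ids)
    } else {
      # shuffle within strata, then interleave strata round-robin
      strata <- split(subject_ids, strat_keys[subject_ids])
      strata <- lapply(strata, sample)
      out <- character(0)
      while (any(lengths(strata) > 0)) {
        for (s in names(strata)) {
          if (length(strata[[s]]) > 0) {
            out <- c(out, strata[[s]][1])
            strata[[s]] <- strata[[s]][-1]
          }
        }
      }
      out
    }
  })
  split <- rep(c("train", "val", "test"), counts)
  structure(data.frame(subject_id = ord, split = split,
                       stringsAsFactors = FALSE),
            class = c("split_plan", "data.frame"))
}

split_subjects <- function(plan, which) {
  plan$subject_id[plan$split == which]
}

## ---- cohort -> tensors ---------------------------------------------------

condition_levels <- function() c("baseline", "stress", "amusement")

#' Preprocess a cohort into model-ready tensors
#'
#' Runs the full signal pipeline on every record: EEG is bandpassed
#' (0.5-45 Hz), common-average referenced, epoched, optionally ICA-cleaned,
#' and converted to a band scalogram image at the profile's input size; ECG
#' is bandpassed (0.5-40 Hz), its central 10 s window kept for the raw
#' path, and the 25-feature HRV panel extracted from the full parent
#' recording.
#'
#' @param cohort A `stress_cohort`.
#' @param profile A [model_profile()].
#' @param run_ica Apply ICA artifact removal to the EEG epochs.
#' @return A list: `scalogram` (N, s, s, 3), `ecg` (N, 7000, 1), `hrv`
#'   (N, 25), `labels` (factor), `subject_ids`, `augmented` (logical).
#' @export
prepare_cohort <- function(cohort, profile = model_profile("test"),
                           run_ica = FALSE) {
  sf_assert(inherits(cohort, "stress_cohort"), "stress_cohort required")
  recs <- cohort$records
  N <- length(recs)
  s <- profile$input_size
  scal <- array(0, c(N, s, s, 3))
  ecg <- array(0, c(N, profile$ecg_len, 1))
  hrv <- matrix(0, N, 25)
  labels <- character(N)
  subs <- character(N)
  aug <- logical(N)
  for (i in seq_len(N)) {
    r <- recs[[i]]
    eeg <- common_average_reference(bandpass_eeg(r$eeg))
    es <- epoch_segments(list(eeg))
    if (run_ica) es <- remove_artifacts_ica(es)
    img <- build_scalogram_image(es$epochs[[1]], fs = es$fs,
                                 n_freq = s, n_time = s)
    scal[i, , , ] <- img$pixels
    ecgf <- bandpass_ecg(r$ecg)
    n_ecg <- ncol(ecgf$data)
    sf_assert(n_ecg >= profile$ecg_len, "ECG segment shorter than 10 s")
    off <- (n_ecg - profile$ecg_len) %/% 2
    ecg[i, , 1] <- ecgf$data[1, off + seq_len(profile$ecg_len)]
    hrv[i, ] <- extract_hrv(r$ecg)
    labels[i] <- r$label
    subs[i] <- r$subject_id
    aug[i] <- isTRUE(r$augmented)
  }
  colnames(hrv) <- hrv_feature_names()
  list(scalogram = scal, ecg = ecg, hrv = hrv,
       labels = factor(labels, levels = condition_levels()),
       subject_ids = subs, augmented = aug)
}

#' Expand a cohort with augmented copies of selected subjects' records
#'
#' Augmentation operates on the raw signals (before any preprocessing) and
#' is only ever applied to the listed subjects -- the training harness
#' passes the training split here, so validation and test records are never
#' augmented. Each copy is tagged `augmented = TRUE`.
#'
#' @param cohort A `stress_cohort`.
#' @param subjects Subject ids whose records may be augmented.
#' @param cfg An [augmentation_config()].
#' @param copies Augmented copies per original record.
#' @param seed Integer seed.
#' @return The expanded `stress_cohort`, with the number of augment() calls
#'   per subject recorded in `attr(, "augment_calls")`.
#' @export
augment_cohort <- function(cohort, subjects, cfg = augmentation_config(),
                           copies = 1, seed = 1L) {
  recs <- cohort$records
  calls <- stats::setNames(integer(length(cohort$profiles)),
                           cohort_subjects(cohort))
  out <- recs
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (!(r$subject_id %in% subjects)) next
    for (k in seq_len(copies)) {
      r2 <- r
      r2$eeg <- augment(r$eeg, cfg, seed = mix_seed(seed, i, k, "eeg"))
      r2$ecg <- augment(r$ecg, cfg, seed = mix_seed(seed, i, k, "ecg"))
      r2$augmented <- TRUE
      calls[r$subject_id] <- calls[r$subject_id] + 2L
      out[[length(out) + 1]] <- r2
    }
  }
  cohort$records <- out
  attr(cohort, "augment_calls") <- calls
  cohort
}

## ---- input standardization ------------------------------------------------

#' Fit input standardizers on the training rows of a prepared dataset
#'
#' Per-band scalogram standardization, per-feature HRV z-scoring, and a
#' global raw-ECG scale, all estimated from the given training rows only.
#'
#' @param data Tensors from [prepare_cohort()].
#' @param train_idx Row indices belonging to the training split.
#' @return List of standardizer parameters with `provenance = "train"`.
#' @export
fit_input_standardizers <- function(data, train_idx) {
  scal_tr <- data$scalogram[train_idx, , , , drop = FALSE]
  img_std <- fit_standardizer(scal_tr)
  hrv_tr <- data$hrv[train_idx, , drop = FALSE]
  hrv_mu <- colMeans(hrv_tr)
  hrv_sd <- apply(hrv_tr, 2, pop_sd)
  hrv_sd[hrv_sd == 0] <- 1
  ecg_tr <- data$ecg[train_idx, , , drop = FALSE]
  list(img = img_std, hrv_mu = hrv_mu, hrv_sd = hrv_sd,
       ecg_mu = mean(ecg_tr), ecg_sd = max(stats::sd(ecg_tr), 1e-12),
       provenance = "train")
}

#' Apply fitted input standardizers to a prepared dataset
#'
#' @param data Tensors from [prepare_cohort()].
#' @param st Parameters from [fit_input_standardizers()] (never refit here).
#' @return The standardized tensors.
#' @export
apply_input_standardizers <- function(data, st) {
  data$scalogram <- apply_standardizer(data$scalogram, st$img)
  data$hrv <- sweep(sweep(data$hrv, 2, st$hrv_mu), 2, st$hrv_sd, "/")
  data$ecg <- (data$ecg - st$ecg_mu) / st$ecg_sd
  data
}

subset_data <- function(data, idx) {
  list(scalogram = data$scalogram[idx, , , , drop = FALSE],
       ecg = data$ecg[idx, , , drop = FALSE],
       hrv = data$hrv[idx, , drop = FALSE],
       labels = data$labels[idx],
       subject_ids = data$subject_ids[idx],
       augmented = data$augmented[idx])
}

## ---- training loop --------------------------------------------------------

#' Training configuration
#'
#' @param epochs Number of epochs.
#' @param batch_size Mini-batch size (default 32).
#' @param schedule A [schedule_config()]; its `t_max` defaults to `epochs`.
#' @param loss A [loss_config()].
#' @param adam_beta1,adam_beta2,adam_eps Adam moments and stabilizer
#'   (0.9, 0.999, 1e-7).
#' @param seed Integer seed for shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 20, batch_size = 32,
                            schedule = NULL, loss = loss_config(),
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-7, seed = 1L, verbose = FALSE) {
  if (is.null(schedule)) {
    schedule <- schedule_config(t_max = max(epochs, 1))
  }
  structure(list(epochs = epochs, batch_size = batch_size,
                 schedule = schedule, loss = loss,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, seed = as.integer(seed),
                 verbose = verbose),
            class = "training_config")
}

batch_loss_acc <- function(model, data, idx, loss_cfg, modules) {
  out <- model_forward(model, list(
    scalogram = data$scalogram[idx, , , , drop = FALSE],
    ecg = data$ecg[idx, , , drop = FALSE],
    hrv = data$hrv[idx, , drop = FALSE]), training = FALSE)
  yidx <- as.integer(data$labels[idx])
  y <- smooth_targets(yidx, loss_cfg)
  lp <- log(pmax(out$probs, 1e-12))
  ce <- -mean(rowSums(y * lp))
  pen <- nn_l2_penalty(modules, loss_cfg$l2_lambda)
  acc <- mean(max.col(out$probs) == yidx)
  list(loss = ce + pen, acc = acc)
}

#' Train a model on a preprocessed dataset under a split plan
#'
#' Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-7) with the cosine-annealed
#' learning rate, label-smoothed cross-entropy plus L2 penalty. Input
#' standardizers (scalogram bands, HRV features, raw ECG) are fit on the
#' training split only. Augmented records are used for training only; an
#' error is raised if any appear in validation or test. Training aborts
#' with a diagnostic on non-finite loss.
#'
#' @param model A `stress_model` from [build_full_model()].
#' @param data Tensors from [prepare_cohort()].
#' @param plan A [make_split()] plan over the data's subjects.
#' @param config A [training_config()].
#' @return List with the trained `model`, `history` (one row per epoch:
#'   epoch, lr, train_loss, train_acc, val_loss, val_acc), and the fitted
#'   `standardizers`.
#' @export
train_model <- function(model, data, plan, config = training_config()) {
  sf_assert(inherits(model, "stress_model"), "stress_model required")
  sf_assert(inherits(plan, "split_plan"), "split_plan required")
  assign_split <- stats::setNames(plan$split, plan$subject_id)
  splits <- assign_split[data$subject_ids]
  train_idx <- which(splits == "train")
  val_idx <- which(splits == "val" & !data$augmented)
  sf_assert(!any(data$augmented[splits != "train"]),
            "augmented records found outside the training split",
            class = "stressfuse_leakage_error")
  sf_assert(length(train_idx) > 0, "empty training split")

  st <- fit_input_standardizers(data, train_idx)
  data <- apply_input_standardizers(data, st)
  modules <- model_modules(model)
  opt <- adam_optimizer(config$adam_beta1, config$adam_beta2,
                        config$adam_eps)
  loss_cfg <- config$loss
  history <- data.frame()
  with_seed(mix_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(min(epoch - 1, config$schedule$t_max),
                        config$schedule)
      ord <- sample(train_idx)
      ep_loss <- 0; ep_correct <- 0
      nb <- 0
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        nB <- length(idx)
        out <- model_forward(model, list(
          scalogram = data$scalogram[idx, , , , drop = FALSE],
          ecg = data$ecg[idx, , , drop = FALSE],
          hrv = data$hrv[idx, , drop = FALSE]), training = TRUE)
        yidx <- as.integer(data$labels[idx])
        y <- smooth_targets(yidx, loss_cfg)
        lse <- log(rowSums(exp(out$logits -
                                 apply(out$logits, 1, max)))) +
          apply(out$logits, 1, max)
        ce <- mean(rowSums(y * (lse - out$logits)))
        pen <- nn_l2_penalty(modules, loss_cfg$l2_lambda)
        loss <- ce + pen
        if (!is.finite(loss)) {
          sf_stop(sprintf(
            "non-finite loss at epoch %d (ce = %g, penalty = %g)",
            epoch, ce, pen), class = "stressfuse_nan_error")
        }
        nn_zero_grads(modules)
        dlogits <- (out$probs - y) / nB
        model_backward(model, dlogits)
        nn_add_l2_grads(modules, loss_cfg$l2_lambda)
        adam_step(opt, modules, lr)
        ep_loss <- ep_loss + loss * nB
        ep_correct <- ep_correct + sum(max.col(out$probs) == yidx)
        nb <- nb + nB
      }
      val <- if (length(val_idx) > 0) {
        batch_loss_acc(model, data, val_idx, loss_cfg, modules)
      } else list(loss = NA_real_, acc = NA_real_)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss / nb,
        train_acc = ep_correct / nb, val_loss = val$loss,
        val_acc = val$acc))
      if (config$verbose) {
        message(sprintf(
          "epoch %d: lr %.2e train loss %.4f acc %.3f val acc %.3f",
          epoch, lr, ep_loss / nb, ep_correct / nb, val$acc))
      }
    }
  })
  list(model = model, history = history, standardizers = st)
}
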