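#' Fixed 14-channel EEG montage
#'
#' The pipeline assumes a 14-channel, 10-20-style headset montage. Channel
#' names are needed for frontal-preferential effects (theta boost, blink
#' artifacts) and for the adjacency graph used by channel-shuffle
#' augmentation.
#'
#' @return Character vector of 14 channel names.
#' @export
eeg_montage <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

frontal_channels <- function() c("AF3", "F7", "F3", "F4", "F8", "AF4")

#' Neighbor graph of the fixed montage
#'
#' Nearest-neighbor adjacency on the scalp for the 14-channel montage,
#' used to restrict channel-shuffle augmentation to mutually non-adjacent
#' electrodes.
#'
#' @return A symmetric 14x14 logical matrix with channel names as dimnames.
#' @export
montage_adjacency <- function() {
  ch <- eeg_montage()
  pairs <- list(
    c("AF3", "AF4"), c("AF3", "F3"), c("AF3", "F7"),
    c("AF4", "F4"), c("AF4", "F8"),
    c("F7", "F3"), c("F7", "FC5"), c("F3", "FC5"),
    c("F8", "F4"), c("F4", "FC6"), c("F8", "FC6"),
    c("FC5", "T7"), c("T7", "P7"), c("P7", "O1"),
    c("O1", "O2"), c("O2", "P8"), c("P8", "T8"), c("T8", "FC6")
  )
  adj <- matrix(FALSE, 14, 14, dimnames = list(ch, ch))
  for (p in pairs) {
    adj[p[1], p[2]] <- TRUE
    adj[p[2], p[1]] <- TRUE
  }
  adj
}

#' Subject profile for the synthetic generator
#'
#' Bundles the stable per-subject physiology that the generator modulates by
#' condition: resting heart rate, a global RR-variability multiplier, and
#' per-band EEG amplitude gains.
#'
#' @param subject_id Opaque subject identifier string.
#' @param baseline_hr Resting heart rate in beats/min, in [40, 180].
#' @param hrv_scale Dimensionless multiplier on all RR variability (> 0).
#' @param band_gain Named numeric of per-band amplitude multipliers with
#'   entries theta, alpha, beta (all > 0).
#' @param seed Integer seed; together with the condition it fully determines
#'   generator output.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, baseline_hr = 65, hrv_scale = 1,
                            band_gain = c(theta = 1, alpha = 1, beta = 1),
                            seed = 1L) {
  sf_assert(is.character(subject_id) && length(subject_id) == 1,
            "subject_id must be a single string")
  sf_assert(baseline_hr >= 40 && baseline_hr <= 180,
            "baseline_hr must lie in [40, 180] beats/min")
  sf_assert(hrv_scale > 0, "hrv_scale must be positive")
  sf_assert(all(c("theta", "alpha", "beta") %in% names(band_gain)) &&
              all(band_gain > 0),
            "band_gain needs positive theta, alpha, beta entries")
  structure(list(subject_id = subject_id, baseline_hr = baseline_hr,
                 hrv_scale = hrv_scale,
                 band_gain = band_gain[c("theta", "alpha", "beta")],
                 seed = as.integer(seed)),
            class = "subject_profile")
}

#' Condition specification for the synthetic generator
#'
#' Encodes how one experimental condition shifts EEG band power and RR
#' dynamics relative to baseline. The stress preset raises theta and beta
#' power, suppresses alpha, raises heart rate, and lowers RR variability
#' (lower RMSSD, higher LF/HF) -- the canonical autonomic stress signature.
#'
#' @param label One of "baseline", "stress", "amusement".
#' @param theta_mult,alpha_mult,beta_mult EEG band-power multipliers
#'   relative to baseline.
#' @param hr_shift Heart-rate shift in beats/min added to the subject's
#'   resting rate.
#' @param rmssd_mult Multiplier on short-term RR variability.
#' @param lf_hf_mult Multiplier on the LF/HF spectral power ratio.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(label, theta_mult = 1, alpha_mult = 1,
                           beta_mult = 1, hr_shift = 0, rmssd_mult = 1,
                           lf_hf_mult = 1) {
  sf_assert(label %in% c("baseline", "stress", "amusement"),
            sprintf("unknown condition label '%s'", label),
            class = "stressfuse_label_error")
  structure(list(label = label, theta_mult = theta_mult,
                 alpha_mult = alpha_mult, beta_mult = beta_mult,
                 hr_shift = hr_shift, rmssd_mult = rmssd_mult,
                 lf_hf_mult = lf_hf_mult),
            class = "condition_spec")
}

#' Condition presets
#'
#' The `default` presets encode a moderate, literature-consistent stress
#' signature (elevated frontal theta and beta, suppressed alpha, +15 bpm,
#' RMSSD down to 0.6x, LF/HF doubled) and a mild amusement state (small
#' alpha increase, +4 bpm, intermediate RMSSD). The `easy` presets widen the
#' separation between conditions and are intended for fast end-to-end
#' training checks where class separability must be guaranteed.
#'
#' @param difficulty "default" or "easy".
#' @return Named list of three `condition_spec` objects.
#' @export
condition_presets <- function(difficulty = c("default", "easy")) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "default") {
    list(
      baseline = condition_spec("baseline"),
      stress = condition_spec("stress", theta_mult = 1.3, alpha_mult = 0.7,
                              beta_mult = 1.4, hr_shift = 15,
                              rmssd_mult = 0.6, lf_hf_mult = 2.0),
      amusement = condition_spec("amusement", theta_mult = 1.05,
                                 alpha_mult = 1.15, beta_mult = 1.05,
                                 hr_shift = 4, rmssd_mult = 0.85,
                                 lf_hf_mult = 1.2)
    )
  } else {
    list(
      baseline = condition_spec("baseline"),
      stress = condition_spec("stress", theta_mult = 1.8, alpha_mult = 0.45,
                              beta_mult = 2.0, hr_shift = 28,
                              rmssd_mult = 0.4, lf_hf_mult = 3.0),
      amusement = condition_spec("amusement", theta_mult = 1.0,
                                 alpha_mult = 1.7, beta_mult = 1.0,
                                 hr_shift = 8, rmssd_mult = 0.8,
                                 lf_hf_mult = 1.3)
    )
  }
}

#' Labeled signal segment
#'
#' The basic container moved through every pipeline stage: a channels x
#' samples matrix with sampling rate, channel names, modality, condition
#' label and subject identity. EEG segments carry 14 channels; ECG segments
#' one. Both modalities are sampled at 700 Hz.
#'
#' @param data channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `data`.
#' @param modality "EEG" or "ECG".
#' @param label Condition label.
#' @param subject_id Subject identifier.
#' @return An object of class `signal_segment`.
#' @export
signal_segment <- function(data, fs, channel_names, modality, label,
                           subject_id) {
  sf_assert(is.matrix(data) && is.numeric(data),
            "data must be a numeric channels x samples matrix")
  sf_assert(modality %in% c("EEG", "ECG"), "modality must be EEG or ECG")
  sf_assert(length(channel_names) == nrow(data),
            "one channel name per data row required")
  if (modality == "EEG") {
    sf_assert(nrow(data) == 14, "EEG segments must have 14 channels")
  } else {
    sf_assert(nrow(data) == 1, "ECG segments must have 1 channel")
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 modality = modality, label = label,
                 subject_id = subject_id),
            class = "signal_segment")
}

#' @export
print.signal_segment <- function(x, ...) {
  cat(sprintf("<signal_segment> %s %s: %d ch x %d samples @ %g Hz (%s, %.1f s)\n",
              x$subject_id, x$modality, nrow(x$data), ncol(x$data), x$fs,
              x$label, ncol(x$data) / x$fs))
  invisible(x)
}

# 1/f "pink-ish" background noise via FFT amplitude shaping, band-limited to
# [f_lo, f_hi], unit variance.
one_over_f_noise <- function(n, fs, f_lo = 0.5, f_hi = 45) {
  white <- stats::rnorm(n)
  xf <- stats::fft(white)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  shape <- ifelse(f >= f_lo & f <= f_hi, 1 / sqrt(pmax(f, f_lo)), 0)
  x <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# Band-limited Gaussian oscillatory process with unit variance.
band_noise <- function(n, fs, band, order = 4) {
  filt <- signal::butter(order, band / (fs / 2), type = "pass")
  # pad to kill filtfilt edge transients, then crop
  pad <- min(n, 2 * round(fs / band[1]))
  x <- stats::rnorm(n + 2 * pad)
  y <- signal::filtfilt(filt, x)[(pad + 1):(pad + n)]
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

#' Generate a synthetic multichannel EEG segment
#'
#' Builds each channel as a sum of band-limited oscillatory processes
#' (theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz) whose variances are scaled
#' by the condition multipliers and the subject's band gains, plus 1/f
#' background noise, optional 50 Hz line interference, and optional
#' blink-like low-frequency frontal transients. The condition's theta boost
#' is applied preferentially to frontal channels.
#'
#' Output is a pure function of (profile, condition, seed): the same triple
#' always yields a bitwise-identical segment.
#'
#' @param profile A `subject_profile`.
#' @param cond A `condition_spec`.
#' @param duration Segment length in seconds (>= 10).
#' @param seed Optional integer mixed into the profile seed, for independent
#'   repetitions from one profile.
#' @param fs Sampling rate (Hz).
#' @param line_amp Amplitude of 50 Hz line interference (0 disables).
#' @param blink_rate Expected blink transients per second (0 disables).
#' @return A `signal_segment` (14 x duration*fs).
#' @export
generate_eeg <- function(profile, cond, duration = 10, seed = 0L, fs = 700,
                         line_amp = 0, blink_rate = 0) {
  sf_assert(inherits(profile, "subject_profile"), "profile required")
  sf_assert(inherits(cond, "condition_spec"),
            "cond must be a condition_spec",
            class = "stressfuse_label_error")
  sf_assert(duration >= 10, "duration must be at least 10 s")
  n <- round(duration * fs)
  ch <- eeg_montage()
  frontal <- ch %in% frontal_channels()

  bands <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
  base_amp <- c(theta = 5, alpha = 6, beta = 4) # uV scale
  mults <- c(theta = cond$theta_mult, alpha = cond$alpha_mult,
             beta = cond$beta_mult)

  with_seed(mix_seed(profile$seed, cond$label, seed, "eeg"), {
    x <- matrix(0, 14, n)
    for (b in names(bands)) {
      for (k in seq_len(14)) {
        # frontal channels take the theta modulation preferentially
        m <- mults[[b]]
        if (b == "theta") {
          w <- if (frontal[k]) 1.5 else 0.5
          m <- 1 + (m - 1) * w
        }
        sd_target <- base_amp[[b]] * sqrt(m * profile$band_gain[[b]])
        x[k, ] <- x[k, ] + sd_target * band_noise(n, fs, bands[[b]])
      }
    }
    for (k in seq_len(14)) {
      x[k, ] <- x[k, ] + 1.5 * one_over_f_noise(n, fs)
    }
    if (line_amp > 0) {
      tt <- seq_len(n) / fs
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + matrix(rep(line_amp * sin(2 * pi * 50 * tt + phase),
                          each = 14), 14, n)
    }
    if (blink_rate > 0) {
      n_blinks <- stats::rpois(1, blink_rate * duration)
      # per-channel blink topography (rank-1, frontal-dominant)
      topo <- ifelse(ch %in% c("AF3", "AF4"), 1.0,
                     ifelse(ch %in% c("F3", "F4"), 0.7,
                            ifelse(ch %in% c("F7", "F8"), 0.5, 0)))
      if (n_blinks > 0) {
        for (i in seq_len(n_blinks)) {
          dur_b <- stats::runif(1, 0.3, 0.5)
          t0 <- stats::runif(1, 0, max(duration - dur_b, 0))
          idx <- seq(round(t0 * fs) + 1, min(round((t0 + dur_b) * fs), n))
          pulse <- 40 * sin(pi * seq_along(idx) / length(idx)) # half-sine
          x[, idx] <- x[, idx] + outer(topo, pulse)
        }
      }
    }
    signal_segment(x, fs, ch, "EEG", cond$label, profile$subject_id)
  })
}

# PQRST template: sum of Gaussian deflections (amplitude mV, center s, width s)
pqrst_template <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amp = c(0.08, -0.12, 1.00, -0.22, 0.25),
    mu = c(-0.200, -0.028, 0.000, 0.030, 0.270),
    sigma = c(0.035, 0.012, 0.011, 0.014, 0.060)
  )
}

#' Generate a synthetic single-lead ECG segment with ground-truth R times
#'
#' R-times are drawn from an integral-pulse-frequency-modulation style RR
#' process: mean interval 60/(baseline_hr + hr_shift) seconds with
#' sinusoidal LF (0.1 Hz) and HF (0.25 Hz) modulation plus white jitter.
#' The HF amplitude and jitter scale with `rmssd_mult * hrv_scale`; the LF
#' amplitude additionally scales with `sqrt(lf_hf_mult)` so the LF/HF power
#' ratio is multiplied by `lf_hf_mult`. A PQRST template (sum of Gaussians)
#' is placed at every R-time; baseline wander and white noise are added on
#' top.
#'
#' @inheritParams generate_eeg
#' @param duration Segment length in seconds; must accommodate >= 2 beats.
#' @param noise_sd Additive white noise SD in mV (ignored if `snr_db` given).
#' @param snr_db If non-NULL, noise SD is set so the segment has this
#'   signal-to-noise ratio in dB.
#' @param modulation Include the LF/HF sinusoidal modulators and jitter.
#' @param wander Include slow baseline wander.
#' @return List with `segment` (a `signal_segment`), `r_times` (seconds),
#'   and `r_indices` (1-based sample indices of ground-truth R peaks).
#' @export
generate_ecg <- function(profile, cond, duration = 60, seed = 0L, fs = 700,
                         noise_sd = 0.02, snr_db = NULL, modulation = TRUE,
                         wander = TRUE) {
  sf_assert(inherits(profile, "subject_profile"), "profile required")
  sf_assert(inherits(cond, "condition_spec"),
            "cond must be a condition_spec",
            class = "stressfuse_label_error")
  hr <- profile$baseline_hr + cond$hr_shift
  mean_rr <- 60 / hr
  sf_assert(duration >= 2 * mean_rr,
            "duration too short to contain two beats",
            class = "stressfuse_duration_error")
  n <- round(duration * fs)

  a_base <- 0.030 * profile$hrv_scale * cond$rmssd_mult # seconds
  a_hf <- if (modulation) a_base else 0
  a_lf <- if (modulation) a_base * sqrt(cond$lf_hf_mult) else 0
  jit <- if (modulation) 0.008 * profile$hrv_scale * cond$rmssd_mult else 0

  with_seed(mix_seed(profile$seed, cond$label, seed, "ecg"), {
    phi_lf <- stats::runif(1, 0, 2 * pi)
    phi_hf <- stats::runif(1, 0, 2 * pi)
    beats <- numeric(0)
    # margins keep full PQRST complexes inside the segment
    t <- 0.3
    while (t < duration - 0.25) {
      beats <- c(beats, t)
      rr <- mean_rr +
        a_lf * sin(2 * pi * 0.1 * t + phi_lf) +
        a_hf * sin(2 * pi * 0.25 * t + phi_hf) +
        if (jit > 0) stats::rnorm(1, 0, jit) else 0
      rr <- min(max(rr, 0.3), 2.4)
      t <- t + rr
    }
    tt <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    tmpl <- pqrst_template()
    for (tb in beats) {
      lo <- max(1, floor((tb - 0.45) * fs) + 1)
      hi <- min(n, ceiling((tb + 0.55) * fs) + 1)
      if (lo > hi) next
      tw <- tt[lo:hi] - tb
      seg <- numeric(length(tw))
      for (w in seq_len(nrow(tmpl))) {
        seg <- seg + tmpl$amp[w] * exp(-(tw - tmpl$mu[w])^2 /
                                         (2 * tmpl$sigma[w]^2))
      }
      x[lo:hi] <- x[lo:hi] + seg
    }
    if (wander) {
      x <- x + 0.05 * sin(2 * pi * 0.20 * tt + stats::runif(1, 0, 2 * pi)) +
        0.03 * sin(2 * pi * 0.33 * tt + stats::runif(1, 0, 2 * pi))
    }
    sd_noise <- if (!is.null(snr_db)) {
      sqrt(mean(x^2)) * 10^(-snr_db / 20)
    } else noise_sd
    if (sd_noise > 0) x <- x + stats::rnorm(n, 0, sd_noise)

    r_idx <- round(beats * fs) + 1
    keep <- r_idx >= 1 & r_idx <= n
    seg <- signal_segment(matrix(x, 1), fs, "ECG", "ECG", cond$label,
                          profile$subject_id)
    list(segment = seg, r_times = beats[keep], r_indices = r_idx[keep])
  })
}

#' Generate a labeled multi-subject cohort of paired EEG + ECG segments
#'
#' Draws per-subject profiles from documented ranges (resting HR uniform in
#' 55-75 bpm, HRV scale and band gains log-uniform-ish around 1), then
#' generates one EEG segment (default 10 s) and one parent ECG recording
#' (default 120 s, from which the raw 10 s window and the HRV panel are
#' later drawn) for every subject x condition x repetition. Labels are
#' balanced across the three conditions by construction.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param per_condition_segments Repetitions per condition per subject.
#' @param seed Master seed; two cohorts with the same seed are identical.
#' @param difficulty Condition preset difficulty; see [condition_presets()].
#' @param eeg_duration,ecg_duration Segment lengths in seconds.
#' @param blink_rate Blink transients per second injected into EEG.
#' @return An object of class `stress_cohort`: list with `records` (each
#'   holding `eeg`, `ecg`, `r_indices`, `label`, `subject_id`, `rep`),
#'   `profiles`, and `conditions`.
#' @export
generate_cohort <- function(n_subjects, per_condition_segments = 2,
                            seed = 1L, difficulty = "default",
                            eeg_duration = 10, ecg_duration = 120,
                            blink_rate = 0) {
  sf_assert(n_subjects >= 3, "need at least 3 subjects")
  conds <- condition_presets(difficulty)
  tight <- difficulty == "easy"
  profiles <- lapply(seq_len(n_subjects), function(i) {
    with_seed(mix_seed(seed, i, "profile"), {
      subject_profile(
        subject_id = sprintf("S%02d", i),
        baseline_hr = stats::runif(1, if (tight) 60 else 55,
                                   if (tight) 70 else 75),
        hrv_scale = exp(stats::runif(1, if (tight) -0.1 else -0.25,
                                     if (tight) 0.1 else 0.25)),
        band_gain = c(theta = exp(stats::runif(1, -0.2, 0.2)),
                      alpha = exp(stats::runif(1, -0.2, 0.2)),
                      beta = exp(stats::runif(1, -0.2, 0.2))),
        seed = mix_seed(seed, i, "subject")
      )
    })
  })
  records <- list()
  for (i in seq_len(n_subjects)) {
    for (cn in names(conds)) {
      for (r in seq_len(per_condition_segments)) {
        eeg <- generate_eeg(profiles[[i]], conds[[cn]],
                            duration = eeg_duration,
                            seed = mix_seed(seed, r, "rep"),
                            blink_rate = blink_rate)
        ecg <- generate_ecg(profiles[[i]], conds[[cn]],
                            duration = ecg_duration,
                            seed = mix_seed(seed, r, "rep"))
        records[[length(records) + 1]] <- list(
          eeg = eeg, ecg = ecg$segment, r_indices = ecg$r_indices,
          label = cn, subject_id = profiles[[i]]$subject_id, rep = r
        )
      }
    }
  }
  structure(list(records = records, profiles = profiles,
                 conditions = conds, seed = seed,
                 difficulty = difficulty),
            class = "stress_cohort")
}

#' @export
print.stress_cohort <- function(x, ...) {
  labs <- vapply(x$records, `[[`, "", "label")
  cat(sprintf("<stress_cohort> %d subjects, %d paired segments (%s)\n",
              length(x$profiles), length(x$records),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

#' Subject identifiers of a cohort
#' @param cohort A `stress_cohort`.
#' @return Character vector of unique subject ids.
#' @export
cohort_subjects <- function(cohort) {
  unique(vapply(cohort$records, `[[`, "", "subject_id"))
}
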