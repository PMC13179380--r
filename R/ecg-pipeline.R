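#' Zero-phase Butterworth bandpass for ECG
#'
#' Fourth-order forward-backward Butterworth, 0.5-40 Hz: removes baseline
#' wander and high-frequency noise while preserving QRS morphology and
#' R-peak timing (zero phase).
#'
#' @param segment A single-lead `signal_segment`.
#' @param spec A `filter_spec`; defaults to 0.5-40 Hz, order 4.
#' @return Filtered `signal_segment`, band edges in `attr(, "band_edges")`.
#' @export
bandpass_ecg <- function(segment, spec = filter_spec(0.5, 40, 4)) {
  sf_assert(inherits(segment, "signal_segment"), "signal_segment required")
  sf_assert(segment$fs > 2 * spec$high_hz, "fs too low for this band",
            class = "stressfuse_band_error")
  out <- segment
  out$data <- apply_butter(segment$data, segment$fs, spec)
  attr(out, "band_edges") <- c(spec$low_hz, spec$high_hz)
  out
}

#' Pan-Tompkins QRS detection
#'
#' The classic pipeline: 5-15 Hz bandpass, five-point derivative, squaring,
#' 150 ms moving-window integration, dual adaptive thresholds with running
#' signal/noise estimates, a 200 ms refractory period, and search-back at
#' 1.66x the running RR average. Detections are refined to the local
#' maximum of the input signal within +/- 50 ms.
#'
#' @param segment A single-lead `signal_segment` (fs >= 200 Hz).
#' @return An object of class `r_peak_series`: list with strictly
#'   increasing `sample_indices` (1-based) and `fs`. An empty series (not
#'   an error) when no peaks are found.
#' @export
detect_r_peaks <- function(segment) {
  sf_assert(inherits(segment, "signal_segment"), "signal_segment required")
  fs <- segment$fs
  sf_assert(fs >= 200, "Pan-Tompkins stages assume fs >= 200 Hz",
            class = "stressfuse_fs_error")
  x <- segment$data[1, ]
  n <- length(x)
  empty <- structure(list(sample_indices = integer(0), fs = fs),
                     class = "r_peak_series")
  if (n < fs || stats::sd(x) == 0) return(empty)

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  # centered five-point derivative
  d <- numeric(n)
  d[3:(n - 2)] <- (2 * xf[5:n] + xf[4:(n - 1)] -
                     xf[2:(n - 3)] - 2 * xf[1:(n - 4)]) / 8
  sq <- d^2
  wlen <- round(0.150 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate fiducial marks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1
  if (length(cand) == 0) return(empty)

  refrac <- round(0.200 * fs)
  init <- mwi[seq_len(min(2 * fs, n))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- function() npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  rr_hist <- numeric(0)
  i <- 1
  while (i <= length(cand)) {
    p <- cand[i]
    pk <- mwi[p]
    since <- if (length(qrs) == 0) Inf else p - qrs[length(qrs)]
    if (pk > thr1() && since > refrac) {
      qrs <- c(qrs, p)
      if (length(qrs) > 1) rr_hist <- c(rr_hist, diff(utils::tail(qrs, 2)))
      spki <- 0.125 * pk + 0.875 * spki
    } else if (since <= refrac) {
      # within refractory: keep the larger fiducial mark
      if (length(qrs) > 0 && pk > mwi[qrs[length(qrs)]]) {
        qrs[length(qrs)] <- p
        spki <- 0.125 * pk + 0.875 * spki
      } else {
        npki <- 0.125 * pk + 0.875 * npki
      }
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      # search-back when the gap exceeds 1.66x the running RR average
      rr_avg <- if (length(rr_hist) > 0) {
        mean(utils::tail(rr_hist, 8))
      } else NA
      if (!is.na(rr_avg) && since > 1.66 * rr_avg) {
        win <- cand[cand > qrs[length(qrs)] + refrac & cand <= p]
        win <- win[mwi[win] > 0.5 * thr1()]
        if (length(win) > 0) {
          best <- win[which.max(mwi[win])]
          qrs <- sort(unique(c(qrs, best)))
          rr_hist <- c(rr_hist, diff(utils::tail(qrs, 2)))
          spki <- 0.25 * mwi[best] + 0.75 * spki
          # re-examine current candidate on next pass
          next
        }
      }
    }
    i <- i + 1
  }
  if (length(qrs) == 0) return(empty)

  # refine to the local maximum of the input signal within +/- 50 ms
  half <- round(0.050 * fs)
  ref <- vapply(qrs, function(p) {
    lo <- max(1, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce the refractory constraint after refinement
  keep <- rep(TRUE, length(ref))
  last <- ref[1]
  for (j in seq_along(ref)[-1]) {
    if (ref[j] - last < refrac) {
      if (x[ref[j]] > x[last]) {
        keep[which(ref == last)] <- FALSE
        last <- ref[j]
      } else keep[j] <- FALSE
    } else last <- ref[j]
  }
  structure(list(sample_indices = ref[keep], fs = fs),
            class = "r_peak_series")
}

#' Convert R-peaks to a corrected RR interval series
#'
#' Successive peak differences are converted to milliseconds. Intervals
#' outside (250, 2500) ms, or deviating more than 30% from the median of
#' their 5 nearest neighbor intervals, are flagged as ectopic/artifactual
#' and replaced by the local median of unflagged neighbors. Series length
#' is preserved; flags mark replaced intervals.
#'
#' @param peaks An `r_peak_series` with at least 3 peaks.
#' @return An object of class `rr_series`: `intervals_ms` and aligned
#'   logical `corrected_flags`.
#' @export
peaks_to_rr <- function(peaks) {
  sf_assert(inherits(peaks, "r_peak_series"), "r_peak_series required")
  sf_assert(length(peaks$sample_indices) >= 3,
            "need at least 3 peaks to form an RR series",
            class = "stressfuse_rr_error")
  rr <- diff(peaks$sample_indices) / peaks$fs * 1000
  m <- length(rr)
  neighbor_median <- function(i, values, use = rep(TRUE, m)) {
    js <- setdiff(order(abs(seq_len(m) - i)), i)
    js <- js[use[js]]
    js <- js[seq_len(min(5, length(js)))]
    if (length(js) == 0) return(NA_real_)
    stats::median(values[js])
  }
  flags <- vapply(seq_len(m), function(i) {
    if (rr[i] <= 250 || rr[i] >= 2500) return(TRUE)
    med <- neighbor_median(i, rr)
    !is.na(med) && abs(rr[i] - med) / med > 0.30
  }, logical(1))
  out <- rr
  if (any(flags) && !all(flags)) {
    for (i in which(flags)) {
      med <- neighbor_median(i, rr, use = !flags)
      if (!is.na(med)) out[i] <- med
    }
  }
  structure(list(intervals_ms = out, corrected_flags = flags),
            class = "rr_series")
}

as_rr <- function(rr) {
  if (inherits(rr, "rr_series")) rr$intervals_ms else as.numeric(rr)
}

#' Time-domain HRV panel (10 features)
#'
#' Population (divide-by-n) variance conventions throughout. pNN
#' percentages use strict inequality (differences *exceeding* the
#' threshold).
#'
#' @param rr An `rr_series` or numeric vector of intervals in ms
#'   (>= 10 intervals).
#' @return Named numeric: mean_nn, median_nn, sdnn, rmssd, sdsd, pnn50,
#'   pnn20, cv_nn, mean_hr, sd_hr.
#' @export
hrv_time_domain <- function(rr) {
  rr <- as_rr(rr)
  sf_assert(length(rr) >= 10, "need at least 10 RR intervals",
            class = "stressfuse_rr_error")
  d <- diff(rr)
  c(mean_nn = mean(rr),
    median_nn = stats::median(rr),
    sdnn = pop_sd(rr),
    rmssd = sqrt(mean(d^2)),
    sdsd = pop_sd(d),
    pnn50 = 100 * mean(abs(d) > 50),
    pnn20 = 100 * mean(abs(d) > 20),
    cv_nn = pop_sd(rr) / mean(rr),
    mean_hr = 60000 / mean(rr),
    sd_hr = pop_sd(60000 / rr))
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-detrended, 50%-overlapping Welch periodogram with
#' one-sided density scaling (units x^2 / Hz).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples (defaults to min(256, length)).
#' @param overlap Fractional overlap between segments.
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = min(256L, length(x)),
                      overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
    p <- p[seq_len(nf)]
    scale <- rep(2, nf); scale[1] <- 1
    if (seg_len %% 2 == 0) scale[nf] <- 1
    acc <- acc + p * scale
  }
  list(freq = seq(0, floor(seg_len / 2)) * fs / seg_len,
       psd = acc / length(starts))
}

band_power <- function(freq, psd, band) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= band[1] & freq < band[2]]) * df
}

#' Frequency-domain HRV panel (8 features)
#'
#' The RR series is cubic-spline interpolated to a uniform 4 Hz tachogram,
#' mean-detrended, and analyzed with a Welch periodogram (64 s windows or
#' the full length if shorter, 50% overlap). Band powers are integrated
#' over VLF 0.0033-0.04, LF 0.04-0.15 and HF 0.15-0.4 Hz.
#'
#' @param rr An `rr_series` or numeric ms vector spanning >= 60 s.
#' @return Named numeric: vlf_power, lf_power, hf_power, total_power,
#'   lf_hf_ratio, lf_nu, hf_nu, hf_peak_freq. Normalized units satisfy
#'   lf_nu + hf_nu = 100 whenever LF + HF > 0.
#' @export
hrv_frequency_domain <- function(rr) {
  rr <- as_rr(rr)
  span <- sum(rr) / 1000
  sf_assert(span >= 60, "RR series must span at least 60 s",
            class = "stressfuse_rr_error")
  t_beat <- cumsum(rr) / 1000
  fs_t <- 4
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / fs_t)
  tach <- stats::spline(t_beat, rr, xout = grid, method = "fmm")$y
  tach <- tach - mean(tach)
  ps <- welch_psd(tach, fs_t, seg_len = min(256L, length(tach)))
  vlf <- band_power(ps$freq, ps$psd, c(0.0033, 0.04))
  lf <- band_power(ps$freq, ps$psd, c(0.04, 0.15))
  hf <- band_power(ps$freq, ps$psd, c(0.15, 0.40))
  hf_idx <- which(ps$freq >= 0.15 & ps$freq < 0.40)
  hf_peak <- if (length(hf_idx) > 0) {
    ps$freq[hf_idx[which.max(ps$psd[hf_idx])]]
  } else NA_real_
  denom <- lf + hf
  c(vlf_power = vlf, lf_power = lf, hf_power = hf,
    total_power = vlf + lf + hf,
    lf_hf_ratio = if (hf > 0) lf / hf else 0,
    lf_nu = if (denom > 0) 100 * lf / denom else 0,
    hf_nu = if (denom > 0) 100 * hf / denom else 0,
    hf_peak_freq = hf_peak)
}

# Sample entropy, m = 2, tolerance r (absolute, same units as x).
sample_entropy <- function(x, m = 2, r) {
  n <- length(x)
  count_matches <- function(mm) {
    n_t <- n - mm + 1
    tmpl <- sapply(seq_len(mm), function(k) x[k:(n_t + k - 1)])
    if (is.null(dim(tmpl))) tmpl <- matrix(tmpl, ncol = mm)
    total <- 0
    for (i in seq_len(n_t - 1)) {
      dmax <- abs(tmpl[(i + 1):n_t, 1] - tmpl[i, 1])
      for (k in seq_len(mm)[-1]) {
        dmax <- pmax(dmax, abs(tmpl[(i + 1):n_t, k] - tmpl[i, k]))
      }
      total <- total + sum(dmax < r)
    }
    total
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Detrended fluctuation analysis slope over the given box-size range.
dfa_alpha <- function(x, box_range) {
  n <- length(x)
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(box_range[1]), log(box_range[2]),
                                length.out = 8))))
  sizes <- sizes[sizes >= 4 & sizes <= floor(n / 2)]
  if (length(sizes) < 3) return(NA_real_)
  fl <- vapply(sizes, function(s) {
    k <- floor(n / s)
    res2 <- 0
    tt <- seq_len(s)
    for (j in seq_len(k)) {
      seg <- y[((j - 1) * s + 1):(j * s)]
      fit <- stats::lm.fit(cbind(1, tt), seg)
      res2 <- res2 + sum(fit$residuals^2)
    }
    sqrt(res2 / (k * s))
  }, numeric(1))
  ok <- fl > 0
  if (sum(ok) < 3) return(NA_real_)
  unname(stats::coef(stats::lm(log(fl[ok]) ~ log(sizes[ok])))[2])
}

#' Nonlinear HRV panel (7 features)
#'
#' Poincare axes from the population variance identity
#' (sd1^2 + sd2^2 = 2 sdnn^2 by construction, sd2 floored at 0), sample
#' entropy with m = 2 and r = 0.2 sdnn, and DFA scaling exponents alpha1
#' (box sizes 4-16) and alpha2 (16-64; NA-coded when the series is too
#' short to support the fit).
#'
#' @param rr An `rr_series` or numeric ms vector. Poincare features need
#'   >= 10 intervals; sample entropy and DFA need >= 100.
#' @return Named numeric: sd1, sd2, sd1_sd2_ratio, ellipse_area, sampen,
#'   dfa_alpha1, dfa_alpha2.
#' @export
hrv_nonlinear <- function(rr) {
  rr <- as_rr(rr)
  sf_assert(length(rr) >= 10,
            "Poincare features need at least 10 intervals",
            class = "stressfuse_rr_error")
  d <- diff(rr)
  sdnn <- pop_sd(rr)
  sd1 <- sqrt(pop_var(d) / 2)
  sd2 <- sqrt(max(2 * sdnn^2 - sd1^2, 0))
  out <- c(sd1 = sd1, sd2 = sd2,
           sd1_sd2_ratio = if (sd2 > 0) sd1 / sd2 else 0,
           ellipse_area = pi * sd1 * sd2,
           sampen = NA_real_, dfa_alpha1 = NA_real_,
           dfa_alpha2 = NA_real_)
  if (length(rr) >= 100) {
    out["sampen"] <- sample_entropy(rr, m = 2, r = 0.2 * sdnn)
    out["dfa_alpha1"] <- dfa_alpha(rr, c(4, 16))
    out["dfa_alpha2"] <- dfa_alpha(rr, c(16, 64))
  } else {
    sf_stop("sampen and DFA need at least 100 intervals",
            class = "stressfuse_rr_error")
  }
  out
}

#' Names and order of the 25-feature HRV panel
#' @return Character vector of length 25.
#' @export
hrv_feature_names <- function() {
  c("mean_nn", "median_nn", "sdnn", "rmssd", "sdsd", "pnn50", "pnn20",
    "cv_nn", "mean_hr", "sd_hr",
    "vlf_power", "lf_power", "hf_power", "total_power", "lf_hf_ratio",
    "lf_nu", "hf_nu", "hf_peak_freq",
    "sd1", "sd2", "sd1_sd2_ratio", "ellipse_area", "sampen",
    "dfa_alpha1", "dfa_alpha2")
}

#' Extract the full 25-feature HRV panel from an ECG segment
#'
#' Bandpasses the segment, detects R-peaks (Pan-Tompkins), builds the
#' corrected RR series, and concatenates the time-domain (10),
#' frequency-domain (8) and nonlinear (7) sub-panels in the fixed
#' documented order. The segment must span at least 60 s; 10 s raw-path
#' windows pair with the panel of their parent recording window.
#'
#' @param segment A single-lead `signal_segment` of >= 60 s.
#' @param rr Optionally, a precomputed `rr_series` (skips detection).
#' @return Named numeric of length 25 (see [hrv_feature_names()]).
#' @export
extract_hrv <- function(segment, rr = NULL) {
  if (is.null(rr)) {
    sf_assert(inherits(segment, "signal_segment"), "signal_segment required")
    sf_assert(ncol(segment$data) / segment$fs >= 60,
              "full HRV panel needs at least 60 s of ECG",
              class = "stressfuse_rr_error")
    filt <- bandpass_ecg(segment)
    peaks <- detect_r_peaks(filt)
    rr <- peaks_to_rr(peaks)
  }
  out <- c(hrv_time_domain(rr), hrv_frequency_domain(rr),
           hrv_nonlinear(rr))
  names(out) <- hrv_feature_names()
  out
}
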