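test_that("ECG bandpass removes wander, keeps R timing, records edges", {
  fs <- 700
  tt <- seq_len(30 * fs) / fs
  wander <- signal_segment(matrix(sin(2 * pi * 0.2 * tt), 1), fs, "ECG",
                           "ECG", "baseline", "S")
  out <- bandpass_ecg(wander)
  mid <- (5 * fs):(25 * fs)
  expect_lt(sqrt(2 * mean(out$data[1, mid]^2)), 0.10)
  expect_equal(attr(out, "band_edges"), c(0.5, 40))

  p <- subject_profile("E1", baseline_hr = 60, seed = 3)
  g <- generate_ecg(p, condition_presets()$baseline, 60, noise_sd = 0,
                    wander = FALSE)
  filt <- bandpass_ecg(g$segment)
  half <- round(0.05 * fs)
  shifts <- vapply(g$r_indices, function(i) {
    lo <- max(1, i - half)
    which.max(filt$data[1, lo:(i + half)]) + lo - 1L - i
  }, numeric(1))
  # zero phase: no systematic delay; peak smoothing can move the sampled
  # argmax by at most one sample (1.4 ms at 700 Hz)
  expect_true(all(abs(shifts) <= 1))
  expect_equal(stats::median(shifts), 0)
  amp_ratio <- max(filt$data) / max(g$segment$data)
  expect_lt(abs(amp_ratio - 1), 0.1) # QRS morphology preserved
})

test_that("Pan-Tompkins finds every beat on clean ECG and degrades gracefully", {
  p <- subject_profile("E1", baseline_hr = 60, seed = 7)
  cs <- condition_presets()
  g <- generate_ecg(p, cs$baseline, 60, noise_sd = 0)
  pk <- detect_r_peaks(bandpass_ecg(g$segment))
  st <- peak_match_stats(pk$sample_indices, g$r_indices, 700, tol_ms = 10)
  expect_equal(unname(st["sensitivity"]), 1.0)
  expect_equal(unname(st["precision"]), 1.0)

  zero <- signal_segment(matrix(0, 1, 7000), 700, "ECG", "ECG",
                         "baseline", "S")
  expect_length(detect_r_peaks(zero)$sample_indices, 0)

  g10 <- generate_ecg(p, cs$baseline, 180, snr_db = 10)
  pk10 <- detect_r_peaks(bandpass_ecg(g10$segment))
  st10 <- peak_match_stats(pk10$sample_indices, g10$r_indices, 700)
  expect_gte(st10["sensitivity"], 0.95)

  slow <- signal_segment(matrix(stats::rnorm(1000), 1), 100, "ECG", "ECG",
                         "baseline", "S")
  expect_error(detect_r_peaks(slow), class = "stressfuse_fs_error")
})

test_that("Pan-Tompkins holds >= 0.95 sensitivity/precision across SNR x HR", {
  cs <- condition_presets()
  for (hr in c(50, 75, 120)) {
    for (snr in list(NULL, 10)) {
      p <- subject_profile("G1", baseline_hr = hr, seed = hr)
      g <- if (is.null(snr)) {
        generate_ecg(p, cs$baseline, 60, noise_sd = 0)
      } else {
        generate_ecg(p, cs$baseline, 60, snr_db = snr)
      }
      pk <- detect_r_peaks(bandpass_ecg(g$segment))
      st <- peak_match_stats(pk$sample_indices, g$r_indices, 700)
      expect_gte(st["sensitivity"], 0.95)
      expect_gte(st["precision"], 0.95)
    }
  }
})

test_that("RR construction and ectopic correction follow the median rule", {
  mk <- function(idx) structure(list(sample_indices = idx, fs = 700),
                                class = "r_peak_series")
  rr <- peaks_to_rr(mk(c(1, 701, 1401)))
  expect_equal(rr$intervals_ms, c(1000, 1000))
  expect_false(any(rr$corrected_flags))

  # a spurious extra peak mid-interval splits one 1000 ms interval into
  # two 500 ms halves; both deviate > 30% from the neighbor median and
  # are replaced by it
  idx <- c(1, 701, 1401, 1751, 2101, 2801, 3501)
  rr2 <- peaks_to_rr(mk(idx))
  expect_length(rr2$intervals_ms, 6)
  expect_equal(rr2$corrected_flags, c(FALSE, FALSE, TRUE, TRUE, FALSE,
                                      FALSE))
  expect_equal(rr2$intervals_ms, rep(1000, 6))

  expect_error(peaks_to_rr(mk(c(1, 701))), class = "stressfuse_rr_error")
})

test_that("time-domain HRV matches closed forms exactly", {
  const <- hrv_time_domain(rep(800, 300))
  expect_equal(unname(const[c("sdnn", "rmssd", "pnn50")]), c(0, 0, 0))
  expect_equal(unname(const["mean_hr"]), 75)

  alt <- hrv_time_domain(rep(c(800, 840), 150))
  expect_equal(unname(alt["rmssd"]), 40, tolerance = 1e-12)
  expect_equal(unname(alt["pnn50"]), 0)
  expect_equal(unname(alt["pnn20"]), 100)
  expect_equal(unname(alt["mean_nn"]), 820)

  # population identity: rmssd^2 = sdsd^2 + mean(diff)^2
  set.seed(4)
  rr <- 800 + cumsum(stats::rnorm(200, 0.5, 20))
  h <- hrv_time_domain(rr)
  expect_lt(abs(h[["rmssd"]]^2 - (h[["sdsd"]]^2 +
                                    mean(diff(rr))^2)), 1e-6)
  expect_error(hrv_time_domain(rep(800, 5)), class = "stressfuse_rr_error")
})

test_that("frequency-domain HRV localizes modulation into the right band", {
  t_approx <- cumsum(rep(0.8, 150))
  rr_lf <- 800 + 40 * sin(2 * pi * 0.10 * t_approx)
  f_lf <- hrv_frequency_domain(rr_lf)
  expect_gt(f_lf[["lf_power"]], 10 * f_lf[["hf_power"]])

  rr_hf <- 800 + 40 * sin(2 * pi * 0.25 * t_approx)
  f_hf <- hrv_frequency_domain(rr_hf)
  expect_lt(abs(f_hf[["hf_peak_freq"]] - 0.25), 0.02)
  expect_gt(f_hf[["hf_power"]], f_hf[["lf_power"]])

  expect_equal(f_lf[["lf_nu"]] + f_lf[["hf_nu"]], 100, tolerance = 1e-9)
  expect_error(hrv_frequency_domain(rep(800, 20)),
               class = "stressfuse_rr_error")
})

test_that("nonlinear HRV: Poincare closed forms, DFA of white noise", {
  const <- hrv_nonlinear(rep(800, 200))
  expect_equal(unname(const[c("sd1", "sd2", "ellipse_area")]), c(0, 0, 0))

  # odd length: successive differences alternate +40/-40 with exact zero
  # mean, so sd1 = sd(diff)/sqrt(2) = 40/sqrt(2) in closed form
  alt <- hrv_nonlinear(rep(c(800, 840), length.out = 201))
  expect_equal(unname(alt["sd1"]), 40 / sqrt(2), tolerance = 1e-9)

  # Poincare identity by construction of sd2
  set.seed(8)
  rr <- 900 + cumsum(stats::rnorm(300, 0, 15))
  h <- hrv_nonlinear(rr)
  sdnn <- stressfuse:::pop_sd(rr)
  expect_lt(abs(h[["sd1"]]^2 + h[["sd2"]]^2 - 2 * sdnn^2) / (2 * sdnn^2),
            1e-6)

  # iid RR has DFA alpha1 ~ 0.5
  a1 <- vapply(1:50, function(s) {
    set.seed(s)
    hrv_nonlinear(stats::rnorm(300, 800, 30))[["dfa_alpha1"]]
  }, numeric(1))
  expect_lt(abs(mean(a1) - 0.5), 0.1)

  expect_error(hrv_nonlinear(stats::rnorm(50, 800, 30)),
               class = "stressfuse_rr_error")
})

test_that("HRV features scale with the RR series (c = 2 toy case)", {
  set.seed(11)
  rr <- 800 + stats::rnorm(150, 0, 30)
  h1 <- hrv_time_domain(rr)
  h2 <- hrv_time_domain(2 * rr)
  for (f in c("sdnn", "rmssd", "sdsd")) {
    expect_equal(unname(h2[f]), 2 * unname(h1[f]), tolerance = 1e-12)
  }
  n1 <- hrv_nonlinear(rr)[c("sd1", "sd2")]
  n2 <- hrv_nonlinear(2 * rr)[c("sd1", "sd2")]
  expect_equal(unname(n2), 2 * unname(n1), tolerance = 1e-9)
  # pnn50 of the doubled series equals pnn25-type count of the original
  expect_equal(unname(h2["pnn50"]), 100 * mean(abs(diff(rr)) > 25))
})

test_that("extract_hrv returns the fixed 25-feature panel and encodes stress", {
  p <- subject_profile("H1", baseline_hr = 62, seed = 2)
  cs <- condition_presets()
  g <- generate_ecg(p, cs$baseline, 120)
  h <- extract_hrv(g$segment)
  expect_length(h, 25)
  expect_identical(names(h), hrv_feature_names())
  expect_true(all(is.finite(h)))

  short <- signal_segment(matrix(stats::rnorm(7000), 1), 700, "ECG", "ECG",
                          "baseline", "S")
  expect_error(extract_hrv(short), class = "stressfuse_rr_error")

  d <- vapply(1:30, function(s) {
    ps <- subject_profile(sprintf("H%d", s), baseline_hr = 62, seed = s)
    hs <- extract_hrv(generate_ecg(ps, cs$stress, 120, seed = s)$segment)
    hb <- extract_hrv(generate_ecg(ps, cs$baseline, 120, seed = s)$segment)
    expect_true(all(is.finite(hs)) && all(is.finite(hb)))
    hs[["rmssd"]] - hb[["rmssd"]]
  }, numeric(1))
  expect_lt(mean(d), 0) # stress lowers RMSSD
})
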