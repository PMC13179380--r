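test_that("Butterworth bandpass matches analytic magnitude responses", {
  fs <- 700
  tt <- seq_len(14000) / fs
  mid <- 3500:10500
  amp <- function(x) sqrt(2 * mean(x[mid]^2))
  mk <- function(v) signal_segment(matrix(rep(v, each = 14), 14), fs,
                                   eeg_montage(), "EEG", "baseline", "S")
  # DC is below the 0.5 Hz edge
  dc <- bandpass_eeg(mk(rep(1, 14000)))
  expect_lt(max(abs(dc$data[1, mid])), 1e-3)
  # 10 Hz sits mid-band: unit amplitude preserved within 2%
  s10 <- bandpass_eeg(mk(sin(2 * pi * 10 * tt)))
  expect_lt(abs(amp(s10$data[1, ]) - 1), 0.02)
  # 100 Hz is deep in the stopband of the squared 4th-order design
  s100 <- bandpass_eeg(mk(sin(2 * pi * 100 * tt)))
  expect_lt(amp(s100$data[1, ]), 0.05)
  # band edges above Nyquist are rejected
  expect_error(bandpass_eeg(mk(sin(tt)), filter_spec(0.5, 400)),
               class = "stressfuse_band_error")
})

test_that("bandpass filtering is linear", {
  p <- fixture_profile()
  seg <- generate_eeg(p, condition_presets()$baseline, 10)
  seg3 <- seg
  seg3$data <- 3 * seg$data
  y1 <- bandpass_eeg(seg)$data
  y3 <- bandpass_eeg(seg3)$data
  expect_lt(max(abs(y3 - 3 * y1)) / max(abs(y3)), 1e-8)
})

test_that("common average referencing: algebra, idempotence, guards", {
  fs <- 700
  same <- signal_segment(matrix(5, 14, 100), fs, eeg_montage(), "EEG",
                         "baseline", "S")
  expect_true(all(common_average_reference(same)$data == 0))

  pm <- matrix(c(1, -1), 2, 50) # two channels at +1 / -1: mean is zero
  expect_equal(common_average_reference(pm), pm)

  p <- fixture_profile()
  seg <- generate_eeg(p, condition_presets()$baseline, 10)
  car1 <- common_average_reference(seg)
  expect_lt(max(abs(colMeans(car1$data))), 1e-10)
  car2 <- common_average_reference(car1)
  expect_lt(max(abs(car2$data - car1$data)), 1e-10)

  expect_error(common_average_reference(matrix(1, 1, 100)),
               class = "stressfuse_channel_error")
})

test_that("epoching: floor division, no boundary crossing, guards", {
  p <- fixture_profile()
  cs <- condition_presets()
  seg35 <- generate_eeg(p, cs$baseline, 35)
  es <- epoch_segments(list(seg35))
  expect_length(es$epochs, 3)
  expect_true(all(vapply(es$epochs, ncol, numeric(1)) == 7000))
  expect_equal(es$labels, rep("baseline", 3))

  es1 <- epoch_segments(generate_eeg(p, cs$baseline, 10))
  expect_length(es1$epochs, 1)

  two <- list(generate_eeg(p, cs$baseline, 20),
              generate_eeg(p, cs$stress, 20, seed = 1))
  es2 <- epoch_segments(two)
  expect_length(es2$epochs, 4)
  expect_equal(es2$source_ids, c(1, 1, 2, 2))
  # epochs re-concatenated reproduce each source segment exactly: no
  # epoch mixes samples across segments
  expect_identical(cbind(es2$epochs[[1]], es2$epochs[[2]]),
                   two[[1]]$data[, 1:14000])

  short <- generate_eeg(p, cs$baseline, 10)
  short$data <- short$data[, 1:3500]
  expect_error(epoch_segments(list(short)),
               class = "stressfuse_epoch_error")
})

test_that("ICA flags nothing on clean data and removes injected blinks", {
  p <- fixture_profile(seed = 5)
  cs <- condition_presets()
  # artifact-free recordings: no component flagged in >= 90%
  flags <- vapply(1:10, function(s) {
    seg <- generate_eeg(p, cs$baseline, 10, seed = 100 + s, blink_rate = 0)
    cl <- suppressWarnings(remove_artifacts_ica(epoch_segments(list(seg))))
    attr(cl, "rejection_report")$n_flagged[1]
  }, integer(1))
  expect_gte(mean(flags == 0), 0.9)

  # blink-laden recordings: frontal 0.5-4 Hz power reduced by >= 50%
  frontal <- which(eeg_montage() %in% c("AF3", "F7", "F3", "F4", "F8",
                                        "AF4"))
  slow_power <- function(ep) {
    mean(apply(ep[frontal, ], 1, function(ch) {
      ps <- welch_psd(ch, 700, seg_len = 2048)
      df <- ps$freq[2] - ps$freq[1]
      sum(ps$psd[ps$freq >= 0.5 & ps$freq < 4]) * df
    }))
  }
  reductions <- vapply(c(1, 2, 4), function(s) {
    seg <- generate_eeg(p, cs$baseline, 10, seed = s, blink_rate = 0.5)
    es <- epoch_segments(list(seg))
    cl <- suppressWarnings(remove_artifacts_ica(es))
    1 - slow_power(cl$epochs[[1]]) / slow_power(es$epochs[[1]])
  }, numeric(1))
  expect_true(all(reductions >= 0.5))

  # thresholds at infinity: nothing flagged, output identical
  seg <- generate_eeg(p, cs$baseline, 10, seed = 1, blink_rate = 0.5)
  es <- epoch_segments(list(seg))
  cl <- suppressWarnings(
    remove_artifacts_ica(es, ica_policy(blink_cor = Inf,
                                        kurtosis_max = Inf)))
  expect_identical(cl$epochs, es$epochs)
  expect_equal(attr(cl, "rejection_report")$n_flagged, 0L)
})

test_that("Morlet scalograms localize tones in frequency and band", {
  sc <- band_scalogram(tone_epoch(6), c(4, 8))
  expect_equal(dim(sc), c(128, 128))
  fr <- attr(sc, "frequencies")
  expect_lt(abs(fr[which.max(rowMeans(sc))] - 6), 0.5)

  expect_true(all(band_scalogram(matrix(0, 14, 7000), c(4, 8)) == 0))
  expect_error(band_scalogram(tone_epoch(6), c(10, 400)),
               class = "stressfuse_band_error")

  # 6 / 10 / 20 Hz tones put maximal energy in theta / alpha / beta
  for (i in seq_along(c(6, 10, 20))) {
    img <- build_scalogram_image(tone_epoch(c(6, 10, 20)[i]))
    expect_equal(dim(img$pixels), c(128, 128, 3))
    expect_identical(img$band_order, c("theta", "alpha", "beta"))
    expect_equal(which.max(apply(img$pixels, 3, mean)), i)
  }
})

test_that("stress epochs carry more theta-plane energy than baseline", {
  p <- fixture_profile()
  cs <- condition_presets()
  d <- vapply(1:30, function(s) {
    ths <- band_scalogram(generate_eeg(p, cs$stress, 10, seed = s)$data,
                          c(4, 8))
    thb <- band_scalogram(generate_eeg(p, cs$baseline, 10, seed = s)$data,
                          c(4, 8))
    mean(ths) - mean(thb)
  }, numeric(1))
  expect_gt(mean(d), 0)
  expect_gte(mean(d > 0), 0.9)
})

test_that("standardizer: z-scoring on train, no refit, zero-variance guard", {
  p <- fixture_profile()
  cs <- condition_presets()
  imgs <- lapply(1:4, function(s) {
    build_scalogram_image(generate_eeg(p, cs$baseline, 10, seed = s)$data)
  })
  st <- fit_standardizer(imgs)
  out <- apply_standardizer(imgs, st)
  arr <- stressfuse:::images_to_array(out)
  for (b in 1:3) {
    expect_lt(abs(mean(arr[, , , b])), 1e-6)
    expect_lt(abs(stressfuse:::pop_sd(as.numeric(arr[, , , b])) - 1), 1e-6)
  }
  # applying to held-out images uses the same params (no refit): params
  # untouched and held-out mean freely nonzero
  held <- lapply(5:6, function(s) {
    build_scalogram_image(generate_eeg(p, cs$stress, 10, seed = s)$data)
  })
  st_before <- unclass(st)
  out2 <- apply_standardizer(held, st)
  expect_identical(unclass(st), st_before)
  arr2 <- stressfuse:::images_to_array(out2)
  expect_gt(abs(mean(arr2[, , , 1])), 1e-8)

  flat <- lapply(imgs, function(im) { im$pixels[, , 2] <- 1; im })
  expect_error(fit_standardizer(flat), class = "stressfuse_variance_error")
})

test_that("pipeline shape contract: k epochs of (s, s, 3) per segment", {
  p <- fixture_profile()
  seg <- generate_eeg(p, condition_presets()$baseline, 20)
  es <- epoch_segments(list(common_average_reference(bandpass_eeg(seg))))
  expect_length(es$epochs, 2)
  imgs <- lapply(es$epochs, build_scalogram_image, fs = es$fs,
                 n_freq = 64, n_time = 64)
  expect_true(all(vapply(imgs, function(im) {
    identical(dim(im$pixels), c(64L, 64L, 3L))
  }, logical(1))))
})
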