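#' Bandpass filter specification
#'
#' @param low_hz,high_hz Band edges in Hz (0 < low < high < fs/2).
#' @param order Butterworth design order (applied forward and backward, so
#'   the effective magnitude response is the squared design).
#' @param zero_phase Apply forward-backward (filtfilt) filtering.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 45, order = 4,
                        zero_phase = TRUE) {
  sf_assert(low_hz > 0 && high_hz > low_hz,
            "need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

# Zero-phase Butterworth bandpass. The forward-backward pass of an LTI
# filter is equivalent to applying its squared magnitude response, which is
# evaluated here in factored pole-zero form (numerically stable even for
# low band edges where the direct-form recursion loses precision) and
# applied in the frequency domain with reflection padding.
apply_butter <- function(x, fs, spec) {
  sf_assert(spec$high_hz < fs / 2,
            "band edges must lie below the Nyquist frequency",
            class = "stressfuse_band_error")
  filt <- signal::butter(spec$order,
                         c(spec$low_hz, spec$high_hz) / (fs / 2),
                         type = "pass")
  if (!spec$zero_phase) {
    return(t(apply(x, 1, function(v) {
      as.numeric(signal::filter(filt, v))
    })))
  }
  zpg <- signal::as.Zpg(filt)
  n <- ncol(x)
  pad <- min(n, ceiling(2 / spec$low_hz * fs))
  nfft <- 2^ceiling(log2(n + 2 * pad))
  e <- exp(2i * pi * seq(0, nfft - 1) / nfft)
  mag2 <- rep(zpg$gain^2, nfft)
  for (z in zpg$zero) mag2 <- mag2 * Mod(e - z)^2
  for (p in zpg$pole) mag2 <- mag2 / Mod(e - p)^2
  t(apply(x, 1, function(v) {
    vp <- c(rev(v[seq_len(pad)]), v, rev(v[(n - pad + 1):n]))
    V <- stats::fft(c(vp, numeric(nfft - length(vp))))
    y <- Re(stats::fft(V * mag2, inverse = TRUE)) / nfft
    y[pad + seq_len(n)]
  }))
}

#' Zero-phase Butterworth bandpass for EEG
#'
#' Forward-backward application of a Butterworth bandpass (default
#' 0.5-45 Hz, order 4), preserving phase relationships across channels.
#' Output length equals input length.
#'
#' @param segment A `signal_segment`.
#' @param spec A `filter_spec`; defaults to the 0.5-45 Hz EEG band.
#' @return Filtered `signal_segment` with band edges recorded in
#'   `attr(, "band_edges")`.
#' @export
bandpass_eeg <- function(segment, spec = filter_spec(0.5, 45, 4)) {
  sf_assert(inherits(segment, "signal_segment"), "signal_segment required")
  out <- segment
  out$data <- apply_butter(segment$data, segment$fs, spec)
  attr(out, "band_edges") <- c(spec$low_hz, spec$high_hz)
  out
}

#' Common average referencing
#'
#' Subtracts the instantaneous across-channel mean from every channel, so
#' the across-channel mean of the output is exactly zero at every sample.
#' Idempotent.
#'
#' @param segment A multichannel `signal_segment` (>= 2 channels), or a
#'   channels x samples matrix.
#' @return Re-referenced object of the same type as the input.
#' @export
common_average_reference <- function(segment) {
  x <- if (inherits(segment, "signal_segment")) segment$data else segment
  sf_assert(is.matrix(x), "signal_segment or matrix required")
  sf_assert(nrow(x) >= 2,
            "common average reference needs at least 2 channels",
            class = "stressfuse_channel_error")
  y <- sweep(x, 2, colMeans(x))
  if (inherits(segment, "signal_segment")) {
    segment$data <- y
    segment
  } else y
}

#' Split segments into non-overlapping fixed-length epochs
#'
#' Each segment contributes floor(duration / epoch_seconds) epochs; any
#' trailing remainder is discarded, and no epoch spans two source segments.
#' Labels and subject ids propagate to every epoch.
#'
#' @param segments A `signal_segment` or list of them.
#' @param epoch_seconds Epoch length in seconds (default 10).
#' @return An object of class `epoch_set` with fields `epochs` (list of
#'   channels x samples matrices), `fs`, `epoch_length`, `labels`,
#'   `subject_ids`, `source_ids`.
#' @export
epoch_segments <- function(segments, epoch_seconds = 10) {
  if (inherits(segments, "signal_segment")) segments <- list(segments)
  sf_assert(length(segments) > 0, "no segments supplied")
  fs <- segments[[1]]$fs
  n_epoch <- round(epoch_seconds * fs)
  epochs <- list(); labels <- character(0); subs <- character(0)
  src <- integer(0)
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    sf_assert(s$fs == fs, "all segments must share one sampling rate")
    k <- ncol(s$data) %/% n_epoch
    if (k < 1) {
      sf_stop(sprintf(
        "segment %d (%s, %.1f s) is shorter than one %g s epoch",
        i, s$subject_id, ncol(s$data) / fs, epoch_seconds),
        class = "stressfuse_epoch_error")
    }
    for (j in seq_len(k)) {
      idx <- ((j - 1) * n_epoch + 1):(j * n_epoch)
      epochs[[length(epochs) + 1]] <- s$data[, idx, drop = FALSE]
      labels <- c(labels, s$label)
      subs <- c(subs, s$subject_id)
      src <- c(src, i)
    }
  }
  structure(list(epochs = epochs, fs = fs, epoch_length = epoch_seconds,
                 labels = labels, subject_ids = subs, source_ids = src),
            class = "epoch_set")
}

# FastICA: negentropy-maximizing fixed-point estimation (logcosh contrast),
# deflationary extraction with Gram-Schmidt decorrelation; deterministic
# under `seed`. When a reference time course is supplied (targeted artifact
# extraction), the first component is fixed to the whitened regression
# direction of that reference, and deflation runs on the orthogonal
# complement. Once a component fails to converge, the remaining
# (near-Gaussian) subspace is completed with an orthonormal basis, since a
# rotation within a Gaussian subspace is unidentifiable anyway.
fastica_deflation <- function(X, n_comp = nrow(X), seed = 42,
                              max_iter = 200, tol = 1e-6,
                              init_signal = NULL) {
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  keep <- which(eg$values > 1e-12 * max(eg$values))[seq_len(n_comp)]
  K <- diag(1 / sqrt(eg$values[keep]), length(keep)) %*% t(eg$vectors[, keep])
  Z <- K %*% Xc
  m <- nrow(Z)
  W0 <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(m * m), m, m))))
  W <- matrix(0, m, m)
  n_conv <- 0
  first <- 1
  if (!is.null(init_signal)) {
    v <- as.numeric(Z %*% (init_signal - mean(init_signal)))
    if (sqrt(sum(v^2)) > 1e-12) {
      W[1, ] <- v / sqrt(sum(v^2)) # template component, kept as-is
      n_conv <- 1
      first <- 2
    }
  }
  for (comp in seq(first, m)) {
    w <- W0[, comp]
    if (comp > 1) {
      w <- as.numeric(w - t(W[seq_len(comp - 1), , drop = FALSE]) %*%
                        (W[seq_len(comp - 1), , drop = FALSE] %*% w))
    }
    w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      s <- as.numeric(w %*% Z)
      g <- tanh(s)
      wn <- as.numeric(Z %*% g) / n - mean(1 - g^2) * w
      if (comp > 1) {
        wn <- wn - t(W[seq_len(comp - 1), , drop = FALSE]) %*%
          (W[seq_len(comp - 1), , drop = FALSE] %*% wn)
        wn <- as.numeric(wn)
      }
      nrm <- sqrt(sum(wn^2))
      if (nrm < 1e-12) break
      wn <- wn / nrm
      delta <- abs(abs(sum(wn * w)) - 1)
      w <- wn
      if (delta < tol) { ok <- TRUE; break }
    }
    W[comp, ] <- w
    if (!ok) {
      # complete the residual subspace orthonormally and stop extracting
      if (comp < m) {
        proj <- diag(m) - t(W[seq_len(comp), , drop = FALSE]) %*%
          W[seq_len(comp), , drop = FALSE]
        basis <- svd(proj)$u[, seq_len(m - comp), drop = FALSE]
        W[(comp + 1):m, ] <- t(basis)
      }
      break
    }
    n_conv <- comp
  }
  W_full <- W %*% K              # unmixing in sensor space: S = W_full Xc
  A <- MASS_ginv(W_full)         # mixing: Xc ~ A S
  list(S = W_full %*% Xc, A = A, W = W_full, mu = mu,
       converged = n_conv >= 1, n_converged = n_conv)
}

# Moore-Penrose pseudoinverse via SVD (tiny matrices only).
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

#' ICA rejection policy
#'
#' Components are flagged when their time course correlates with a
#' 0.5-4 Hz frontal-average blink proxy beyond `blink_cor`, or when their
#' kurtosis exceeds `kurtosis_max` (a Gaussian source has kurtosis 3;
#' transient artifacts are strongly leptokurtic).
#'
#' @param blink_cor Absolute-correlation threshold with the blink proxy.
#' @param kurtosis_max Raw kurtosis threshold.
#' @param seed Seed for the ICA fixed-point initialization.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return A list usable as the `policy` of [remove_artifacts_ica()].
#' @export
ica_policy <- function(blink_cor = 0.7, kurtosis_max = 8, seed = 42,
                       max_iter = 200, tol = 1e-6) {
  list(blink_cor = blink_cor, kurtosis_max = kurtosis_max, seed = seed,
       max_iter = max_iter, tol = tol)
}

#' ICA-based artifact removal
#'
#' Estimates an unmixing matrix per recording (epochs sharing a source
#' segment are concatenated), flags components by the rejection policy
#' (blink-proxy correlation or kurtosis), zeroes flagged components and
#' remixes. Non-convergent recordings are passed through unmodified with a
#' warning and are marked in the report.
#'
#' @param epoch_set An `epoch_set`.
#' @param policy A policy list from [ica_policy()].
#' @return The cleaned `epoch_set`, with a `rejection_report` attribute:
#'   a data.frame with one row per recording (columns `recording`,
#'   `n_flagged`, `converged`, `flagged`).
#' @export
remove_artifacts_ica <- function(epoch_set, policy = ica_policy()) {
  sf_assert(inherits(epoch_set, "epoch_set"), "epoch_set required")
  fs <- epoch_set$fs
  out <- epoch_set
  recs <- unique(epoch_set$source_ids)
  report <- data.frame(recording = recs, n_flagged = 0L,
                       converged = TRUE, flagged = "",
                       stringsAsFactors = FALSE)
  frontal_idx <- which(eeg_montage() %in% frontal_channels())
  # order 2: higher-order transfer-function designs are numerically
  # unstable for this narrow low band at 700 Hz
  lp <- signal::butter(2, c(0.5, 4) / (fs / 2), type = "pass")
  for (ri in seq_along(recs)) {
    idx <- which(epoch_set$source_ids == recs[ri])
    X <- do.call(cbind, epoch_set$epochs[idx])
    sf_assert(ncol(X) >= 14 * nrow(X), "too few samples for ICA")
    proxy0 <- signal::filtfilt(lp, colMeans(X[frontal_idx, , drop = FALSE]))
    ica <- fastica_deflation(X, seed = policy$seed,
                             max_iter = policy$max_iter, tol = policy$tol,
                             init_signal = proxy0)
    if (!ica$converged) {
      warning(sprintf("ICA did not converge for recording %d; passing through",
                      recs[ri]))
      report$converged[ri] <- FALSE
      next
    }
    proxy <- proxy0
    kurt <- apply(ica$S, 1, function(s) {
      s <- s - mean(s); mean(s^4) / (mean(s^2)^2)
    })
    cors <- abs(apply(ica$S, 1, function(s) stats::cor(s, proxy)))
    flagged <- which(cors > policy$blink_cor | kurt > policy$kurtosis_max)
    report$n_flagged[ri] <- length(flagged)
    report$flagged[ri] <- paste(flagged, collapse = ",")
    if (length(flagged) > 0) {
      keep <- setdiff(seq_len(nrow(ica$S)), flagged)
      Xc_hat <- ica$A[, keep, drop = FALSE] %*% ica$S[keep, , drop = FALSE]
      X_hat <- Xc_hat + ica$mu
      n_epoch <- ncol(epoch_set$epochs[[idx[1]]])
      for (j in seq_along(idx)) {
        cols <- ((j - 1) * n_epoch + 1):(j * n_epoch)
        out$epochs[[idx[j]]] <- X_hat[, cols, drop = FALSE]
      }
    }
  }
  attr(out, "rejection_report") <- report
  out
}

# Morlet wavelet filter bank in the frequency domain (analytic, L2-ish
# normalized following the standard convention). Only the first `n_rows`
# frequency bins of the length-`nfft` grid are materialized: the analytic
# Gaussian support of every filter must fit below row n_rows.
morlet_filter_bank <- function(freqs, nfft, fs, omega0 = 6,
                               n_rows = nfft) {
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs)
  w <- 2 * pi * fs * seq(0, n_rows - 1) / nfft
  H <- matrix(0, n_rows, length(freqs))
  pos <- w > 0
  for (j in seq_along(freqs)) {
    H[pos, j] <- sqrt(2 * pi * scales[j] * fs) * pi^(-0.25) *
      exp(-(scales[j] * w[pos] - omega0)^2 / 2)
  }
  list(H = H, freqs = freqs, scales = scales)
}

#' Band-limited Morlet scalogram plane
#'
#' Computes the continuous wavelet transform (Morlet, center frequency
#' `omega0`) of every channel on `n_freq` log-spaced frequencies spanning
#' the band, averages squared magnitude across channels, reduces the time
#' axis to `n_time` bins by non-overlapping window averaging, and applies
#' log(1 + power) compression.
#'
#' @param epoch channels x samples numeric matrix.
#' @param band c(f_lo, f_hi) in Hz, inside (0, fs/2).
#' @param fs Sampling rate in Hz.
#' @param n_freq,n_time Output grid (rows = frequency, low to high;
#'   columns = time).
#' @param omega0 Morlet center frequency (dimensionless).
#' @return n_freq x n_time matrix with frequencies as
#'   `attr(, "frequencies")`.
#' @export
band_scalogram <- function(epoch, band, fs = 700, n_freq = 128,
                           n_time = 128, omega0 = 6) {
  if (is.numeric(epoch) && !is.matrix(epoch)) epoch <- matrix(epoch, 1)
  sf_assert(band[1] > 0 && band[2] > band[1] && band[2] < fs / 2,
            "band must lie inside (0, fs/2)",
            class = "stressfuse_band_error")
  n <- ncol(epoch)
  nfft <- 2^ceiling(log2(n))
  freqs <- exp(seq(log(band[1]), log(band[2]), length.out = n_freq))
  # The analytic Morlet filters are band-limited (Gaussian support below
  # ~2 * f_hi), so the complex CWT can be synthesized exactly at a
  # decimated rate by inverse-transforming only the occupied low-frequency
  # block of the spectrum (spectral folding with all upper blocks zero).
  decim <- max(1, 2^floor(log2(fs / (4 * band[2]))))
  while (nfft / decim < 4 * n_time && decim > 1) decim <- decim / 2
  nfft_d <- nfft / decim
  fb <- morlet_filter_bank(freqs, nfft, fs, omega0, n_rows = nfft_d)
  n_d <- ceiling(n / decim) # decimated samples covering the epoch
  pw <- matrix(0, n_d, n_freq)
  for (k in seq_len(nrow(epoch))) {
    xf <- stats::fft(c(epoch[k, ], numeric(nfft - n)))
    Z <- stats::mvfft(fb$H * xf[seq_len(nfft_d)], inverse = TRUE) / nfft
    Z <- Z[seq_len(n_d), , drop = FALSE]
    pw <- pw + Re(Z)^2 + Im(Z)^2
  }
  pw <- pw / nrow(epoch)
  # non-overlapping time-bin averaging onto the n_time grid
  bounds <- round(seq(0, n_d, length.out = n_time + 1))
  A <- matrix(0, n_time, n_d)
  for (t in seq_len(n_time)) {
    cols <- (bounds[t] + 1):bounds[t + 1]
    A[t, cols] <- 1 / length(cols)
  }
  out <- t(A %*% pw) # n_freq x n_time
  out <- log1p(out)
  attr(out, "frequencies") <- freqs
  out
}

#' Default scalogram bands
#' @return Named list of c(lo, hi) band edges for theta, alpha, beta.
#' @export
scalogram_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Build the 3-band scalogram image of one EEG epoch
#'
#' Stacks the theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz)
#' [band_scalogram()] planes, in that order, into a 128 x 128 x 3 image.
#'
#' @param epoch channels x samples matrix (one 10 s, 14-channel epoch).
#' @inheritParams band_scalogram
#' @param meta Optional source reference stored with the image.
#' @return An object of class `scalogram_image` with fields `pixels`
#'   (128 x 128 x 3 array, rows = frequency, columns = time), `band_order`,
#'   and `meta`.
#' @export
build_scalogram_image <- function(epoch, fs = 700, n_freq = 128,
                                  n_time = 128, omega0 = 6, meta = NULL) {
  bands <- scalogram_bands()
  px <- array(0, c(n_freq, n_time, 3))
  for (b in seq_along(bands)) {
    px[, , b] <- band_scalogram(epoch, bands[[b]], fs = fs, n_freq = n_freq,
                                n_time = n_time, omega0 = omega0)
  }
  structure(list(pixels = px, band_order = names(bands), meta = meta),
            class = "scalogram_image")
}

images_to_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (inherits(images, "scalogram_image")) images <- list(images)
  d <- dim(images[[1]]$pixels)
  arr <- array(0, c(length(images), d))
  for (i in seq_along(images)) arr[i, , , ] <- images[[i]]$pixels
  arr
}

#' Fit per-band standardization parameters on training images
#'
#' Computes the per-band (theta/alpha/beta) pixel mean and population SD
#' over a set of scalogram images. By contract these parameters are
#' estimated on training-split images only; [apply_standardizer()] never
#' refits.
#'
#' @param train_images List of `scalogram_image` objects (or an
#'   N x H x W x 3 array).
#' @param provenance Optional tag recording which split/cohort the
#'   parameters came from.
#' @return An object of class `standardizer` with `mean` and `sd` (length-3
#'   named vectors).
#' @export
fit_standardizer <- function(train_images, provenance = "train") {
  arr <- images_to_array(train_images)
  bands <- c("theta", "alpha", "beta")
  mu <- sdv <- stats::setNames(numeric(3), bands)
  for (b in 1:3) {
    v <- as.numeric(arr[, , , b])
    mu[b] <- mean(v)
    sdv[b] <- pop_sd(v)
    if (sdv[b] <= 0) {
      sf_stop(sprintf("zero variance in %s band; cannot standardize",
                      bands[b]),
              class = "stressfuse_variance_error")
    }
  }
  structure(list(mean = mu, sd = sdv, provenance = provenance),
            class = "standardizer")
}

#' Apply fitted standardization to images
#'
#' @param images List of `scalogram_image` objects or an N x H x W x 3
#'   array.
#' @param params A `standardizer` from [fit_standardizer()].
#' @return Same structure as the input, with (x - mean) / sd applied per
#'   band.
#' @export
apply_standardizer <- function(images, params) {
  sf_assert(inherits(params, "standardizer"), "standardizer required")
  std1 <- function(px) {
    for (b in 1:3) px[, , b] <- (px[, , b] - params$mean[b]) / params$sd[b]
    px
  }
  if (is.array(images) && length(dim(images)) == 4) {
    for (b in 1:3) {
      images[, , , b] <- (images[, , , b] - params$mean[b]) / params$sd[b]
    }
    return(images)
  }
  if (inherits(images, "scalogram_image")) {
    images$pixels <- std1(images$pixels)
    return(images)
  }
  lapply(images, function(im) { im$pixels <- std1(im$pixels); im })
}
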