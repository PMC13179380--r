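# Shared fixtures, memoized across test files within one session (heavy
# synthetic cohorts and their preprocessed tensors are built once).

sf_test_cache <- function() {
  if (!exists(".stressfuse_test_cache", envir = globalenv())) {
    assign(".stressfuse_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".stressfuse_test_cache", envir = globalenv())
}

fixture_profile <- function(hr = 62, seed = 7) {
  subject_profile("T01", baseline_hr = hr, seed = seed)
}

# 10-subject easy-separation cohort + test-profile tensors (the end-to-end
# study conditions)
easy_cohort <- function() {
  cache <- sf_test_cache()
  if (is.null(cache$easy_cohort)) {
    cache$easy_cohort <- generate_cohort(10, per_condition_segments = 2,
                                         seed = 42, difficulty = "easy")
  }
  cache$easy_cohort
}

easy_prep <- function() {
  cache <- sf_test_cache()
  if (is.null(cache$easy_prep)) {
    cache$easy_prep <- prepare_cohort(easy_cohort(), model_profile("test"))
  }
  cache$easy_prep
}

# tone epoch: one frequency on all 14 channels
tone_epoch <- function(freq, n = 7000, fs = 700) {
  tt <- seq_len(n) / fs
  matrix(rep(sin(2 * pi * freq * tt), each = 14), 14)
}

# sensitivity/precision of detected peaks vs ground truth
peak_match_stats <- function(detected, truth, fs, tol_ms = 50) {
  tol <- round(tol_ms / 1000 * fs)
  if (length(detected) == 0) return(c(sensitivity = 0, precision = 0))
  d <- outer(detected, truth, function(a, b) abs(a - b))
  c(sensitivity = mean(apply(d, 2, min) <= tol),
    precision = mean(apply(d, 1, min) <= tol))
}
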