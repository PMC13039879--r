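# Brute-force reference implementations, written independently of the
# package internals (explicit loops, base R only). They define the expected
# behaviour for the oracle-equivalence suites.

# dilation-speed MAD filter: plain-loop re-implementation
brute_dilation_filter <- function(t, x, valid, k = 3, passes = 2) {
  for (pass in seq_len(passes)) {
    v <- which(valid)
    if (length(v) < 3) break
    m <- length(v)
    d <- numeric(m)
    for (j in seq_len(m)) {
      back <- if (j > 1)
        abs(x[v[j]] - x[v[j - 1]]) / (t[v[j]] - t[v[j - 1]]) else NA
      fwd <- if (j < m)
        abs(x[v[j + 1]] - x[v[j]]) / (t[v[j + 1]] - t[v[j]]) else NA
      d[j] <- max(back, fwd, na.rm = TRUE)
    }
    med <- median(d)
    mad_u <- median(abs(d - med)) # unscaled MAD
    thr <- med + k * mad_u
    bad <- d > thr
    if (!any(bad)) break
    valid[v[bad]] <- FALSE
  }
  valid
}

# windowed extremum with +/- half_width ms mean, earliest tie-break
brute_peak <- function(w, t, window, polarity = "negative",
                       half_width = 4) {
  best <- NA
  for (i in seq_along(w)) {
    if (t[i] < window[1] || t[i] > window[2]) next
    if (is.na(best)) { best <- i; next }
    if (polarity == "negative" && w[i] < w[best]) best <- i
    if (polarity == "positive" && w[i] > w[best]) best <- i
  }
  sel <- c()
  for (i in seq_along(w))
    if (abs(t[i] - t[best]) <= half_width + 1e-9) sel <- c(sel, i)
  list(amp = mean(w[sel]), lat = t[best])
}

# random two-eye series with spikes, gaps and out-of-range excursions
random_pupil_series <- function(n = 600, rate = 300) {
  t <- (seq_len(n) - 1) * 1000 / rate
  base <- runif(1, 3, 6)
  mk_eye <- function() {
    x <- base + cumsum(rnorm(n, 0, 0.01)) + rnorm(n, 0, 0.03)
    n_spk <- rpois(1, 2)
    if (n_spk > 0) {
      pos <- sample.int(n, n_spk)
      x[pos] <- x[pos] + sample(c(-1, 1), n_spk, TRUE) * runif(n_spk, 0.5, 2)
    }
    n_gap <- rpois(1, 1.5)
    for (g in seq_len(n_gap)) {
      len <- sample(5:80, 1)
      s <- sample.int(n - len, 1)
      x[s:(s + len - 1)] <- NA
    }
    if (runif(1) < 0.2) x[sample.int(n, 3)] <- runif(3, 8.1, 9) # out of range
    x
  }
  pupil_series(t, mk_eye(), mk_eye())
}

# zero-effect generator world (no noise, artifacts, or condition effects)
params_noise_free <- function(...) {
  generator_params(
    pupil_noise_sd_mm = 0, blink_rate_per_min = 0,
    artifact_spike_rate_per_min = 0, sepr_trial_sd_mm = 0,
    erp_trial_sd_uv = 0, eeg_pink_sd_uv = 0, eeg_white_sd_uv = 0,
    subject_intercept_sd_mm = 0, erp_subject_sd_uv = 0,
    missing_trial_rate = 0, ...
  )
}

# one row of trial metadata for single-trial simulation
example_trial <- function(stimulus = "standard", phase = "before",
                          isi = 1900, onset = 0) {
  list(tone_duration_ms = 100, isi_ms = isi, onset_ms = onset,
       stimulus = stimulus, manipulation_phase = phase)
}
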