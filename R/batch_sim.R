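# Batched per-subject simulation + feature extraction. Statistically the
# same generative world as simulate_subject() followed by
# subject_trial_features(), but all trials of a subject are generated and
# reduced with matrix operations, which makes large Monte-Carlo studies
# (parameter recovery, CI coverage) tractable on one CPU. With all noise
# parameters at zero the two paths agree exactly; with noise they agree in
# distribution (both properties are asserted in the test suite).

simulate_subject_features_fast <- function(params, subject_id, group, seed,
                                           n_blocks = 4L,
                                           blocks = seq_len(n_blocks),
                                           what = c("pupil", "eeg"),
                                           lead_in = 3L) {
  schedule <- build_schedule(subject_id, derive_seed(seed, 1L),
                             n_blocks = n_blocks, blocks = blocks)
  trials <- schedule$trials
  nt <- nrow(trials)
  odd <- trials$stimulus == "oddball"
  with_seed(derive_seed(seed, 2L), {
    age <- min(max(rnorm(1L, params$age_mean_years, params$age_sd_years),
                   params$age_range_years[1L]), params$age_range_years[2L])
    gender <- sample(c("f", "m"), 1L,
                     prob = c(params$female_fraction[[group]],
                              1 - params$female_fraction[[group]]))
    pupil_intercept <- rnorm(1L, 0, params$subject_intercept_sd_mm)
    mmn_intercept <- rnorm(1L, 0, params$erp_subject_sd_uv)
    p3a_intercept <- rnorm(1L, 0, params$erp_subject_sd_uv)
    missing <- runif(nt) < params$missing_trial_rate
    live <- which(!missing)

    pupil_vals <- matrix(NA_real_, nt, 4L)
    eeg_vals <- matrix(NA_real_, nt, 4L)
    truth <- data.frame(true_bps = rep(NA_real_, nt), true_sepr = NA_real_,
                        true_mmn_amp = NA_real_, true_p3a_amp = NA_real_)
    amp_dev <- rnorm(nt, 0, params$sepr_trial_sd_mm)

    if ("pupil" %in% what && length(live)) {
      dt <- 1000 / params$pupil_rate_hz
      dur <- trials$tone_duration_ms + trials$isi_ms
      n_i <- floor((dur - dt / 2) / dt) + 1L
      nmax <- max(n_i)
      tg <- (seq_len(nmax) - 1L) * dt
      kernel <- pupil_kernel(tg, params$sepr_latency_ms, params$sepr_shape_n)
      shift <- params$group_bps_manipulation_shift_mm[[group]] *
        (trials$manipulation_phase == "after")
      base_level <- params$baseline_mm + pupil_intercept + shift
      amp <- params$sepr_amp_mm + odd * params$sepr_oddball_increment_mm +
        amp_dev
      # nmax x nt deterministic signal
      mu <- outer(tg, trials$onset_ms, `+`) *
        (params$tonic_drift_mm_min / 60000) +
        rep(base_level, each = nmax) + outer(kernel, amp)
      over <- outer(seq_len(nmax), n_i, `>`) # samples past each trial's end
      mu[over] <- NA_real_
      left <- mu + rnorm(nmax * nt, 0, params$pupil_noise_sd_mm)
      right <- mu + rnorm(nmax * nt, 0, params$pupil_noise_sd_mm)

      n_blinks <- rpois(nt, params$blink_rate_per_min * dur / 60000)
      for (i in which(n_blinks > 0 & !missing)) {
        for (bn in seq_len(n_blinks[i])) {
          bdur <- runif(1L, params$blink_duration_range_ms[1L],
                        params$blink_duration_range_ms[2L])
          bstart <- runif(1L, 0, max(dur[i] - bdur, 0))
          gap <- tg >= bstart & tg < bstart + bdur
          left[gap, i] <- NA_real_
          right[gap, i] <- NA_real_
        }
      }
      if (params$artifact_spike_rate_per_min > 0) {
        for (eye in 1:2) {
          n_spk <- rpois(nt, params$artifact_spike_rate_per_min * dur / 60000)
          for (i in which(n_spk > 0 & !missing)) {
            pos <- sample.int(n_i[i], n_spk[i])
            sgn <- sample(c(-1, 1), n_spk[i], replace = TRUE)
            if (eye == 1L) left[pos, i] <- left[pos, i] +
                sgn * params$spike_amp_mm
            else right[pos, i] <- right[pos, i] + sgn * params$spike_amp_mm
          }
        }
      }
      base_rows <- tg >= 0 & tg < 250
      sepr_rows <- tg >= 500 & tg < 1500
      truth$true_bps[live] <- colMeans(mu[base_rows, live, drop = FALSE])
      truth$true_sepr[live] <-
        colMeans(mu[sepr_rows, live, drop = FALSE]) - truth$true_bps[live]
      for (i in live) {
        idx <- seq_len(n_i[i])
        pupil_vals[i, ] <- preprocess_values_cpp(tg[idx], left[idx, i],
                                                 right[idx, i], 3, 2L)
      }
    }

    if ("eeg" %in% what && length(live)) {
      dt <- 1000 / params$eeg_rate_hz
      te <- seq(params$epoch_window_ms[1L], params$epoch_window_ms[2L],
                by = dt)
      n <- length(te)
      mmn_amp <- params$mmn_amp_uv + odd * params$mmn_oddball_increment_uv +
        mmn_intercept + rnorm(nt, 0, params$erp_trial_sd_uv) +
        params$coupling_sepr_mmn_uv_per_mm * amp_dev
      p3a_amp <- params$p3a_amp_uv + odd * params$p3a_oddball_increment_uv +
        p3a_intercept + rnorm(nt, 0, params$erp_trial_sd_uv)
      truth$true_mmn_amp[live] <- mmn_amp[live]
      truth$true_p3a_amp[live] <- p3a_amp[live]

      g1 <- exp(-(te - params$mmn_peak_ms)^2 / (2 * params$mmn_width_ms^2))
      g2 <- exp(-(te - params$p3a_peak_ms)^2 / (2 * params$p3a_width_ms^2))
      nl <- length(live)
      signal <- outer(g1, -mmn_amp[live]) + outer(g2, p3a_amp[live])

      # Cluster-level noise with the exact covariance induced by averaging
      # independent per-channel noise: the MMN cluster pools FC1/FC2/FCz/Fz
      # and the P3a cluster Cz/FCz, sharing FCz. Only three independent
      # series are needed: the mean of the three MMN-only channels (variance
      # sigma^2/3 per component, pink keeps its spectral shape under
      # averaging), FCz and Cz.
      chan_noise <- function(scale) {
        nc <- if (params$eeg_pink_sd_uv > 0)
          scale * params$eeg_pink_sd_uv * pink_noise(n, nl)
        else matrix(0, n, nl)
        if (params$eeg_white_sd_uv > 0)
          nc <- nc + rnorm(n * nl, 0, scale * params$eeg_white_sd_uv)
        nc
      }
      mean3 <- chan_noise(1 / sqrt(3)) # mean of FC1, FC2, Fz
      fcz <- chan_noise(1)
      cz <- chan_noise(1)
      mmn_wave <- signal + (3 * mean3 + fcz) / 4
      p3a_wave <- signal + (cz + fcz) / 2

      ba <- butter_lowpass(4L, 30, params$eeg_rate_hz)
      mmn_wave <- filtfilt_rows_cpp(ba$b, ba$a, t(mmn_wave), ba$zi)
      p3a_wave <- filtfilt_rows_cpp(ba$b, ba$a, t(p3a_wave), ba$zi)
      pre <- te >= -500 & te < 0
      mmn_wave <- mmn_wave - rowMeans(mmn_wave[, pre, drop = FALSE])
      p3a_wave <- p3a_wave - rowMeans(p3a_wave[, pre, drop = FALSE])

      eeg_vals[live, 1:2] <- batch_extract(mmn_wave, te, c(100, 150), "min")
      eeg_vals[live, 3:4] <- batch_extract(p3a_wave, te, c(150, 250), "max")
    }

    assemble_trial_features(
      subject = list(subject_id = subject_id, group = group, age = age,
                     gender = gender),
      trials = trials, pupil_vals = pupil_vals, eeg_vals = eeg_vals,
      has_eeg = !missing & "eeg" %in% what, truth = truth, lead_in = lead_in)
  })
}

# vectorised windowed-peak extraction over trial rows; mirrors
# extract_peak(): earliest tie-break, +/- 4 ms (2-sample) mean around the
# peak sample. Returns cbind(amp, lat).
batch_extract <- function(waves, t, window, type = c("min", "max")) {
  type <- match.arg(type)
  idx <- which(t >= window[1L] & t <= window[2L])
  sub <- waves[, idx, drop = FALSE]
  if (type == "min") sub <- -sub
  peak_rel <- max.col(sub, ties.method = "first")
  peak <- idx[peak_rel]
  nr <- nrow(waves)
  noff <- floor(4 / (t[2L] - t[1L]) + 1e-9)
  amp <- numeric(nr)
  for (o in -noff:noff) {
    cols <- pmin(pmax(peak + o, 1L), ncol(waves)) # clip at epoch bounds
    amp <- amp + waves[cbind(seq_len(nr), cols)]
  }
  cbind(amp / (2L * noff + 1L), t[peak])
}
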