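# Synthetic cohort generator: two-eye 300 Hz pupil traces and 500 Hz
# multichannel ERP epochs with the statistical structure the downstream
# analysis assumes (subject random intercepts, stimulus / group /
# manipulation effects, blinks, spike artifacts, whole-trial dropouts).
# Numeric defaults are generator choices, documented in the methods
# vignette; they are not estimates from any real dataset.

#' Generator parameters
#'
#' Returns the full parameter set of the synthetic-data generator with
#' defaults describing a plausible adolescent cohort under laboratory
#' lighting. Any field can be overridden by name.
#'
#' @param ... Name-value overrides of the defaults listed below.
#' @return A validated list of class `generator_params`.
#'
#' @section Pupil model:
#' Sample-level diameter = tonic level (group/phase baseline + subject
#' intercept + linear within-block drift) + trial dilation amplitude x
#' gamma-shaped response kernel + white measurement noise per eye. Blinks
#' are binocular missing runs, spike artifacts isolated high-dilation-speed
#' excursions. `group_bps_manipulation_shift_mm` moves the tonic level in
#' after-manipulation blocks only, per group.
#'
#' @section EEG model:
#' Epoch = -(MMN amplitude) x Gaussian(center `mmn_peak_ms`) + (P3a
#' amplitude) x Gaussian(center `p3a_peak_ms`) on every channel, plus 1/f
#' ("pink") and white noise per channel. Oddballs increase both component
#' amplitudes by the configured increments. `coupling_sepr_mmn_uv_per_mm`
#' adds the trial's pupil dilation-amplitude deviation into the MMN
#' amplitude, giving a ground-truth pupil-ERP association for recovery
#' tests.
#' @export
generator_params <- function(...) {
  p <- list(
    # pupil
    pupil_rate_hz = 300,
    baseline_mm = 5.0,
    tonic_drift_mm_min = -0.05,
    subject_intercept_sd_mm = 0.5,
    sepr_amp_mm = 0.05,
    sepr_oddball_increment_mm = 0.03,
    sepr_trial_sd_mm = 0.05,
    sepr_latency_ms = 930,
    sepr_shape_n = 10.1,
    pupil_noise_sd_mm = 0.05,
    blink_rate_per_min = 15,
    blink_duration_range_ms = c(100, 200),
    artifact_spike_rate_per_min = 4,
    spike_amp_mm = 1.5,
    missing_trial_rate = 0.1,
    group_bps_manipulation_shift_mm = c(ASD = 0.08, CON = 0, MHC = 0.11),
    # eeg
    eeg_rate_hz = 500,
    epoch_window_ms = c(-500, 800),
    channels = c("Fz", "FC1", "FC2", "FCz", "Cz"),
    mmn_amp_uv = 1.0,
    mmn_oddball_increment_uv = 1.0,
    mmn_peak_ms = 125,
    mmn_width_ms = 20,
    p3a_amp_uv = 1.5,
    p3a_oddball_increment_uv = 0.75,
    p3a_peak_ms = 200,
    p3a_width_ms = 30,
    erp_subject_sd_uv = 0.5,
    erp_trial_sd_uv = 0.5,
    eeg_pink_sd_uv = 2,
    eeg_white_sd_uv = 1,
    coupling_sepr_mmn_uv_per_mm = 0,
    # cohort
    age_mean_years = 15,
    age_sd_years = 1.9,
    age_range_years = c(12, 18),
    female_fraction = c(ASD = 10 / 52, CON = 30 / 55, MHC = 29 / 43)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(p))
  if (length(unknown))
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(override)] <- override
  stopifnot(
    p$pupil_rate_hz > 0, p$eeg_rate_hz > 0,
    p$blink_duration_range_ms[1L] >= 40, p$blink_duration_range_ms[2L] <= 600,
    p$subject_intercept_sd_mm >= 0, p$pupil_noise_sd_mm >= 0,
    p$sepr_trial_sd_mm >= 0, p$erp_subject_sd_uv >= 0,
    p$erp_trial_sd_uv >= 0, p$eeg_pink_sd_uv >= 0, p$eeg_white_sd_uv >= 0,
    p$missing_trial_rate >= 0, p$missing_trial_rate < 1,
    all(c("ASD", "CON", "MHC") %in% names(p$group_bps_manipulation_shift_mm))
  )
  structure(p, class = "generator_params")
}

#' Pupil dilation response kernel
#'
#' Gamma-shaped kernel `(t/tmax)^n * exp(n * (1 - t/tmax))`, normalised to
#' peak 1 at `t = tmax`. With the default `tmax = 930` ms the bulk of the
#' response falls inside the 500-1500 ms SEPR window.
#'
#' @param t_ms Time since stimulus onset in ms (values < 0 return 0).
#' @param latency_ms Peak time `tmax` in ms.
#' @param n Shape parameter.
#' @return Kernel values in \[0, 1\].
#' @export
pupil_kernel <- function(t_ms, latency_ms = 930, n = 10.1) {
  k <- ifelse(t_ms <= 0, 0,
              (t_ms / latency_ms)^n * exp(n * (1 - t_ms / latency_ms)))
  k
}

#' SEPR window gain of the dilation kernel
#'
#' Mean of the baseline-corrected response kernel over the SEPR window:
#' converts a dilation-amplitude increment (mm) into the SEPR increment
#' (mm) it induces in a noise-free measurement.
#'
#' @param params A `generator_params` object.
#' @param sepr_window,baseline_window Analysis windows in ms (half-open).
#' @return Scalar gain in (0, 1).
#' @export
sepr_window_gain <- function(params, sepr_window = c(500, 1500),
                             baseline_window = c(0, 250)) {
  dt <- 1000 / params$pupil_rate_hz
  kern <- function(w) {
    t <- seq(w[1L], w[2L] - dt / 2, by = dt)
    mean(pupil_kernel(t, params$sepr_latency_ms, params$sepr_shape_n))
  }
  kern(sepr_window) - kern(baseline_window)
}

#' Simulate one trial's two-eye pupil series
#'
#' Uses the current RNG state. Ground-truth deterministic BPS and SEPR
#' components (what a noise-free measurement would return) are attached as
#' attribute `"truth"` for recovery tests.
#'
#' @param params A `generator_params` object.
#' @param trial One row of a schedule's `trials` table.
#' @param subject_effects List with `pupil_intercept_mm` (subject random
#'   intercept) and `group` (for the manipulation shift); both optional.
#' @return A `pupil_series` covering stimulus onset to onset + tone + ISI.
#' @export
simulate_pupil_trial <- function(params, trial, subject_effects = list()) {
  dt <- 1000 / params$pupil_rate_hz
  duration <- trial$tone_duration_ms + trial$isi_ms
  t <- seq(0, duration - dt / 2, by = dt)
  n <- length(t)

  shift <- 0
  if (identical(trial$manipulation_phase, "after") &&
      !is.null(subject_effects$group))
    shift <- params$group_bps_manipulation_shift_mm[[subject_effects$group]]
  intercept <- subject_effects$pupil_intercept_mm %||% 0
  tonic <- params$baseline_mm + intercept + shift +
    params$tonic_drift_mm_min * (trial$onset_ms + t) / 60000

  amp <- params$sepr_amp_mm +
    (trial$stimulus == "oddball") * params$sepr_oddball_increment_mm +
    rnorm(1L, 0, params$sepr_trial_sd_mm)
  kernel <- pupil_kernel(t, params$sepr_latency_ms, params$sepr_shape_n)
  mu <- tonic + amp * kernel

  left <- mu + rnorm(n, 0, params$pupil_noise_sd_mm)
  right <- mu + rnorm(n, 0, params$pupil_noise_sd_mm)

  # binocular blinks: missing runs
  n_blinks <- rpois(1L, params$blink_rate_per_min * duration / 60000)
  for (i in seq_len(n_blinks)) {
    bdur <- runif(1L, params$blink_duration_range_ms[1L],
                  params$blink_duration_range_ms[2L])
    bstart <- runif(1L, 0, max(duration - bdur, 0))
    gap <- t >= bstart & t < bstart + bdur
    left[gap] <- NA_real_
    right[gap] <- NA_real_
  }
  # monocular spike artifacts: isolated high-dilation-speed excursions
  for (eye in c("left", "right")) {
    n_spk <- rpois(1L, params$artifact_spike_rate_per_min * duration / 60000)
    if (n_spk > 0) {
      pos <- sample.int(n, n_spk)
      sgn <- sample(c(-1, 1), n_spk, replace = TRUE)
      if (eye == "left") left[pos] <- left[pos] + sgn * params$spike_amp_mm
      else right[pos] <- right[pos] + sgn * params$spike_amp_mm
    }
  }

  out <- new_pupil_series(t, left, right)
  base_sel <- t >= 0 & t < 250
  sepr_sel <- t >= 500 & t < 1500
  attr(out, "truth") <- list(
    bps = mean(mu[base_sel]),
    sepr = mean(mu[sepr_sel]) - mean(mu[base_sel]),
    amp = amp
  )
  out
}

# 1/f ("pink") amplitude-spectrum noise via inverse FFT; `m` independent
# unit-variance series as columns of an n x m matrix. The spectral modulus
# is deterministic (random phases only), so the realised variance is a
# constant that can be divided out analytically.
.pink_cache <- new.env(parent = emptyenv())
pink_noise <- function(n, m = 1L) {
  key <- as.character(n)
  cached <- .pink_cache[[key]]
  if (is.null(cached)) {
    nf <- n %/% 2L
    mod <- 1 / sqrt(seq_len(nf))
    # Re(ifft) of a hermitian-extended spectrum with fixed moduli has
    # constant sample variance independent of the phases
    phases <- rep(0, nf)
    full <- complex(real = numeric(n))
    full[2L:(nf + 1L)] <- complex(modulus = mod, argument = phases)
    full[n:(n - nf + 2L)] <- Conj(full[2L:nf])
    probe <- Re(fft(full, inverse = TRUE))
    cached <- list(nf = nf, mod = mod, sd = sd(probe))
    .pink_cache[[key]] <- cached
  }
  nf <- cached$nf
  spec <- matrix(complex(modulus = rep(cached$mod, m),
                         argument = runif(nf * m, -pi, pi)), nf, m)
  full <- matrix(complex(real = 0), n, m)
  full[2L:(nf + 1L), ] <- spec
  full[n:(n - nf + 2L), ] <- Conj(spec[seq_len(nf - 1L), , drop = FALSE])
  Re(stats::mvfft(full, inverse = TRUE)) / cached$sd
}

#' Simulate one trial's EEG epoch
#'
#' Uses the current RNG state. Noise-free component amplitudes are attached
#' as attribute `"truth"`.
#'
#' @param params A `generator_params` object.
#' @param trial One row of a schedule's `trials` table.
#' @param subject_effects List with optional `mmn_intercept_uv`,
#'   `p3a_intercept_uv` (subject random intercepts on component amplitudes)
#'   and `pupil_amp_deviation_mm` (for the pupil-ERP coupling).
#' @return An `erp_epoch` with channels Fz, FC1, FC2, FCz, Cz, -500..+800 ms
#'   at 500 Hz.
#' @export
simulate_eeg_epoch <- function(params, trial, subject_effects = list()) {
  dt <- 1000 / params$eeg_rate_hz
  t <- seq(params$epoch_window_ms[1L], params$epoch_window_ms[2L], by = dt)
  n <- length(t)
  odd <- trial$stimulus == "oddball"

  mmn_amp <- params$mmn_amp_uv + odd * params$mmn_oddball_increment_uv +
    (subject_effects$mmn_intercept_uv %||% 0) +
    rnorm(1L, 0, params$erp_trial_sd_uv) +
    params$coupling_sepr_mmn_uv_per_mm *
      (subject_effects$pupil_amp_deviation_mm %||% 0)
  p3a_amp <- params$p3a_amp_uv + odd * params$p3a_oddball_increment_uv +
    (subject_effects$p3a_intercept_uv %||% 0) +
    rnorm(1L, 0, params$erp_trial_sd_uv)

  g_mmn <- exp(-(t - params$mmn_peak_ms)^2 / (2 * params$mmn_width_ms^2))
  g_p3a <- exp(-(t - params$p3a_peak_ms)^2 / (2 * params$p3a_width_ms^2))
  signal <- -mmn_amp * g_mmn + p3a_amp * g_p3a

  nch <- length(params$channels)
  data <- matrix(signal, nch, n, byrow = TRUE)
  if (params$eeg_pink_sd_uv > 0)
    data <- data + params$eeg_pink_sd_uv * t(pink_noise(n, nch))
  if (params$eeg_white_sd_uv > 0)
    data <- data + rnorm(nch * n, 0, params$eeg_white_sd_uv)
  rownames(data) <- params$channels

  out <- erp_epoch(data, rate = params$eeg_rate_hz, t = t)
  attr(out, "truth") <- list(mmn_amp = mmn_amp, p3a_amp = p3a_amp)
  out
}

#' Simulate one subject
#'
#' @param params A `generator_params` object.
#' @param subject_id Identifier.
#' @param group One of `"ASD"`, `"CON"`, `"MHC"`.
#' @param seed Per-subject seed.
#' @param n_blocks Blocks in the schedule (default 4).
#' @param blocks Block indices to retain (see [build_schedule()]).
#' @param what Which modalities to simulate (`"pupil"`, `"eeg"`).
#' @return A list of class `subject_record` with demographic fields, the
#'   schedule, per-trial `pupil` series and `epochs` (NULL entries mark
#'   unusable/dropped trials) and a per-trial ground-truth `data.frame`.
#' @export
simulate_subject <- function(params, subject_id, group, seed,
                             n_blocks = 4L, blocks = seq_len(n_blocks),
                             what = c("pupil", "eeg")) {
  schedule <- build_schedule(subject_id, derive_seed(seed, 1L),
                             n_blocks = n_blocks, blocks = blocks)
  trials <- schedule$trials
  nt <- nrow(trials)
  with_seed(derive_seed(seed, 2L), {
    age <- min(max(rnorm(1L, params$age_mean_years, params$age_sd_years),
                   params$age_range_years[1L]), params$age_range_years[2L])
    gender <- sample(c("f", "m"), 1L,
                     prob = c(params$female_fraction[[group]],
                              1 - params$female_fraction[[group]]))
    effects <- list(
      group = group,
      pupil_intercept_mm = rnorm(1L, 0, params$subject_intercept_sd_mm),
      mmn_intercept_uv = rnorm(1L, 0, params$erp_subject_sd_uv),
      p3a_intercept_uv = rnorm(1L, 0, params$erp_subject_sd_uv)
    )
    missing <- runif(nt) < params$missing_trial_rate

    pupil <- vector("list", nt)
    epochs <- vector("list", nt)
    true_bps <- true_sepr <- true_mmn <- true_p3a <- rep(NA_real_, nt)
    do_pupil <- "pupil" %in% what
    do_eeg <- "eeg" %in% what
    for (i in seq_len(nt)) {
      if (missing[i]) next
      tr <- list(tone_duration_ms = trials$tone_duration_ms[i],
                 isi_ms = trials$isi_ms[i], onset_ms = trials$onset_ms[i],
                 stimulus = trials$stimulus[i],
                 manipulation_phase = trials$manipulation_phase[i])
      if (do_pupil) {
        ps <- simulate_pupil_trial(params, tr, effects)
        tru <- attr(ps, "truth")
        true_bps[i] <- tru$bps
        true_sepr[i] <- tru$sepr
        effects$pupil_amp_deviation_mm <-
          tru$amp - params$sepr_amp_mm -
          (tr$stimulus == "oddball") * params$sepr_oddball_increment_mm
        pupil[[i]] <- ps
      }
      if (do_eeg) {
        ep <- simulate_eeg_epoch(params, tr, effects)
        tru <- attr(ep, "truth")
        true_mmn[i] <- tru$mmn_amp
        true_p3a[i] <- tru$p3a_amp
        epochs[[i]] <- ep
      }
    }
    truth <- data.frame(trial = seq_len(nt), missing = missing,
                        true_bps = true_bps, true_sepr = true_sepr,
                        true_mmn_amp = true_mmn, true_p3a_amp = true_p3a)
    structure(
      list(subject_id = subject_id, group = group, age = age,
           gender = gender, schedule = schedule, pupil = pupil,
           epochs = epochs, truth = truth, effects = effects),
      class = "subject_record"
    )
  })
}

#' Simulate a full cohort
#'
#' Subjects are drawn with random intercepts; the group-specific BPS
#' manipulation shift applies only in after-manipulation blocks. Per-subject
#' seeds derive deterministically from the master seed, so the cohort is
#' reproducible.
#'
#' @param params A `generator_params` object.
#' @param n_per_group Named counts, default `c(ASD = 52, CON = 55, MHC = 43)`.
#' @param seed Master seed.
#' @param n_blocks,blocks,what Passed to [simulate_subject()].
#' @return A list of `subject_record`s, class `oddball_cohort`.
#' @export
simulate_cohort <- function(params, n_per_group = c(ASD = 52, CON = 55, MHC = 43),
                            seed = 1L, n_blocks = 4L,
                            blocks = seq_len(n_blocks),
                            what = c("pupil", "eeg")) {
  stopifnot(all(n_per_group >= 1), !is.null(names(n_per_group)))
  groups <- rep(names(n_per_group), n_per_group)
  records <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    records[[i]] <- simulate_subject(
      params, sprintf("S%03d", i), groups[i],
      seed = derive_seed(seed, 100L + i), n_blocks = n_blocks,
      blocks = blocks, what = what)
  }
  structure(records, class = "oddball_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
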