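# Bridge from simulated (or imported) recordings to the one-row-per-trial
# feature table consumed by the mixed models: pupil preprocessing to
# BPS/SEPR, ERP extraction to MMN/P3a, and the per-block EEG inclusion rule.

#' Extract MMN and P3a features from one epoch
#'
#' Applies the zero-phase 30 Hz Butterworth low-pass, pre-stimulus baseline
#' correction, electrode-cluster averaging and windowed peak extraction.
#'
#' @param epoch An `erp_epoch`.
#' @param cutoff_hz Low-pass cutoff (default 30; `NA` skips filtering).
#' @param mmn_cluster,p3a_cluster Electrode clusters.
#' @return One-row `data.frame`: `mmn_amp`, `mmn_lat`, `p3a_amp`, `p3a_lat`.
#' @export
epoch_features <- function(epoch, cutoff_hz = 30,
                           mmn_cluster = c("FC1", "FC2", "FCz", "Fz"),
                           p3a_cluster = c("Cz", "FCz")) {
  v <- epoch_feature_values(epoch, cutoff_hz, mmn_cluster, p3a_cluster)
  data.frame(mmn_amp = v[[1L]], mmn_lat = v[[2L]],
             p3a_amp = v[[3L]], p3a_lat = v[[4L]])
}

# internal fast path: returns c(mmn_amp, mmn_lat, p3a_amp, p3a_lat)
epoch_feature_values <- function(epoch, cutoff_hz = 30,
                                 mmn_cluster = c("FC1", "FC2", "FCz", "Fz"),
                                 p3a_cluster = c("Cz", "FCz")) {
  if (!is.na(cutoff_hz)) epoch <- lowpass_epoch(epoch, cutoff_hz)
  epoch <- baseline_epoch(epoch)
  mmn <- extract_mmn(cluster_waveform(epoch, mmn_cluster))
  p3a <- extract_p3a(cluster_waveform(epoch, p3a_cluster))
  c(mmn$amp, mmn$lat, p3a$amp, p3a$lat)
}

#' Per-trial feature table for one subject
#'
#' Runs the full pupil preprocessing chain and the ERP extraction on every
#' usable trial, applies the EEG block-inclusion rule (2/3 of scheduled
#' trials per stimulus type) and the pupil 50% validity rule, and drops the
#' three lead-in standards of each block from the analysis table.
#'
#' @param record A `subject_record`.
#' @param lead_in Number of lead-in standards per block excluded from
#'   analysis (default 3).
#' @param keep_truth Keep the generator's ground-truth columns (default
#'   TRUE; they are absent for imported data).
#' @return A `data.frame` with one row per analysed trial.
#' @export
subject_trial_features <- function(record, lead_in = 3L, keep_truth = TRUE) {
  stopifnot(inherits(record, "subject_record"))
  trials <- record$schedule$trials
  nt <- nrow(trials)
  has_pupil <- !vapply(record$pupil, is.null, logical(1L))
  has_eeg <- !vapply(record$epochs, is.null, logical(1L))

  pupil_vals <- matrix(NA_real_, nt, 4L)
  for (i in which(has_pupil))
    pupil_vals[i, ] <- preprocess_trial_values(record$pupil[[i]])
  eeg_vals <- matrix(NA_real_, nt, 4L)
  for (i in which(has_eeg))
    eeg_vals[i, ] <- epoch_feature_values(record$epochs[[i]])
  truth <- if (keep_truth && !is.null(record$truth))
    record$truth[c("true_bps", "true_sepr", "true_mmn_amp", "true_p3a_amp")]
  assemble_trial_features(
    subject = list(subject_id = record$subject_id, group = record$group,
                   age = record$age, gender = record$gender),
    trials = trials, pupil_vals = pupil_vals, eeg_vals = eeg_vals,
    has_eeg = has_eeg, truth = truth, lead_in = lead_in)
}

# shared assembly: block-inclusion, NA-ing of excluded features, lead-in
# removal, and the final column layout
assemble_trial_features <- function(subject, trials, pupil_vals, eeg_vals,
                                    has_eeg, truth = NULL, lead_in = 3L) {
  feat <- data.frame(
    bps = pupil_vals[, 1L], sepr = pupil_vals[, 2L],
    pupil_valid_fraction = pupil_vals[, 3L],
    pupil_included = pupil_vals[, 4L] %in% 1,
    mmn_amp = eeg_vals[, 1L], mmn_lat = eeg_vals[, 2L],
    p3a_amp = eeg_vals[, 3L], p3a_lat = eeg_vals[, 4L],
    eeg_included = FALSE
  )

  # EEG block inclusion over the pseudorandom portion of each block
  pseudo <- trials$index_in_block > lead_in
  for (b in unique(trials$block)) {
    in_block <- trials$block == b & pseudo
    n_odd <- sum(in_block & has_eeg & trials$stimulus == "oddball")
    n_std <- sum(in_block & has_eeg & trials$stimulus == "standard")
    sched <- c(sum(in_block & trials$stimulus == "oddball"),
               sum(in_block & trials$stimulus == "standard"))
    ok <- block_inclusion(n_odd, n_std, scheduled = sched)
    feat$eeg_included[trials$block == b] <- ok & has_eeg[trials$block == b]
  }
  feat[!feat$eeg_included, c("mmn_amp", "mmn_lat", "p3a_amp", "p3a_lat")] <-
    NA_real_
  feat[!feat$pupil_included, c("bps", "sepr")] <- NA_real_

  out <- cbind(
    data.frame(subject_id = subject$subject_id, group = subject$group,
               age = subject$age, gender = subject$gender,
               stringsAsFactors = FALSE),
    trials[c("block", "index_in_block", "stimulus", "manipulation_phase",
             "block_direction")],
    feat
  )
  names(out)[names(out) == "manipulation_phase"] <- "manipulation"
  if (!is.null(truth)) out <- cbind(out, truth)
  out <- out[pseudo, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-trial feature table for a cohort
#'
#' @param cohort An `oddball_cohort`.
#' @param ... Passed to [subject_trial_features()].
#' @return Row-bound feature table across subjects.
#' @export
cohort_trial_table <- function(cohort, ...) {
  stopifnot(inherits(cohort, "oddball_cohort"))
  do.call(rbind, lapply(cohort, subject_trial_features, ...))
}

#' Simulate a cohort and reduce it to trial features subject by subject
#'
#' Equivalent to `cohort_trial_table(simulate_cohort(...))` but discards each
#' subject's raw recordings once their features are extracted, keeping the
#' memory footprint flat for large simulation studies.
#'
#' @inheritParams simulate_cohort
#' @param fast Use the batched matrix implementation (default TRUE); the
#'   trial-wise path (`fast = FALSE`) generates full `subject_record`s and is
#'   the reference implementation the batched path is tested against.
#' @param ... Passed to [subject_trial_features()].
#' @return Trial feature table.
#' @export
simulate_cohort_features <- function(params,
                                     n_per_group = c(ASD = 52, CON = 55, MHC = 43),
                                     seed = 1L, n_blocks = 4L,
                                     blocks = seq_len(n_blocks),
                                     what = c("pupil", "eeg"),
                                     fast = TRUE, ...) {
  stopifnot(all(n_per_group >= 1), !is.null(names(n_per_group)))
  groups <- rep(names(n_per_group), n_per_group)
  parts <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    if (fast) {
      parts[[i]] <- simulate_subject_features_fast(
        params, sprintf("S%03d", i), groups[i],
        seed = derive_seed(seed, 100L + i), n_blocks = n_blocks,
        blocks = blocks, what = what, ...)
    } else {
      rec <- simulate_subject(params, sprintf("S%03d", i), groups[i],
                              seed = derive_seed(seed, 100L + i),
                              n_blocks = n_blocks, blocks = blocks,
                              what = what)
      parts[[i]] <- subject_trial_features(rec, ...)
    }
  }
  do.call(rbind, parts)
}
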