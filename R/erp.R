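# Trial-level ERP extraction: MMN (negative fronto-central peak, 100-150 ms)
# and P3a (positive central peak, 150-250 ms) from epoched EEG.

#' Construct an ERP epoch
#'
#' @param data Channels x time numeric matrix (uV); rownames are channel
#'   labels.
#' @param rate Sampling rate in Hz (default 500).
#' @param t Time axis in ms relative to stimulus onset; defaults to a uniform
#'   grid starting at `t0`.
#' @param t0 Epoch start in ms (default -500, the pre-stimulus baseline).
#' @return An object of class `erp_epoch`.
#' @export
erp_epoch <- function(data, rate = 500, t = NULL, t0 = -500) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  if (is.null(t)) t <- t0 + (seq_len(ncol(data)) - 1L) * 1000 / rate
  stopifnot(length(t) == ncol(data))
  structure(list(data = data, t = t, rate = rate), class = "erp_epoch")
}

#' @export
print.erp_epoch <- function(x, ...) {
  cat("<erp_epoch>", nrow(x$data), "channels x", ncol(x$data), "samples,",
      x$rate, "Hz, t in [", min(x$t), ",", max(x$t), "] ms\n")
  invisible(x)
}

#' Zero-phase Butterworth low-pass of an epoch
#'
#' @param epoch An `erp_epoch`.
#' @param cutoff Low-pass cutoff in Hz (default 30).
#' @param order Butterworth order (default 4).
#' @return The filtered epoch.
#' @export
lowpass_epoch <- function(epoch, cutoff = 30, order = 4L) {
  stopifnot(inherits(epoch, "erp_epoch"))
  ba <- butter_lowpass(order, cutoff, epoch$rate)
  filtered <- filtfilt_rows_cpp(ba$b, ba$a, epoch$data, ba$zi)
  dimnames(filtered) <- dimnames(epoch$data)
  epoch$data <- filtered
  epoch
}

#' Pre-stimulus baseline correction of an epoch
#'
#' Subtracts, per channel, the mean amplitude over the pre-stimulus window
#' \[-500, 0) ms.
#'
#' @param epoch An `erp_epoch`.
#' @param window Baseline window in ms, default `c(-500, 0)` (half-open).
#' @return The baseline-corrected epoch.
#' @export
baseline_epoch <- function(epoch, window = c(-500, 0)) {
  stopifnot(inherits(epoch, "erp_epoch"))
  sel <- epoch$t >= window[1L] & epoch$t < window[2L]
  if (!any(sel)) stop("no samples in the pre-stimulus window", call. = FALSE)
  epoch$data <- epoch$data - rowMeans(epoch$data[, sel, drop = FALSE])
  epoch
}

#' Average waveform of an electrode cluster
#'
#' @param epoch An `erp_epoch`.
#' @param channels Channel labels to pool (e.g. `c("FC1","FC2","FCz","Fz")`
#'   for MMN, `c("Cz","FCz")` for P3a).
#' @return Numeric waveform (pointwise mean across the cluster), with the time
#'   axis attached as attribute `t`.
#' @export
cluster_waveform <- function(epoch, channels) {
  stopifnot(inherits(epoch, "erp_epoch"))
  missing <- setdiff(channels, rownames(epoch$data))
  if (length(missing))
    stop("channel(s) not present in epoch: ", paste(missing, collapse = ", "),
         call. = FALSE)
  w <- colMeans(epoch$data[channels, , drop = FALSE])
  attr(w, "t") <- epoch$t
  w
}

# Windowed extremum with a +/- half_width ms mean amplitude around the peak
# sample. Ties break to the earliest sample; the peak may sit on a window
# edge. The amplitude window stays centred on the peak (it may extend past
# the search window but is clipped at the epoch bounds).
extract_peak <- function(waveform, t = attr(waveform, "t"),
                         window, polarity = c("negative", "positive"),
                         half_width_ms = 4) {
  polarity <- match.arg(polarity)
  if (is.null(t) || length(t) != length(waveform))
    stop("waveform needs a time axis of matching length", call. = FALSE)
  if (min(t) > window[1L] - half_width_ms || max(t) < window[2L] + half_width_ms)
    stop("waveform does not cover [", window[1L] - half_width_ms, ", ",
         window[2L] + half_width_ms, "] ms", call. = FALSE)
  idx <- which(t >= window[1L] & t <= window[2L])
  y <- if (polarity == "negative") waveform[idx] else -waveform[idx]
  peak <- idx[which.min(y)] # which.min takes the earliest on ties
  sel <- which(abs(t - t[peak]) <= half_width_ms + 1e-9)
  list(amp = mean(waveform[sel]), lat = t[peak])
}

#' Extract trial-level MMN from a cluster waveform
#'
#' MMN is the negative peak within 100-150 ms after stimulus onset; the
#' reported amplitude is the mean over +/- 4 ms around the peak sample
#' (5 samples at 500 Hz) and the latency is the peak time.
#'
#' @param waveform Cluster waveform (from [cluster_waveform()]).
#' @param t Time axis in ms; taken from the waveform attribute by default.
#' @param window Search window in ms, default `c(100, 150)` (closed).
#' @return A list with `amp` (uV) and `lat` (ms).
#' @export
extract_mmn <- function(waveform, t = attr(waveform, "t"),
                        window = c(100, 150)) {
  extract_peak(waveform, t, window, "negative")
}

#' Extract trial-level P3a from a cluster waveform
#'
#' P3a is the positive peak within 150-250 ms after stimulus onset, with the
#' same +/- 4 ms mean-amplitude convention as [extract_mmn()].
#'
#' @inheritParams extract_mmn
#' @param window Search window in ms, default `c(150, 250)` (closed).
#' @return A list with `amp` (uV) and `lat` (ms).
#' @export
extract_p3a <- function(waveform, t = attr(waveform, "t"),
                        window = c(150, 250)) {
  extract_peak(waveform, t, window, "positive")
}

#' Oddball-minus-standard difference wave
#'
#' @param oddball_mean,standard_mean Averaged waveforms of equal length and
#'   time axis.
#' @return Pointwise difference (oddball - standard) with the time axis
#'   preserved; aggregated MMN is extracted from this waveform.
#' @export
difference_wave <- function(oddball_mean, standard_mean) {
  if (length(oddball_mean) != length(standard_mean))
    stop("waveform lengths differ (", length(oddball_mean), " vs ",
         length(standard_mean), ")", call. = FALSE)
  d <- oddball_mean - standard_mean
  attr(d, "t") <- attr(oddball_mean, "t")
  d
}

#' Block inclusion by the two-thirds data rule
#'
#' A task block enters the EEG analysis only if at least two thirds of its
#' scheduled trials survive artifact rejection per stimulus type. With the
#' standard schedule (20 oddballs, 80 pseudorandom standards) the thresholds
#' are floor(2/3 * (20, 80)) = (13, 53).
#'
#' @param valid_oddball,valid_standard Number of usable trials per type.
#' @param scheduled Scheduled counts, default `c(20, 80)`.
#' @return `TRUE` if the block is included.
#' @export
block_inclusion <- function(valid_oddball, valid_standard,
                            scheduled = c(20, 80)) {
  stopifnot(valid_oddball >= 0, valid_standard >= 0)
  if (valid_oddball > scheduled[1L] || valid_standard > scheduled[2L])
    stop("valid counts exceed scheduled counts", call. = FALSE)
  thr <- floor(2 / 3 * scheduled)
  valid_oddball >= thr[1L] && valid_standard >= thr[2L]
}

#' @rdname block_inclusion
#' @export
block_inclusion_thresholds <- function(scheduled = c(20, 80)) {
  setNames(floor(2 / 3 * scheduled), c("oddball", "standard"))
}
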