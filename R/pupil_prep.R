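# Pupil preprocessing: raw two-eye samples -> per-trial baseline pupil size
# (BPS, mean diameter 0-250 ms post-onset) and stimulus-evoked pupillary
# response (SEPR, mean baseline-corrected diameter 500-1500 ms post-onset).
#
# Chain (in order): plausibility range filter, repeated dilation-speed MAD
# outlier rejection, blink detection with gap padding, linear interpolation of
# short gaps, binocular averaging, subtractive baseline correction, SEPR
# window mean, 50% validity rule. Eyes are filtered independently and
# averaged afterwards; all analysis windows are half-open [a, b) ms.

#' Construct a two-eye pupil sample series
#'
#' @param t_ms Sample times in ms relative to stimulus onset (strictly
#'   increasing; nominal spacing 1000/300 ms at the 300 Hz recording rate).
#' @param left_mm,right_mm Pupil diameters in mm (NA = not recorded).
#' @param valid_l,valid_r Optional validity flags; default: finite samples.
#' @return A `data.frame` of class `pupil_series`.
#' @export
pupil_series <- function(t_ms, left_mm, right_mm,
                         valid_l = is.finite(left_mm),
                         valid_r = is.finite(right_mm)) {
  stopifnot(length(t_ms) == length(left_mm),
            length(t_ms) == length(right_mm))
  if (is.unsorted(t_ms, strictly = TRUE))
    stop("`t_ms` must be strictly increasing", call. = FALSE)
  out <- data.frame(t_ms = t_ms, left_mm = left_mm, right_mm = right_mm,
                    valid_l = valid_l & is.finite(left_mm),
                    valid_r = valid_r & is.finite(right_mm))
  class(out) <- c("pupil_series", "data.frame")
  out
}

# fast internal constructor (no validation; validity = finiteness)
new_pupil_series <- function(t_ms, left_mm, right_mm) {
  structure(list(t_ms = t_ms, left_mm = left_mm, right_mm = right_mm,
                 valid_l = is.finite(left_mm), valid_r = is.finite(right_mm)),
            class = c("pupil_series", "data.frame"),
            row.names = c(NA_integer_, -length(t_ms)))
}

eye_cols <- list(left = c("left_mm", "valid_l"), right = c("right_mm", "valid_r"))

# apply a per-eye (x, valid, t) -> valid function to both eyes
map_eyes <- function(series, fn) {
  for (eye in eye_cols) {
    series[[eye[2L]]] <- fn(series[[eye[1L]]], series[[eye[2L]]],
                            series$t_ms)
    series[[eye[2L]]][!is.finite(series[[eye[1L]]])] <- FALSE
  }
  series
}

#' Plausibility range filter
#'
#' Marks samples with pupil diameter below 2 mm or above 8 mm invalid
#' (strict bounds); all other samples are untouched.
#'
#' @param series A `pupil_series`.
#' @param range_mm Plausible diameter range, default `c(2, 8)`.
#' @return The series with updated validity flags.
#' @export
range_filter <- function(series, range_mm = c(2, 8)) {
  map_eyes(series, function(x, valid, t) {
    valid & !(x < range_mm[1L] | x > range_mm[2L]) %in% TRUE
  })
}

#' Dilation-speed outlier rejection (repeated MAD threshold)
#'
#' Computes per-sample dilation speeds over each eye's valid samples and
#' marks samples whose speed exceeds `median + k * MAD` invalid (MAD
#' unscaled by default). The pass is repeated on the surviving samples --
#' the "new trend line" -- `passes` times in total.
#'
#' @param series A `pupil_series`.
#' @param k MAD multiplier, default 3.
#' @param passes Number of passes, default 2.
#' @param threshold_form `"median_plus_k_mad"` (default) or `"k_mad"`
#'   (plain `k * MAD` threshold).
#' @param speed `"max_bidirectional"` (default; max of backward/forward
#'   absolute speed) or `"forward"` (backward difference only).
#' @param mad_constant Consistency constant for the MAD (default 1,
#'   i.e. unscaled; 1.4826 gives the normal-consistent estimate).
#' @return The series with updated validity flags. If an eye has fewer than
#'   3 valid samples it is returned unchanged and a warning is recorded in
#'   the `"warnings"` attribute.
#' @export
dilation_speed_filter <- function(series, k = 3, passes = 2L,
                                  threshold_form = c("median_plus_k_mad", "k_mad"),
                                  speed = c("max_bidirectional", "forward"),
                                  mad_constant = 1) {
  threshold_form <- match.arg(threshold_form)
  speed <- match.arg(speed)
  warnings <- character(0)
  series <- map_eyes(series, function(x, valid, t) {
    if (sum(valid) < 3L) {
      warnings <<- c(warnings,
                     "dilation_speed_filter: <3 valid samples; eye left unchanged")
      return(valid)
    }
    dilation_valid_cpp(t, x, valid, k, as.integer(passes),
                       threshold_form == "median_plus_k_mad", mad_constant,
                       speed == "forward")
  })
  if (length(warnings)) attr(series, "warnings") <- warnings
  series
}

#' Blink detection and gap padding
#'
#' Contiguous invalid runs lasting 75-250 ms are labelled blinks; valid
#' samples within 27 ms before the gap start or after the gap end are
#' discarded (blink on- and offset distort the diameter estimate).
#'
#' @param series A `pupil_series` (validity finalised by the preceding
#'   filters).
#' @param blink_range_ms Gap-duration range identifying a blink, default
#'   `c(75, 250)`.
#' @param pad_ms Padding discarded around blink gaps, default 27.
#' @return The series with updated validity flags and per-eye logical blink
#'   columns (`blink_l`, `blink_r`).
#' @export
detect_blinks <- function(series, blink_range_ms = c(75, 250), pad_ms = 27) {
  dt <- median(diff(series$t_ms))
  for (side in names(eye_cols)) {
    vcol <- eye_cols[[side]][2L]
    res <- blink_valid_cpp(series$t_ms, series[[vcol]],
                           blink_range_ms[1L], blink_range_ms[2L], pad_ms, dt)
    series[[vcol]] <- res$valid
    series[[paste0("blink_", substr(side, 1, 1))]] <- res$blink
  }
  series
}

#' Linear interpolation of short gaps
#'
#' Invalid runs up to `max_gap_ms` with valid samples on both sides are
#' replaced by linear interpolation between the anchoring samples and count
#' as valid (imputed) downstream. Longer gaps and gaps touching the series
#' edge are left missing.
#'
#' @param series A `pupil_series`.
#' @param max_gap_ms Maximum imputable gap duration, default 300.
#' @return The series with imputed values, updated validity flags and per-eye
#'   logical `imputed_l` / `imputed_r` columns.
#' @export
interpolate_gaps <- function(series, max_gap_ms = 300) {
  dt <- median(diff(series$t_ms))
  for (side in names(eye_cols)) {
    xcol <- eye_cols[[side]][1L]
    vcol <- eye_cols[[side]][2L]
    res <- interp_gaps_cpp(series$t_ms, series[[xcol]], series[[vcol]],
                           max_gap_ms, dt)
    series[[xcol]] <- res$x
    series[[vcol]] <- res$valid
    series[[paste0("imputed_", substr(side, 1, 1))]] <- res$imputed
  }
  series
}

#' Average the two eyes into a mono series
#'
#' Per sample: mean of both eyes when both are valid (or imputed), the single
#' available eye's value when only one is, and missing when neither is.
#'
#' @param series A `pupil_series` with per-eye preprocessing complete.
#' @return A `data.frame` with columns `t_ms`, `mm`, `valid`.
#' @export
average_eyes <- function(series) {
  l <- ifelse(series$valid_l, series$left_mm, NA_real_)
  r <- ifelse(series$valid_r, series$right_mm, NA_real_)
  mm <- rowMeans(cbind(l, r), na.rm = TRUE)
  mm[is.nan(mm)] <- NA_real_
  structure(list(t_ms = series$t_ms, mm = mm, valid = !is.na(mm)),
            class = "data.frame",
            row.names = c(NA_integer_, -length(mm)))
}

#' Subtractive baseline correction
#'
#' The trial baseline pupil size (BPS) is the mean of valid samples in the
#' first 250 ms after stimulus onset; the corrected series is the mono series
#' minus this baseline.
#'
#' @param mono A mono series from [average_eyes()].
#' @param window Baseline window in ms, default `c(0, 250)` (half-open).
#' @return A list with `series` (the corrected mono series) and `bps` (mm).
#'   If no valid baseline sample exists, `bps` is `NA` and `series` is `NULL`
#'   (the trial is unusable).
#' @export
baseline_correct <- function(mono, window = c(0, 250)) {
  sel <- mono$valid & mono$t_ms >= window[1L] & mono$t_ms < window[2L]
  if (!any(sel)) return(list(series = NULL, bps = NA_real_))
  bps <- mean(mono$mm[sel])
  mono$mm <- mono$mm - bps
  list(series = mono, bps = bps)
}

#' Stimulus-evoked pupillary response
#'
#' Mean of the valid baseline-corrected samples 500-1500 ms after stimulus
#' onset.
#'
#' @param corrected Corrected mono series (from [baseline_correct()]).
#' @param window SEPR window in ms, default `c(500, 1500)` (half-open).
#' @return SEPR in mm, or `NA` if the window holds no valid sample.
#' @export
compute_sepr <- function(corrected, window = c(500, 1500)) {
  sel <- corrected$valid & corrected$t_ms >= window[1L] &
    corrected$t_ms < window[2L]
  if (!any(sel)) return(NA_real_)
  mean(corrected$mm[sel])
}

#' Trial validity under the 50% rule
#'
#' @param mono A mono series; imputed samples count as valid.
#' @param min_fraction Inclusion threshold, default 0.5.
#' @return A list with `valid_fraction` and `included`
#'   (`valid_fraction >= min_fraction`).
#' @export
trial_validity <- function(mono, min_fraction = 0.5) {
  frac <- mean(mono$valid)
  list(valid_fraction = frac, included = frac >= min_fraction)
}

#' Full per-trial pupil preprocessing
#'
#' Applies, in order: [range_filter()], [dilation_speed_filter()] (two
#' passes), [detect_blinks()], [interpolate_gaps()], [average_eyes()],
#' [baseline_correct()], [compute_sepr()] and [trial_validity()]. BPS and
#' SEPR are reported only for included trials.
#'
#' @param series A raw `pupil_series` segmented to one trial.
#' @param ... Passed on to [dilation_speed_filter()].
#' @return A one-row `data.frame`: `bps`, `sepr`, `valid_fraction`,
#'   `included`.
#' @export
preprocess_trial <- function(series, ...) {
  series <- range_filter(series)
  series <- dilation_speed_filter(series, ...)
  series <- detect_blinks(series)
  series <- interpolate_gaps(series)
  mono <- average_eyes(series)
  validity <- trial_validity(mono)
  bc <- baseline_correct(mono)
  if (is.null(bc$series) || !validity$included) {
    return(data.frame(bps = NA_real_, sepr = NA_real_,
                      valid_fraction = validity$valid_fraction,
                      included = FALSE))
  }
  data.frame(bps = bc$bps, sepr = compute_sepr(bc$series),
             valid_fraction = validity$valid_fraction, included = TRUE)
}

# Internal fast path: the identical chain at default settings, executed in
# compiled code (test-pupil_prep.R asserts agreement with preprocess_trial
# on noisy random series). Returns c(bps, sepr, valid_fraction, included).
preprocess_trial_values <- function(series, k = 3, passes = 2L) {
  preprocess_values_cpp(series$t_ms, series$left_mm, series$right_mm,
                        k, as.integer(passes))
}
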