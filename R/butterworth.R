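# Butterworth low-pass design and zero-phase (forward-backward) filtering.
# Implemented from the analog prototype via the bilinear transform; the
# magnitude response therefore satisfies
#   |H(w)|^2 = 1 / (1 + (tan(w/2) / tan(wc/2))^(2n)),
# which the test suite checks against directly.

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

.butter_cache <- new.env(parent = emptyenv())

#' Design a digital Butterworth low-pass filter
#'
#' @param order Filter order (poles), default 4.
#' @param cutoff Cutoff frequency in Hz (the -3 dB point).
#' @param rate Sampling rate in Hz.
#' @return A list with numerator `b` and denominator `a` coefficients
#'   (transfer-function form, `a[1] == 1`).
#' @export
butter_lowpass <- function(order = 4L, cutoff, rate) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("`cutoff` must lie strictly between 0 and the Nyquist frequency (",
         rate / 2, " Hz)", call. = FALSE)
  n <- as.integer(order)
  stopifnot(n >= 1L)
  key <- paste(n, cutoff, rate, sep = "|")
  cached <- .butter_cache[[key]]
  if (!is.null(cached)) return(cached)
  W <- cutoff / (rate / 2)      # normalized cutoff in (0, 1)
  fs2 <- 4                      # 2 * fs with fs = 2 (scipy convention)
  warped <- fs2 * tan(pi * W / 2)
  k <- seq_len(n)
  p_analog <- warped * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  gain <- warped^n
  # bilinear transform: poles map, the n analog zeros at infinity map to z = -1
  p_digital <- (fs2 + p_analog) / (fs2 - p_analog)
  gain_digital <- gain * Re(1 / prod(fs2 - p_analog))
  b <- Re(poly_from_roots(rep(-1, n))) * gain_digital
  a <- Re(poly_from_roots(p_digital))
  out <- list(b = b / a[1], a = a / a[1], zi = NULL)
  out$zi <- lfilter_zi(out$b, out$a)
  .butter_cache[[key]] <- out
  out
}

# steady-state initial conditions for a unit step (scipy lfilter_zi)
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  A <- matrix(0, m, m)
  if (m > 1L) A[cbind(seq_len(m - 1L) + 1L, seq_len(m - 1L))] <- 1
  A[1L, ] <- -a[-1L]
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(m) - t(A), B)
}

# single-pass IIR filter with steady-state initialisation scaled to x[1]
lfilter <- function(b, a, x, zi = NULL) {
  if (is.null(zi)) zi <- rep(0, max(length(a), length(b)) - 1L)
  iir_filter_cpp(b, a, x, zi)
}

#' Zero-phase filtering by forward-backward application
#'
#' Applies the filter forward and then backward over the series, cancelling
#' the phase response (the squared magnitude response remains). Edge
#' transients are controlled with odd-reflection padding and steady-state
#' initial conditions, as in standard `filtfilt` implementations.
#'
#' @param b,a Transfer-function coefficients (e.g. from [butter_lowpass()]).
#' @param x Numeric series.
#' @return Filtered series of the same length.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  padlen <- 3L * max(length(a), length(b))
  if (n <= padlen)
    stop("series too short for filtfilt padding (need > ", padlen,
         " samples)", call. = FALSE)
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1L])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}
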