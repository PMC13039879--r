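rate <- 500
t_epoch <- seq(-500, 800, by = 1000 / rate)

make_epoch <- function(fun, channels = c("Fz", "FC1", "FC2", "FCz", "Cz")) {
  data <- t(vapply(channels, function(ch) fun(t_epoch), t_epoch))
  rownames(data) <- channels
  erp_epoch(data, rate = rate, t = t_epoch)
}

test_that("Butterworth design matches the analytic magnitude response", {
  ba <- butter_lowpass(4, 30, 500)
  # bilinear-transformed Butterworth: |H(w)|^2 = 1/(1 + (tan(w/2)/tan(wc/2))^(2n))
  H <- function(f) {
    w <- 2 * pi * f / 500
    h <- sum(ba$b * exp(-1i * w * (seq_along(ba$b) - 1))) /
      sum(ba$a * exp(-1i * w * (seq_along(ba$a) - 1)))
    Mod(h)
  }
  wc <- 2 * pi * 30 / 500
  for (f in c(5, 15, 30, 50, 100)) {
    w <- 2 * pi * f / 500
    expect_equal(H(f), 1 / sqrt(1 + (tan(w / 2) / tan(wc / 2))^8),
                 tolerance = 1e-9)
  }
  expect_equal(H(30), 1 / sqrt(2), tolerance = 1e-9) # -3 dB at cutoff
})

test_that("zero-phase filtering preserves DC and attenuates the stopband", {
  ba <- butter_lowpass(4, 30, 500)
  expect_equal(filtfilt(ba$b, ba$a, rep(3, 300)), rep(3, 300),
               tolerance = 1e-9)
  x <- sin(2 * pi * 50 * (0:999) / 500)
  y <- filtfilt(ba$b, ba$a, x)
  # two passes square the single-pass magnitude at 50 Hz
  w <- 2 * pi * 50 / 500; wc <- 2 * pi * 30 / 500
  expected <- 1 / (1 + (tan(w / 2) / tan(wc / 2))^8)
  expect_equal(sd(y[200:800]) / sd(x[200:800]), expected, tolerance = 0.01)
})

test_that("forward-backward filtering leaves the pulse centroid in place", {
  ba <- butter_lowpass(4, 30, 500)
  x <- numeric(500)
  x[200:210] <- c(1, 3, 6, 9, 10, 8, 5, 3, 2, 1, 0.5) # asymmetric pulse
  y <- filtfilt(ba$b, ba$a, x)
  centroid <- function(v) sum(seq_along(v) * pmax(v, 0)) / sum(pmax(v, 0))
  expect_equal(centroid(y), centroid(x), tolerance = 0.15)
})

test_that("cutoff at or above Nyquist is rejected", {
  expect_error(butter_lowpass(4, 250, 500), "Nyquist")
  ep <- make_epoch(function(t) rep(0, length(t)))
  expect_error(lowpass_epoch(ep, cutoff = 300), "Nyquist")
})

test_that("epoch baseline correction zeroes the pre-stimulus mean", {
  ep <- make_epoch(function(t) ifelse(t < 0, 1, 2))
  bl <- baseline_epoch(ep)
  pre <- bl$t >= -500 & bl$t < 0
  expect_true(all(abs(rowMeans(bl$data[, pre])) < 1e-12))
  expect_true(all(abs(bl$data[, pre]) < 1e-12))
  expect_true(all(abs(bl$data[, !pre] - 1) < 1e-12))
  const <- baseline_epoch(make_epoch(function(t) rep(3, length(t))))
  expect_true(all(const$data == 0))
})

test_that("cluster waveform is the pointwise channel mean", {
  ep <- make_epoch(function(t) rep(0, length(t)))
  ep$data["Fz", ] <- 1; ep$data["FC1", ] <- 2
  ep$data["FC2", ] <- 3; ep$data["FCz", ] <- 6
  w <- cluster_waveform(ep, c("Fz", "FC1", "FC2", "FCz"))
  expect_true(all(w == 3))
  expect_error(cluster_waveform(ep, c("Fz", "Pz")), "Pz")
  two <- cluster_waveform(ep, c("FC1", "FC2")) # {2, 3} -> 2.5
  expect_true(all(two == 2.5))
})

test_that("MMN/P3a extraction handles peaks, edges and flat input", {
  # noise-free Gaussian trough centred at 130 ms, depth -2 uV
  w <- -2 * exp(-(t_epoch - 130)^2 / (2 * 15^2))
  attr(w, "t") <- t_epoch
  mmn <- extract_mmn(w)
  expect_equal(mmn$lat, 130)
  offs <- seq(-4, 4, by = 2)
  expect_equal(mmn$amp, mean(-2 * exp(-offs^2 / (2 * 15^2))),
               tolerance = 1e-9)
  # flat zero waveform: earliest-sample tie-break
  z <- rep(0, length(t_epoch)); attr(z, "t") <- t_epoch
  expect_equal(extract_mmn(z), list(amp = 0, lat = 100))
  expect_equal(extract_p3a(z), list(amp = 0, lat = 150))
  # trough outside the window: the window-edge minimum wins
  w90 <- -2 * exp(-(t_epoch - 90)^2 / (2 * 10^2))
  attr(w90, "t") <- t_epoch
  expect_equal(extract_mmn(w90)$lat, 100)
  # max/min duality
  pos <- 1.5 * exp(-(t_epoch - 200)^2 / (2 * 20^2))
  attr(pos, "t") <- t_epoch
  p3a <- extract_p3a(pos)
  neg <- -pos; attr(neg, "t") <- t_epoch
  dual <- oddpupil:::extract_peak(neg, t_epoch, c(150, 250), "negative")
  expect_equal(p3a$amp, -dual$amp)
  expect_equal(p3a$lat, dual$lat)
  # window not covered
  short <- rep(0, 50); attr(short, "t") <- seq(0, 98, by = 2)
  expect_error(extract_mmn(short), "cover")
})

test_that("extraction matches a brute-force scan and scales linearly", {
  set.seed(314)
  for (rep in 1:80) {
    w <- cumsum(rnorm(length(t_epoch), 0, 0.5))
    attr(w, "t") <- t_epoch
    mmn <- extract_mmn(w)
    want <- brute_peak(w, t_epoch, c(100, 150), "negative")
    expect_equal(mmn$amp, want$amp)
    expect_equal(mmn$lat, want$lat)
    expect_true(mmn$lat >= 100 && mmn$lat <= 150)
    p3a <- extract_p3a(w)
    wantp <- brute_peak(w, t_epoch, c(150, 250), "positive")
    expect_equal(p3a$amp, wantp$amp)
    expect_true(p3a$lat >= 150 && p3a$lat <= 250)
    # amplitude linearity, latency invariance
    c_scale <- runif(1, 0.5, 3)
    w2 <- w * c_scale; attr(w2, "t") <- t_epoch
    mmn2 <- extract_mmn(w2)
    expect_equal(mmn2$amp, c_scale * mmn$amp, tolerance = 1e-12)
    expect_equal(mmn2$lat, mmn$lat)
  }
})

test_that("difference waves subtract pointwise and reject length mismatch", {
  a <- rep(1, 100); b <- rep(2, 100)
  attr(a, "t") <- seq_len(100)
  d <- difference_wave(a, b)
  expect_true(all(d == -1))
  expect_true(all(difference_wave(a, a) == 0))
  expect_error(difference_wave(a, b[1:50]), "length")
})

test_that("the aggregated difference wave recovers the oddball increment", {
  p <- params_noise_free()
  set.seed(11)
  std <- simulate_eeg_epoch(p, example_trial("standard"), list())
  odd <- simulate_eeg_epoch(p, example_trial("oddball"), list())
  f <- function(ep) {
    ep <- baseline_epoch(lowpass_epoch(ep))
    cluster_waveform(ep, c("FC1", "FC2", "FCz", "Fz"))
  }
  d <- difference_wave(f(odd), f(std))
  attr(d, "t") <- std$t
  mmn <- extract_mmn(d)
  # the difference wave is -increment * gaussian plus the small tail of the
  # P3a increment leaking into the MMN window (~3%); 30 Hz filtering barely
  # touches a 20 ms-wide component
  expect_equal(mmn$amp, -p$mmn_oddball_increment_uv, tolerance = 0.1)
  expect_equal(mmn$lat, p$mmn_peak_ms, tolerance = 2)
})

test_that("block inclusion implements the floored 2/3 rule", {
  expect_equal(unname(block_inclusion_thresholds()), c(13, 53))
  expect_true(block_inclusion(13, 53))
  expect_false(block_inclusion(12, 80))
  expect_false(block_inclusion(20, 52))
  expect_true(block_inclusion(20, 80))
  expect_error(block_inclusion(21, 80), "exceed")
})
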