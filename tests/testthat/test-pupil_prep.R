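dt <- 1000 / 300

series_of <- function(left, right = left, rate = 300) {
  t <- (seq_along(left) - 1) * 1000 / rate
  pupil_series(t, left, right)
}

test_that("range filter excludes implausible diameters (strict bounds)", {
  s <- series_of(c(1.9, 5.0, 8.1, 2.0, 8.0, NA))
  f <- range_filter(s)
  expect_equal(f$valid_l, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(f$left_mm, s$left_mm) # values untouched, only flags change
  expect_identical(range_filter(f)$valid_l, f$valid_l) # idempotent
})

test_that("dilation-speed filter flags an isolated spike", {
  # on a series long enough for robust statistics the spike sample is
  # removed (together with its neighbours, whose bidirectional speed also
  # reflects the jump)
  x <- rep(4, 20); x[10] <- 7
  s <- series_of(x)
  f <- dilation_speed_filter(s)
  expect_false(f$valid_l[10])
  expect_true(all(f$valid_l[c(1:8, 12:20)]))
  # in a 6-sample series half the speeds touch the spike, so median + 3*MAD
  # cannot single it out; the filter must agree with the brute-force oracle,
  # which keeps all samples here
  s6 <- series_of(c(4, 4, 4, 7, 4, 4))
  f6 <- dilation_speed_filter(s6)
  expect_equal(f6$valid_l,
               brute_dilation_filter(s6$t_ms, s6$left_mm, rep(TRUE, 6)))
  expect_true(all(f6$valid_l))
})

test_that("dilation-speed filter leaves constant series untouched", {
  s <- series_of(rep(4, 10))
  expect_true(all(dilation_speed_filter(s)$valid_l))
})

test_that("dilation-speed filter warns and passes through on <3 valid samples", {
  s <- series_of(c(4, NA, NA, NA, NA, 4))
  f <- dilation_speed_filter(s)
  expect_false(is.null(attr(f, "warnings")))
  expect_equal(f$valid_l, s$valid_l)
})

test_that("dilation-speed filter matches the brute-force oracle", {
  set.seed(401)
  for (rep in 1:100) {
    n <- sample(4:20, 1)
    t <- cumsum(runif(n, 2, 5))
    x <- runif(n, 3, 6)
    spikes <- runif(n) < 0.15
    x[spikes] <- x[spikes] + sample(c(-1, 1), sum(spikes), TRUE) *
      runif(sum(spikes), 0.5, 3)
    valid <- runif(n) > 0.1
    if (sum(valid) < 3) next
    s <- pupil_series(t, x, x, valid_l = valid, valid_r = valid)
    got <- dilation_speed_filter(s)
    want <- brute_dilation_filter(t, x, valid & is.finite(x))
    expect_equal(got$valid_l, want)
  }
})

test_that("blink detection labels 75-250 ms gaps and pads 27 ms", {
  # 30 missing samples at 300 Hz = 100 ms gap
  left <- rep(5, 120)
  left[41:70] <- NA
  s <- series_of(left)
  f <- detect_blinks(s)
  expect_true(all(f$blink_l[41:70]))
  # 8 samples on each side are discarded (offsets <= 27 ms at 3.33 ms)
  expect_true(all(!f$valid_l[33:40]))
  expect_true(all(!f$valid_l[71:78]))
  expect_true(f$valid_l[32] && f$valid_l[79])
})

test_that("a 50 ms gap is not a blink and gets no padding", {
  left <- rep(5, 120)
  left[41:55] <- NA # 15 samples = 50 ms
  f <- detect_blinks(series_of(left))
  expect_false(any(f$blink_l))
  expect_true(all(f$valid_l[c(1:40, 56:120)]))
})

test_that("interpolation imputes interior gaps up to 300 ms linearly", {
  left <- c(rep(4, 30), rep(NA, 60), rep(5, 30)) # 200 ms interior gap
  s <- series_of(left)
  f <- interpolate_gaps(s)
  expect_true(all(f$valid_l))
  expect_true(all(f$imputed_l[31:90]))
  expect_true(all(diff(f$left_mm[30:91]) > 0)) # strictly increasing
  expect_equal(f$left_mm[31:90],
               approx(c(s$t_ms[30], s$t_ms[91]), c(4, 5),
                      xout = s$t_ms[31:90])$y)
})

test_that("long gaps and edge gaps are left missing", {
  long <- c(rep(4, 30), rep(NA, 120), rep(5, 30)) # 400 ms
  f <- interpolate_gaps(series_of(long))
  expect_true(all(!f$valid_l[31:150]))
  edge <- c(rep(NA, 30), rep(5, 60))
  f2 <- interpolate_gaps(series_of(edge))
  expect_true(all(!f2$valid_l[1:30]))
})

test_that("filter stages never un-mark an invalid sample", {
  set.seed(77)
  for (rep in 1:25) {
    s <- random_pupil_series(200)
    s1 <- range_filter(s)
    expect_true(all(s$valid_l | !s1$valid_l))
    s2 <- dilation_speed_filter(s1)
    expect_true(all(s1$valid_l | !s2$valid_l))
    s3 <- detect_blinks(s2)
    expect_true(all(s2$valid_l | !s3$valid_l))
    # interpolation may restore samples, but only flagged as imputed
    s4 <- interpolate_gaps(s3)
    restored <- s4$valid_l & !s3$valid_l
    expect_true(all(s4$imputed_l[restored]))
  }
})

test_that("eye averaging falls back to the single available eye", {
  s <- pupil_series(c(0, dt, 2 * dt), c(4.0, 4.0, NA), c(5.0, NA, NA))
  mono <- average_eyes(s)
  expect_equal(mono$mm, c(4.5, 4.0, NA))
  expect_equal(mono$valid, c(TRUE, TRUE, FALSE))
})

test_that("baseline correction forces zero mean over [0, 250) ms", {
  # piecewise series: 4.0 on [0, 250), 4.6 on [500, 1500)
  t <- seq(0, 1600, by = dt)
  mm <- ifelse(t < 250, 4.0, ifelse(t >= 500 & t < 1500, 4.6, 4.3))
  mono <- data.frame(t_ms = t, mm = mm, valid = TRUE)
  bc <- baseline_correct(mono)
  expect_equal(bc$bps, 4.0)
  expect_equal(mean(bc$series$mm[t < 250]), 0)
  expect_equal(compute_sepr(bc$series), 0.6)
  # constant series: bps = level, corrected identically zero
  const <- data.frame(t_ms = t, mm = 5, valid = TRUE)
  bc2 <- baseline_correct(const)
  expect_equal(bc2$bps, 5.0)
  expect_true(all(bc2$series$mm == 0))
})

test_that("trial validity applies the 50% rule inclusively", {
  mono <- function(frac) {
    n <- 100
    data.frame(t_ms = (seq_len(n) - 1) * dt, mm = 5,
               valid = seq_len(n) <= round(frac * n))
  }
  expect_false(trial_validity(mono(0.49))$included)
  expect_true(trial_validity(mono(0.50))$included)
  v <- trial_validity(mono(1))
  expect_equal(v$valid_fraction, 1)
  expect_true(v$included)
})

test_that("preprocess_trial handles unusable trials", {
  s <- series_of(rep(NA_real_, 100))
  out <- preprocess_trial(s)
  expect_false(out$included)
  expect_true(is.na(out$bps) && is.na(out$sepr))
})

test_that("the compiled fast path agrees with the composed operations", {
  set.seed(88)
  for (rep in 1:40) {
    s <- random_pupil_series(sample(450:650, 1))
    slow <- preprocess_trial(s)
    fast <- oddpupil:::preprocess_trial_values(s)
    expect_equal(fast[1], slow$bps, tolerance = 1e-9)
    expect_equal(fast[2], slow$sepr, tolerance = 1e-9)
    expect_equal(fast[3], slow$valid_fraction, tolerance = 1e-12)
    expect_equal(fast[4] == 1, slow$included)
  }
})

test_that("noise-free synthetic trials recover generator ground truth", {
  p <- params_noise_free()
  set.seed(5)
  tr <- example_trial()
  s <- simulate_pupil_trial(p, tr, list(group = "CON", pupil_intercept_mm = 0))
  truth <- attr(s, "truth")
  out <- preprocess_trial(s)
  expect_true(out$included)
  expect_equal(out$bps, truth$bps, tolerance = 1e-9)
  expect_equal(out$sepr, truth$sepr, tolerance = 1e-9)
})

test_that("a spike-free noise-controlled trial has a very low rejection fraction", {
  # white measurement noise alone drives the MAD filter to its inherent
  # ~5-8% tail rejection, so "noise-controlled" means the smooth kernel only
  p <- generator_params(artifact_spike_rate_per_min = 0,
                        blink_rate_per_min = 0,
                        pupil_noise_sd_mm = 0)
  set.seed(9)
  rejected <- vapply(1:20, function(i) {
    s <- simulate_pupil_trial(p, example_trial(), list(group = "CON"))
    f <- dilation_speed_filter(range_filter(s))
    1 - mean(f$valid_l)
  }, numeric(1))
  expect_lt(mean(rejected), 0.01)
})
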