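fs50 <- filter_spec(50)

test_that("filter_spec validates its band edges and orders", {
  expect_error(filter_spec(50, eog_low = 0), class = "eogstress_parameter_error")
  expect_error(filter_spec(50, eog_low = 8, eog_high = 7.5),
               class = "eogstress_parameter_error")
  expect_error(filter_spec(14, eog_high = 7.5),
               class = "eogstress_parameter_error")
  expect_error(filter_spec(50, accel_cutoff = 30),
               class = "eogstress_parameter_error")
})

test_that("band-pass removes DC and passes/stops tones per its own response", {
  t <- seq(0, 60, by = 1/50)
  # constant offset is entirely outside the 0.25-7.5 Hz passband
  y0 <- bandpass_eog(rep(500, length(t)), fs50)
  expect_lt(max(abs(y0)), 1e-6 * 500)
  # oracle: designed transfer function, squared for forward-backward passes
  bf <- signal::butter(3, c(0.25, 7.5) / 25, type = "pass")
  fr <- signal::freqz(bf, n = 2^14, Fs = 50)
  gain2 <- function(f) abs(fr$h[which.min(abs(fr$f - f))])^2
  mid <- 500:2500
  y2 <- bandpass_eog(100 * sin(2 * pi * 2 * t), fs50)
  expect_lt(abs(20 * log10(max(abs(y2[mid])) / 100) -
                  20 * log10(gain2(2))), 0.5)
  expect_lt(abs(20 * log10(max(abs(y2[mid])) / 100)), 1)  # within 1 dB of unity
  y20 <- bandpass_eog(100 * sin(2 * pi * 20 * t), fs50)
  expect_lt(20 * log10(max(abs(y20[mid])) / 100), -30)
})

test_that("band-pass filtering is idempotent for a passband tone", {
  t <- seq(0, 60, by = 1/50)
  y1 <- bandpass_eog(100 * sin(2 * pi * 2 * t), fs50)
  y2 <- bandpass_eog(y1, fs50)
  mid <- 500:2500
  expect_lt(abs(20 * log10(max(abs(y2[mid])) / max(abs(y1[mid])))), 1)
})

test_that("low-pass keeps DC and follows its designed response", {
  t <- seq(0, 30, by = 1/50)
  expect_equal(lowpass_accel(rep(1, 500), fs50), rep(1, 500), tolerance = 1e-9)
  h <- signal::fir1(8, 10 / 25, type = "low")
  h <- h / sum(h)
  fr <- signal::freqz(h, n = 2^14, Fs = 50)
  gain2 <- function(f) abs(fr$h[which.min(abs(fr$f - f))])^2
  mid <- 300:1200
  y1 <- lowpass_accel(sin(2 * pi * 1 * t), fs50)
  expect_lt(abs(20 * log10(max(abs(y1[mid])))), 1)
  y24 <- lowpass_accel(sin(2 * pi * 24 * t), fs50)
  expect_lt(abs(20 * log10(max(abs(y24[mid]))) - 20 * log10(gain2(24))), 1)
})

test_that("filters reject bad input and preserve length", {
  expect_error(bandpass_eog(c(1, NA, 3), fs50),
               class = "eogstress_input_error")
  expect_error(bandpass_eog(rep(1, 10), fs50),
               class = "eogstress_length_error")
  for (n in c(100, 1013, 44200)) {
    x <- sin(seq_len(n) / 7)
    expect_length(bandpass_eog(x, fs50), n)
    expect_length(lowpass_accel(x, fs50), n)
  }
})

test_that("acceleration magnitude equals the Euclidean norm", {
  expect_equal(accel_magnitude(0, 0, 0), 0)
  expect_equal(accel_magnitude(0.6, 0.8, 0), 1.0)
  withr::with_seed(3, {
    x <- rnorm(200); y <- rnorm(200); z <- rnorm(200)
  })
  expect_equal(accel_magnitude(x, y, z), sqrt(x^2 + y^2 + z^2),
               tolerance = 1e-12)
  expect_error(accel_magnitude(1:3, 1:2, 1:3),
               class = "eogstress_input_error")
})

test_that("artifact mask thresholds at mean + 3 sd with strict inequality", {
  m0 <- compute_artifact_mask(rep(2.5, 100))
  expect_equal(sum(m0$flag), 0)
  expect_equal(m0$threshold_value, 2.5)

  m1 <- compute_artifact_mask(c(rep(1, 999), 5))
  expect_equal(which(m1$flag), 1000L)
  expect_equal(m1$threshold_value, mean(c(rep(1, 999), 5)) +
                 3 * sd(c(rep(1, 999), 5)))

  expect_equal(sum(compute_artifact_mask(rep(0, 50))$flag), 0)
  expect_error(compute_artifact_mask(numeric(0)),
               class = "eogstress_input_error")
})

test_that("artifact removal interpolates only inside guard regions", {
  x <- c(1, 2, 10, 4, 5)
  no_mask <- rep(FALSE, 5)
  expect_identical(remove_artifact_peaks(x, no_mask, 50), x)

  mask <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  y <- remove_artifact_peaks(x, mask, 50, guard_s = 0)
  expect_equal(y[3], 3)          # midpoint of neighbours 2 and 4
  expect_identical(y[-3], x[-3])

  expect_error(remove_artifact_peaks(x, rep(TRUE, 5), 50),
               class = "eogstress_degenerate_input_error")
  expect_error(remove_artifact_peaks(x, mask[1:3], 50),
               class = "eogstress_input_error")
})

test_that("interpolated spans stay within their boundary values", {
  withr::with_seed(8, x <- cumsum(rnorm(500)))
  mask <- rep(FALSE, 500)
  mask[c(100:110, 300:302)] <- TRUE
  y <- remove_artifact_peaks(x, mask, 50, guard_s = 0.1)
  bad <- eogstress:::guard_dilate(mask, 5)
  runs <- rle(bad)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in which(runs$values)) {
    lo <- x[max(1, starts[i] - 1)]
    hi <- x[min(500, ends[i] + 1)]
    seg <- y[starts[i]:ends[i]]
    expect_true(all(seg >= min(lo, hi) - 1e-12 & seg <= max(lo, hi) + 1e-12))
  }
})

test_that("injected motion spikes are cleaned from the EOG of a session", {
  cfg <- tiny_config(seed = 11, artifact_rate = 6)
  s <- render_session(cfg)
  n_art <- length(s$truth$artifact_times_s)
  expect_gt(n_art, 2)
  p <- preprocess_session(s)
  raw_bp <- bandpass_eog(s$signals$eog_v, filter_spec(s$sampling_rate))
  art_idx <- round(s$truth$artifact_times_s * s$sampling_rate) + 1
  # every spike apex is altered by the cleaning
  expect_true(all(abs(p$signals$eog_v[art_idx] - raw_bp[art_idx]) > 1e-9))
  # the cleaned apex no longer carries the 400 uV spike
  expect_true(all(abs(p$signals$eog_v[art_idx]) <
                    abs(raw_bp[art_idx])))
  # >= 99% of samples outside the guard regions are untouched
  guard <- eogstress:::guard_dilate(p$artifact_mask$flag,
                                    round(0.5 * s$sampling_rate))
  expect_gt(mean(p$signals$eog_v[!guard] == raw_bp[!guard]), 0.99)
})
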