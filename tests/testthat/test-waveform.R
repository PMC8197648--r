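# Envelope extraction, theta bandpass, extrema equalization, phase
# shifting, sham pulse and current scaling.

test_that("envelope extraction recovers known modulators", {
  fs <- 4000
  t <- (0:(fs * 4 - 1)) / fs

  # unmodulated carrier -> flat envelope
  tone <- audio_signal(sin(2 * pi * 440 * t), fs)
  env <- extract_envelope(tone)
  mid <- seq(fs, 3 * fs)
  expect_lt(max(abs(env$values[mid] - 1)), 0.01)

  # AM tone -> the modulator, within 5% away from the edges
  x <- (1 + 0.5 * cos(2 * pi * 5 * t)) * sin(2 * pi * 440 * t)
  env2 <- extract_envelope(audio_signal(x, fs))
  modulator <- 1 + 0.5 * cos(2 * pi * 5 * t)
  expect_lt(max(abs(env2$values[mid] - modulator[mid])), 0.05)

  # all-zero signal -> all-zero envelope
  env3 <- extract_envelope(audio_signal(rep(0, fs), fs))
  expect_equal(env3$values, rep(0, fs))

  # resampling preserves duration and rate bookkeeping
  env4 <- extract_envelope(audio_signal(x, fs), out_rate = 250)
  expect_equal(env4$rate, 250)
  expect_equal(length(env4$values), 250 * 4)

  expect_error(audio_signal(c(1, NA, 3), fs), "non-finite")
})

test_that("theta bandpass matches its own frequency-response oracle and is zero-phase", {
  fs <- 100
  dur <- 60
  t <- (0:(fs * dur - 1)) / fs
  filt <- tacsphase:::design_theta_filter(fs, 4, 8, 6)
  trim <- seq(fs * 15, fs * 45)
  # lock-in amplitude measurement at frequency f of a filtered sinusoid
  measured_gain <- function(f) {
    y <- bandpass_theta(envelope_signal(1 + 0.5 * sin(2 * pi * f * t), fs))$values
    yt <- y[trim]; tt <- t[trim]
    a <- 2 * mean(yt * sin(2 * pi * f * tt))
    b <- 2 * mean(yt * cos(2 * pi * f * tt))
    sqrt(a^2 + b^2) / 0.5
  }
  # forward-backward gain is |H|^2
  for (f in c(6, 1)) {
    oracle <- Mod(tacsphase:::filter_response(filt, f, fs))^2
    expect_lt(abs(measured_gain(f) / oracle - 1), 0.05)
  }
  expect_lt(abs(measured_gain(6) - 1), 0.02)  # 6 Hz sits in the passband

  # DC blocked
  ydc <- bandpass_theta(envelope_signal(rep(2, fs * 10), fs))$values
  expect_lt(max(abs(ydc)), 1e-6)

  # zero phase: cross-correlation with a 6 Hz input peaks at lag 0
  x6 <- sin(2 * pi * 6 * t)
  y6 <- bandpass_theta(x6, rate = fs)$values
  cc <- stats::ccf(y6[trim], x6[trim], lag.max = 8, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # >90% of white-noise output power inside [3, 9] Hz
  set.seed(11)
  yn <- bandpass_theta(abs(rnorm(fs * 30)), rate = fs)$values
  expect_gt(band_power_fraction(yn, band = c(3, 9), rate = fs), 0.9)

  expect_error(bandpass_theta(runif(100), rate = 12), "too low")
  expect_error(tacsphase:::design_theta_filter(100, order = 5), "even")
})

test_that("extrema equalization pins all interior extrema to +/-1", {
  fs <- 250
  # uniform rescale of a pure sinusoid
  t <- (0:(fs * 5 - 1)) / fs
  nw <- equalize_extrema(0.3 * sin(2 * pi * 6 * t), rate = fs)
  ex <- tacsphase:::local_extrema(nw$values)
  expect_gt(length(ex$idx), 10)
  expect_lt(max(abs(abs(nw$values[ex$idx]) - 1)), 1e-6)

  # amplitude-modulated theta signal
  x <- modulated_theta(rate = fs)
  nw2 <- equalize_extrema(x, rate = fs)
  ex2 <- tacsphase:::local_extrema(nw2$values)
  expect_lt(max(abs(abs(nw2$values[ex2$idx]) - 1)), 1e-6)
  # extremum count and alternation preserved
  ex0 <- tacsphase:::local_extrema(x)
  expect_equal(length(ex2$idx), length(ex0$idx))
  expect_equal(ex2$type, ex0$type)

  # idempotence
  nw3 <- equalize_extrema(nw2)
  expect_equal(nw3$values, nw2$values, tolerance = 1e-6)

  expect_error(equalize_extrema(seq(0, 1, length.out = 100), rate = 100),
               "fewer than 2")
})

test_that("phase shifting rotates the analytic signal", {
  fs <- 250
  x <- modulated_theta(rate = fs)

  # identity at 0 degrees
  expect_identical(phase_shift(x, 0, rate = fs), x)

  # exact negation at 180 degrees, arbitrary input
  set.seed(4)
  for (sig in list(x, rnorm(512))) {
    expect_identical(phase_shift(sig, 180, rate = fs), -sig)
  }

  # sin -> cos at +90 degrees
  t <- (0:(fs * 10 - 1)) / fs
  s <- sin(2 * pi * 6 * t)
  y <- phase_shift(s, 90, rate = fs)
  mid <- seq(fs * 2, fs * 8)
  expect_lt(max(abs(y[mid] - cos(2 * pi * 6 * t)[mid])), 1e-6)

  # composition on a periodic narrowband input (integer cycles, so the
  # analytic signal is exact and only the rotation algebra is tested)
  per <- sin(2 * pi * 5 * t) + 0.6 * cos(2 * pi * 6 * t) +
    0.3 * sin(2 * pi * 7 * t)
  y12 <- phase_shift(phase_shift(per, 50, rate = fs), 70, rate = fs)
  y3 <- phase_shift(per, 120, rate = fs)
  expect_lt(max(abs(y12 - y3)), 1e-9)

  # instantaneous amplitude preserved
  amp <- function(v) sqrt(v^2 + tacsphase:::hilbert_im(v)^2)
  y45 <- phase_shift(per, 45, rate = fs)
  expect_lt(max(abs(amp(y45) - amp(per))), 1e-9)
})

test_that("sham pulse has the stated duration, ramps and plateau", {
  sh <- make_sham(rate = 1000)
  expect_equal(sum(sh$values > 0), 500)
  expect_true(all(diff(sh$values[1:100]) > 0))
  expect_true(all(diff(sh$values[401:500]) < 0))
  expect_equal(unique(sh$values[101:400]), sh$max_current)
  expect_equal(sh$source, "sham")

  # rectangular limiting case
  rect <- make_sham(rate = 1000, ramp_ms = 0, max_mA = 1)
  expect_equal(rect$values[1:500], rep(1, 500))

  # plateau would be negative
  expect_error(make_sham(1000, duration_ms = 150, ramp_ms = 100), "plateau")
})

test_that("current scaling is peak-referenced and shape-preserving", {
  fs <- 250
  nw <- equalize_extrema(modulated_theta(rate = fs), rate = fs)
  st <- scale_current(nw, 0.67, source = "target", phase_deg = 90)
  expect_equal(max(abs(st$values)), 0.67)
  expect_equal(st$values / 0.67 * max(abs(nw$values)), nw$values,
               tolerance = 1e-12)
  expect_equal(st$phase_deg, 90)

  unit <- normalized_waveform(sin(2 * pi * 6 * (0:999) / 250), 250)
  expect_equal(max(abs(scale_current(unit, 1)$values)), 1)

  zero <- normalized_waveform(rep(0, 100), 250)
  expect_equal(scale_current(zero, 0.5)$values, rep(0, 100))

  expect_error(scale_current(nw, -1), "positive")
})

test_that("audio-to-stimulus chain is deterministic", {
  fs <- 4000
  t <- (0:(fs * 4 - 1)) / fs
  a <- audio_signal((1 + 0.5 * cos(2 * pi * 5 * t)) * sin(2 * pi * 300 * t),
                    fs)
  w1 <- make_stimulus(a, phase_deg = 90, max_mA = 0.67)
  w2 <- make_stimulus(a, phase_deg = 90, max_mA = 0.67)
  expect_identical(w1$values, w2$values)
  expect_equal(max(abs(w1$values)), 0.67)
})

test_that("envelope pair correlation handles the degenerate and independent cases", {
  set.seed(9)
  e <- runif(500) + 0.5
  # identical -> r = 1
  r1 <- envelope_pair_correlation(list(list(e, e), list(e + 0.1, e + 0.1)))
  expect_equal(unname(r1$r), c(1, 1))
  # anti-correlated with offset -> r = -1
  r2 <- envelope_pair_correlation(list(list(e, -e + 3), list(e, -e + 3)))
  expect_equal(unname(r2$r), c(-1, -1))
  # unequal lengths are truncated and counted
  r3 <- envelope_pair_correlation(list(list(e, c(e, 1))))
  expect_equal(r3$n_truncated, 1L)
  expect_error(envelope_pair_correlation(list(list(e, rep(1, 500)))),
               "zero-variance")
  # independent surrogate pairs -> mean r near 0 (3 SEM)
  pairs <- lapply(1:50, function(i)
    generate_envelope_pair(duration_s = 2, rate = 125, seed = 100 + i))
  rr <- envelope_pair_correlation(pairs)
  expect_lt(abs(rr$mean_r), 3 * rr$sem_r)
})

test_that("WAV files round-trip through the reader and writer", {
  set.seed(2)
  v <- runif(2000, -0.95, 0.95)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(v, f, rate = 8000)
  back <- read_wav(f)
  expect_equal(back$rate, 8000)
  expect_lt(max(abs(back$samples - v)), 1 / 32000)
  write_wav(v, f, rate = 44100, bits = 32)
  back32 <- read_wav(f)
  expect_lt(max(abs(back32$samples - v)), 1e-6)
  expect_equal(back32$rate, 44100)
})
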