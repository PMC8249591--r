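test_that("pure-tone level calibration matches the closed form", {
  # RMS = p0 * 10^(L/20) for an unramped tone
  s <- pure_tone(1000, 70, 0.1, 2e4, ramp_dur = 0)
  expect_equal(sqrt(mean(s$samples^2)), 2e-5 * 10^3.5, tolerance = 1e-9)
  expect_equal(rms_level_dB(s), 70, tolerance = 1e-9)

  s0 <- pure_tone(750, 0, 0.1, 2e4, ramp_dur = 0)
  expect_equal(sqrt(mean(s0$samples^2)), 2e-5, tolerance = 1e-9)

  # sinusoid peak is sqrt(2) times the RMS
  expect_equal(max(abs(s$samples)), sqrt(2) * sqrt(mean(s$samples^2)),
               tolerance = 1e-6)

  # calibration holds across random frequency/level combinations
  # (frequencies snapped to integer cycles per 50-ms window so the discrete
  # RMS of the sinusoid is exact)
  for (i in 1:20) {
    f <- 20 * sample(5:450, 1); L <- stats::runif(1, 0, 100)
    st <- pure_tone(f, L, 0.05, 2e4, ramp_dur = 0)
    expect_equal(rms_level_dB(st), L, tolerance = 1e-9)
  }
})

test_that("tone generation rejects aliasing and bad durations", {
  expect_error(pure_tone(12000, 70, 0.1, 2e4), "aliasing")
  expect_error(pure_tone(1000, 70, -0.1, 2e4), "duration")
  expect_error(pure_tone(1000, 70, 0.005, 2e4, ramp_dur = 0.005), "ramp")
})

test_that("ramping reduces RMS and never renormalises", {
  for (f in c(250, 1000, 4000)) {
    unramped <- pure_tone(f, 70, 0.1, 2e4, ramp_dur = 0)
    ramped <- pure_tone(f, 70, 0.1, 2e4, ramp_dur = 0.005)
    expect_lt(sqrt(mean(ramped$samples^2)), sqrt(mean(unramped$samples^2)))
    # inner portion untouched by the ramps
    expect_equal(ramped$samples[150:1850], unramped$samples[150:1850])
  }
})

test_that("SAM tone follows its closed form, phase-pi onset and RMS contract", {
  fs <- 2e4
  s <- sam_tone(1000, 100, 1, 70, 0.2, fs, ramp_dur = 0)
  t <- (seq_along(s$samples) - 1) / fs
  raw <- (1 + cos(2 * pi * 100 * t + pi)) * sin(2 * pi * 1000 * t)
  # identical up to the global RMS rescaling
  k <- s$samples[500] / raw[500]
  expect_equal(s$samples, raw * k, tolerance = 1e-9)
  # envelope zero at onset for m = 1; half for m = 0.5
  expect_equal(1 + 1 * cos(pi), 0)
  s5 <- sam_tone(1000, 100, 0.5, 70, 0.2, fs, ramp_dur = 0)
  raw5 <- (1 + 0.5 * cos(2 * pi * 100 * t + pi))
  expect_equal(raw5[1], 0.5)
  # RMS calibrated to the requested level after envelope construction
  expect_equal(rms_level_dB(s), 70, tolerance = 1e-6)
  expect_equal(rms_level_dB(s5), 70, tolerance = 1e-6)
  expect_error(sam_tone(1000, 100, 1.5, 70, 0.2, fs), "modulation depth")
})

test_that("tone pairs have exact silent gaps and the stated arithmetic", {
  fs <- 2e4
  tp <- tone_pair(2000, 80, 0.1, 0.4, fs)
  n_tone <- round(0.1 * fs)
  expect_length(tp$samples, 2 * n_tone + round(0.4 * fs))
  gap <- tp$samples[(n_tone + 1):(n_tone + round(0.4 * fs))]
  expect_identical(unique(gap), 0)
  expect_length(gap, 8000)
  expect_length(seq(0.1, 1.9, by = 0.2), 10)
})

test_that("step currents and seeded batches behave as specified", {
  s <- step_current(10, 0.01, 0.05, 1e5)
  expect_equal(sum(s$samples != 0), 5000)
  expect_true(all(step_current(0, 0.01, 0.05, 1e5)$samples == 0))
  b1 <- step_current_batch(5, 0.01, 0.05, 1e5, seed = 9L)
  b2 <- step_current_batch(5, 0.01, 0.05, 1e5, seed = 9L)
  expect_identical(b1, b2)
  amps <- vapply(b1, function(x) max(x$samples), numeric(1))
  expect_true(all(amps >= 0 & amps <= 1000))
})

test_that("speech-like corpus is seeded and level-calibrated", {
  corpus <- speech_like_corpus(10, 0.25, 2e4, seed = 5)
  levels <- vapply(corpus, rms_level_dB, numeric(1))
  expect_equal(levels[1:5], rep(70, 5), tolerance = 1e-6)
  expect_equal(levels[6:10], rep(130, 5), tolerance = 1e-6)
  # odd item count: first ceiling(n/2) at 70 dB
  c3 <- speech_like_corpus(3, 0.1, 2e4, seed = 5)
  expect_equal(vapply(c3, rms_level_dB, numeric(1))[1:2], c(70, 70),
               tolerance = 1e-6)
  # bitwise reproducible
  again <- speech_like_corpus(10, 0.25, 2e4, seed = 5)
  expect_identical(corpus, again)
  # short-term levels of the pooled corpus sit between the two targets
  bins <- unlist(lapply(corpus, binned_levels_dB))
  expect_gt(mean(bins[is.finite(bins)]), 70)
  expect_lt(mean(bins[is.finite(bins)]), 130)
})

test_that("WAV round trip preserves calibrated samples", {
  s <- pure_tone(1000, 65, 0.05, 2e4)
  f32 <- tempfile(fileext = ".wav")
  write_wav(s, f32, bits = 32)
  r32 <- read_wav(f32)
  expect_equal(r32$samples, s$samples, tolerance = 1e-7)
  expect_equal(r32$fs, s$fs)
  expect_equal(r32$level_dB, 65)
  f16 <- tempfile(fileext = ".wav")
  write_wav(s, f16, bits = 16)
  r16 <- read_wav(f16)
  # 16-bit quantisation: error bounded by one quantisation step
  expect_lt(max(abs(r16$samples - s$samples)), max(abs(s$samples)) / 1e4)
})
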