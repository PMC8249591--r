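test_that("vector strength matches Fourier closed forms", {
  fs <- 2e4; fm <- 100
  t <- seq(0, 0.4 - 1 / fs, by = 1 / fs)      # integer number of periods
  r <- 80 * (1 + cos(2 * pi * fm * t))
  expect_equal(vector_strength(r, fs, fm), 0.5, tolerance = 1e-9)

  expect_equal(vector_strength(rep(55, length(t)), fs, fm), 0, tolerance = 1e-12)

  # half-wave-rectified cosine: VS = pi/4
  rh <- pmax(cos(2 * pi * fm * t), 0)
  expect_equal(vector_strength(rh, fs, fm), pi / 4, tolerance = 1e-3)

  expect_error(vector_strength(numeric(100), fs, fm), "undefined")

  # bounded by 1 for any non-negative rate
  set.seed(8)
  for (i in 1:20) {
    rr <- stats::runif(4000)^2
    vs <- vector_strength(rr, fs, fm)
    expect_gte(vs, 0); expect_lte(vs, 1)
  }
})

test_that("half-wave rectified RMS of a sinusoid is half the amplitude", {
  fs <- 2e4
  t <- seq(0, 0.1 - 1 / fs, by = 1 / fs)
  for (a in c(0.5, 1, 3)) {
    expect_equal(half_wave_rms(a * sin(2 * pi * 500 * t)), a / 2,
                 tolerance = 1e-3 / 2)  # discrete error < 1e-3 * a
  }
  expect_equal(half_wave_rms(numeric(100)), 0)
})

test_that("RMSE matches a brute-force oracle", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5 + 2, 1:5), 2)
  set.seed(6)
  a <- stats::rnorm(100); b <- stats::rnorm(100)
  brute <- sqrt(sum(vapply(seq_along(a), function(i) (a[i] - b[i])^2,
                           numeric(1))) / length(a))
  expect_equal(rmse(a, b), brute)
  expect_error(rmse(1:3, 1:4), "shape")
})

test_that("AC/DC convention on a constructed receptor potential", {
  fs <- 1e5; onset <- 0.02
  t <- seq(0, 0.1 - 1 / fs, by = 1 / fs)
  v <- rep(-57e-3, length(t))
  after <- t >= onset
  v[after] <- -57e-3 + 5e-3 + 2.5e-3 * sin(2 * pi * 1000 * (t[after] - onset))
  expect_equal(ac_dc_from_trace(v, fs, onset), (2.5e-3 / sqrt(2)) / 5e-3,
               tolerance = 1e-3)
  # DC-only response has zero ratio
  v2 <- rep(-57e-3, length(t)); v2[after] <- -52e-3
  expect_equal(ac_dc_from_trace(v2, fs, onset), 0)
})

test_that("a constant-rate dummy model yields a flat rate-level curve", {
  dummy <- periph_model(
    predict = function(stim)
      response_field(matrix(77, length(stim$samples), 1), stim$fs, 1007,
                     "spikes_per_s"),
    cf_axis = 1007, fs_in = 2e4, stage = "anf", name = "dummy")
  rl <- rate_level_curve(dummy, 1007, levels = c(10, 50, 90))
  expect_equal(rl$y, rep(77, 3))
  # metric procedures are pure: repeated calls identical
  expect_identical(rl, rate_level_curve(dummy, 1007, levels = c(10, 50, 90)))
})

test_that("teacher firing rates phase-lock at 1 kHz but not at 4 kHz", {
  m <- wrap_teacher_model("anf", c(1000, 4000), fiber = fiber_preset("hsr"))
  comp <- function(mc, f0) {
    o <- round((mc$meta$onset + 0.1) * mc$meta$fs)
    seg <- mc$y[o:(o + round(0.2 * mc$meta$fs))]
    Mod(mean((seg - mean(seg)) * exp(-2i * pi * f0 * (seq_along(seg) - 1) /
                                       mc$meta$fs))) / mean(seg)
  }
  f1 <- firing_rate_response(m, 1000, "tone")
  f4 <- firing_rate_response(m, 4000, "tone")
  expect_gt(comp(f1, 1000), 2 * comp(f4, 4000))
  # silence region reproduces the spontaneous rate
  pre <- f1$y[1:round(0.015 * f1$meta$fs)]
  expect_equal(mean(pre), 68.5, tolerance = 0.01)
})

test_that("the evaluation report covers the requested metrics with zero self-RMSE", {
  cfs <- c(1000, 2000)
  ihc <- wrap_teacher_model("ihc", cfs)
  anf <- wrap_teacher_model("anf", cfs, fiber = fiber_preset("hsr"))
  both <- list(ihc = ihc, anf = anf)
  rep <- evaluate_surrogate(both, both)
  expect_named(rep$metrics, c("excitation_pattern", "ac_dc_ratio",
                              "potential_level_growth", "firing_rate",
                              "rate_level", "synchrony_level"))
  expect_length(rep$rmse, 6)
  expect_true(all(rep$rmse == 0))
})
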