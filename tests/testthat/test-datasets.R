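test_that("resampling preserves length, passband amplitude and rejects aliases", {
  x <- pure_tone(1000, 70, 1.0, 1e5, ramp_dur = 0)$samples
  y <- resample_to_model_rate(x, 1e5, 2e4)
  expect_length(y, 20000)

  # passband tone survives with < 0.1 dB amplitude loss
  seg <- y[2000:18000]
  loss_dB <- 20 * log10(sqrt(mean(seg^2)) / sqrt(mean(x^2)))
  expect_lt(abs(loss_dB), 0.1)

  # a tone above the output Nyquist is rejected by > 60 dB
  hi <- pure_tone(12000, 70, 0.5, 1e5, ramp_dur = 0)$samples
  yh <- resample_to_model_rate(hi, 1e5, 2e4)
  rej_dB <- 20 * log10(sqrt(mean(yh[1000:9000]^2)) / sqrt(mean(hi^2)))
  expect_lt(rej_dB, -60)

  expect_length(resample_to_model_rate(numeric(12345), 1e5, 2e4),
                round(12345 / 5))
})

test_that("stage scalings match their conventions and round-trip exactly", {
  expect_equal(scale_signal(1e-6, "bm"), 1.0)
  expect_equal(scale_signal(-0.057, "ihc"), -0.57)
  expect_equal(scale_signal(100, "anf"), 1.0)
  set.seed(4)
  for (stage in c("bm", "ihc", "anf")) {
    x <- stats::rnorm(100)
    expect_equal(unscale_signal(scale_signal(x, stage), stage), x,
                 tolerance = 1e-14)
  }
  expect_error(scale_signal(1, "cochlea"))
  rf <- response_field(stats::rnorm(10), 2e4, 1000, "m")
  expect_equal(scale_signal(rf, "bm")$units, "um_scaled")
  expect_equal(unscale_signal(scale_signal(rf, "bm"), "bm")$values, rf$values)
})

test_that("silence padding adds exact zeros", {
  x <- stats::rnorm(20000)
  y <- add_silence(x, 2e4)
  expect_length(y, 50000)
  expect_identical(y[1:10000], numeric(10000))
  expect_identical(y[30001:50000], numeric(20000))
  expect_identical(y[10001:30000], x)
  expect_identical(add_silence(x, 2e4, 0, 0), x)
})

test_that("window slicing matches the closed-form count and edge policy", {
  sw <- slice_windows(stats::rnorm(20000), 2048, 0.5, 256, 256)
  expect_equal(nrow(sw$inputs), 18)    # floor((20000-2048)/1024)+1
  expect_equal(ncol(sw$inputs), 2560)

  x <- stats::rnorm(512)
  sw1 <- slice_windows(x, 512, 0.5, 64, 64)
  expect_equal(nrow(sw1$inputs), 1)
  expect_identical(sw1$inputs[1, 1:64], numeric(64))     # zero left context
  expect_identical(sw1$inputs[1, 65:576], x)

  expect_warning(slice_windows(stats::rnorm(100), 512), "zero-padding")

  # brute-force enumeration oracle over random lengths
  set.seed(77)
  for (i in 1:200) {
    len <- sample(512:30000, 1)
    L <- sample(c(128, 256, 512, 2048), 1)
    if (len < L) next
    hop <- L / 2
    n_brute <- length(seq(1, len - L + 1, by = hop))
    expect_equal(nrow(slice_windows(stats::rnorm(len), L)$inputs), n_brute)
  }
})

test_that("CF flattening yields one sequence per item-channel pair", {
  mk_pair <- function(ncf, n = 8) {
    cf <- seq(100, 1000, length.out = ncf)
    list(input = response_field(matrix(stats::rnorm(n * ncf), n), 2e4, cf, "m"),
         target = response_field(matrix(stats::rnorm(n * ncf), n), 2e4, cf, "V"))
  }
  seqs <- flatten_cf(replicate(10, mk_pair(3), simplify = FALSE))
  expect_length(seqs, 30)
  expect_length(flatten_cf(list(mk_pair(1))), 1)
  # total sample count is preserved
  expect_equal(sum(lengths(lapply(seqs, `[[`, "input"))), 10 * 3 * 8)
  bad <- list(list(input = mk_pair(2)$input, target = mk_pair(3)$target))
  expect_error(flatten_cf(bad), "share")
})

test_that("Greenwood axis hits its endpoints and inverts through the map", {
  cf <- greenwood_cf_axis(201, 112, 12000)
  expect_length(cf, 201)
  expect_equal(cf[1], 112, tolerance = 1e-9)
  expect_equal(cf[201], 12000, tolerance = 1e-9)
  expect_true(all(diff(cf) > 0))
  # uniform spacing in place: the midpoint's place is the mean of the ends
  place <- function(f) log10(f / 165.4 + 0.88) / 2.1
  expect_equal(place(cf[101]), (place(112) + place(12000)) / 2,
               tolerance = 1e-12)
  expect_equal(165.4 * (10^(2.1 * place(cf[50])) - 0.88), cf[50],
               tolerance = 1e-9)
  expect_error(greenwood_cf_axis(10, 5000, 100), "below")
})

test_that("the full training-set pipeline is deterministic with exact geometry", {
  corpus <- speech_like_corpus(2, 0.3, 1e5, seed = 21)
  spec <- desk_specs()$ihc
  ws <- build_training_set(corpus, "ihc", spec, cf_axis = 1000, seed = 21)
  # per sequence: 0.3 s at 20 kHz = 6000 samples, L 512 hop 256
  n_per <- floor((6000 - 512) / 256) + 1
  expect_equal(nrow(ws$inputs), 2 * n_per)
  expect_equal(ncol(ws$inputs), spec$L_c)
  expect_equal(ncol(ws$targets), spec$L)
  ws2 <- build_training_set(corpus, "ihc", spec, cf_axis = 1000, seed = 21)
  expect_identical(ws$inputs, ws2$inputs)
  expect_identical(ws$targets, ws2$targets)
  # synapse-stage sets add 0.5 + 1 s of silence before slicing
  wsa <- build_training_set(corpus[1], "anf", desk_specs()$anf,
                            cf_axis = 1000, fiber = fiber_preset("hsr"))
  n_anf <- floor(((6000 + 30000) - 512) / 256) + 1
  expect_equal(nrow(wsa$inputs), n_anf)
})
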