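test_that("Hodgkin-Huxley axon rests, spikes, and matches an independent solver", {
  # zero current: stays near rest
  v0 <- simulate_hh(step_current(0, 0, 0.1, 1e5, total = 0.1))
  expect_true(all(abs(v0[2000:10000] - v0[10000]) < 1))
  expect_equal(count_spikes(v0), 0)

  # sustained 10 uA/cm^2: repetitive spiking, bounded amplitude
  v10 <- simulate_hh(step_current(10, 0.01, 0.5, 1e5, total = 0.52))
  expect_gt(count_spikes(v10), 10)
  expect_lt(diff(range(v10)), 120)

  # deterministic
  expect_identical(v10, simulate_hh(step_current(10, 0.01, 0.5, 1e5,
                                                 total = 0.52)))

  # sustained current >= 7.5 uA/cm^2: non-decaying train (bounded ISIs)
  v75 <- simulate_hh(step_current(7.5, 0.01, 1.0, 1e5, total = 1.01))
  crossings <- which(diff(v75 > 0) == 1)
  expect_gt(length(crossings), 30)
  expect_lt(max(diff(crossings)) / 1e5, 0.05)   # no gap longer than 50 ms

  skip_if_not_installed("deSolve")
  # independent oracle: adaptive lsoda on the same equations
  p <- hh_params()
  am <- function(V) ifelse(abs(V + 40) < 1e-7, 1, 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10)))
  bm <- function(V) 4 * exp(-(V + 65) / 18)
  ah <- function(V) 0.07 * exp(-(V + 65) / 20)
  bh <- function(V) 1 / (1 + exp(-(V + 35) / 10))
  an <- function(V) ifelse(abs(V + 55) < 1e-7, 0.1, 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10)))
  bn <- function(V) 0.125 * exp(-(V + 65) / 80)
  deriv <- function(t, y, parms) {
    V <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    I <- if (t >= 10 && t < 110) 10 else 0
    dV <- (I - p$gNa * m^3 * h * (V - p$ENa) - p$gK * n^4 * (V - p$EK) -
             p$gL * (V - p$EL)) / p$Cm
    list(c(dV, am(V) * (1 - m) - bm(V) * m, ah(V) * (1 - h) - bh(V) * h,
           an(V) * (1 - n) - bn(V) * n))
  }
  V0 <- -65
  y0 <- c(V0, am(V0) / (am(V0) + bm(V0)), ah(V0) / (ah(V0) + bh(V0)),
          an(V0) / (an(V0) + bn(V0)))
  sol <- deSolve::lsoda(y0, seq(0, 120, by = 0.01), deriv, NULL,
                        rtol = 1e-8, atol = 1e-8)
  v_ora <- sol[, 2]
  v_mine <- simulate_hh(step_current(10, 0.010, 0.100, 1e5, total = 0.120))
  expect_equal(count_spikes(v_mine), count_spikes(v_ora))
})

test_that("synapse presets reproduce their spontaneous rates from silence", {
  sil <- response_field(rep(ihc_params()$v_rest, 1e5), 1e5, 1000, "V")
  for (tp in c("hsr", "msr", "lsr")) {
    f <- fiber_preset(tp)
    r <- simulate_anf(sil, f)
    expect_equal(mean(r$values[50001:1e5, 1]), f$sr_target, tolerance = 0.5 /
                   f$sr_target)
    expect_true(all(r$values >= 0))
  }
})

test_that("synapse shows onset adaptation and conserves its store budget", {
  f <- fiber_preset("hsr")
  stim <- pure_tone(1000, 70, 0.4, 1e5)
  v <- simulate_periphery(stim, 1000, "ihc")
  r <- simulate_anf(v, f, keep_states = TRUE)
  rate <- r$values[, 1]
  n <- length(rate)
  expect_gt(max(rate[1:2000]), mean(rate[(n - 10000):n]))
  # flux bookkeeping: total content tracks the integral of its explicit fluxes
  content <- sum(attr(r, "states")[n, ])
  expect_lt(abs(attr(r, "budget_residual")), 1e-8 * content)
  # deterministic
  expect_identical(r$values, simulate_anf(v, f)$values)
})

test_that("IHC stand-in rests at its resting potential and phase-locks selectively", {
  sil <- stimulus(numeric(20000), 1e5, NULL, "corpus_item")
  v <- simulate_periphery(sil, 1000, "ihc")
  expect_equal(max(abs(v$values - ihc_params()$v_rest)), 0, tolerance = 1e-9)

  m <- wrap_teacher_model("ihc", c(250, 2000))
  acdc <- ac_dc_ratio(m, freqs = c(250, 2000))
  expect_lt(acdc$y[2], acdc$y[1])   # phase-locking loss at high frequency

  g <- potential_level_growth(m, levels = seq(0, 90, by = 15))
  expect_true(all(diff(g$y) >= 0))  # monotone growth 0-90 dB
})

test_that("adaptation-time estimation matches the analytic exponential", {
  fs <- 1e4; tau <- 0.010
  t <- seq(0, 0.5, by = 1 / fs)
  r_ss <- 100; r_pk <- 300
  r <- r_ss + (r_pk - r_ss) * exp(-t / tau)
  est <- estimate_adaptation_time(r, fs)
  expected <- tau * log((r_pk - r_ss) / (0.05 * r_ss))
  expect_equal(est, expected, tolerance = 0.02)

  flat <- estimate_adaptation_time(rep(5, 1000), fs)
  expect_equal(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "warn")))

  # synapse adaptation outlasts IHC membrane adaptation
  stim <- pure_tone(1000, 70, 1.0, 1e5)
  rate <- simulate_periphery(stim, 1000, "anf", fiber_preset("lsr"))$values[, 1]
  vihc <- simulate_periphery(stim, 1000, "ihc")$values[, 1]
  t_anf <- estimate_adaptation_time(rate, 1e5)
  t_ihc <- estimate_adaptation_time(vihc - min(vihc), 1e5, oscillatory = TRUE)
  expect_gt(t_anf, t_ihc)
})

test_that("steady-state fraction follows its definition", {
  fs <- 1e4
  t <- seq(0, 1, by = 1 / fs)
  r <- 50 + 200 * exp(-t / 0.05)
  fr <- steady_state_fraction(r, fs, 0.4, 1)
  sm <- function(tt) mean(50 + 200 * exp(-seq(tt - 0.0099, tt, by = 1e-4) / 0.05))
  expect_equal(fr, sm(0.4) / sm(1), tolerance = 1e-3)
  expect_equal(steady_state_fraction(rep(7, 10000), fs, 0.4, 1), 1.0)
  expect_error(steady_state_fraction(rep(0, 10000), fs, 0.4, 1), "zero")
  # the high-SR fiber is closer to its steady state at 0.4 s than the low-SR
  stim <- pure_tone(1000, 70, 1.0, 1e5)
  fh <- simulate_periphery(stim, 1000, "anf", fiber_preset("hsr"))$values[, 1]
  fl <- simulate_periphery(stim, 1000, "anf", fiber_preset("lsr"))$values[, 1]
  expect_lt(abs(steady_state_fraction(fh, 1e5, 0.4, 1) - 1),
            abs(steady_state_fraction(fl, 1e5, 0.4, 1) - 1))
})
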