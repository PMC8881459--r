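# Coherence, phase, PLV, surrogate significance, spike-field locking.

test_that("Welch msc: self-coherence is 1, independents sit at the 1/K bias", {
  set.seed(5)
  x <- rnorm(8000)
  coh <- power_coherence(x, x, fs = 1000)
  expect_true(all(coh$msc > 1 - 1e-9))
  y <- rnorm(8000)
  c2 <- power_coherence(x, y, fs = 1000)
  expect_equal(mean(c2$msc), 1 / c2$n_segments, tolerance = 0.5)
  expect_true(all(c2$msc >= 0 & c2$msc <= 1))
  expect_error(power_coherence(x, y[-1], fs = 1000), "equal length")
})

test_that("Welch msc matches the independent direct implementation", {
  set.seed(6)
  s <- tone(5, 500, 12)
  x <- s + rnorm(6000, sd = 0.7)
  y <- s + rnorm(6000, sd = 0.7)
  coh <- power_coherence(x, y, fs = 500)
  ora <- msc_direct(x, y, fs = 500)
  expect_equal(coh$msc, ora$msc, tolerance = 1e-10)
  expect_equal(coh$n_segments, ora$K)
})

test_that("common-signal coherence matches its closed form within 10%", {
  # x = s + e1, y = s + e2: msc = Ps^2 / ((Ps+Pe1)(Ps+Pe2)) at the tone,
  # with powers measured per frequency bin
  set.seed(7)
  fs <- 500; dur <- 60
  s <- tone(1, fs, dur)
  sd_e <- 1
  x <- s + rnorm(fs * dur, sd = sd_e)
  y <- s + rnorm(fs * dur, sd = sd_e)
  coh <- power_coherence(x, y, fs = fs, segment_s = 2)
  i1 <- which.min(abs(coh$freq - 1))
  # per-bin noise power: variance spread over nf bins of the one-sided grid
  w <- slowsync:::welch_spectra(x, NULL, fs = fs, nseg = 2 * fs)
  df <- w$freq[2] - w$freq[1]
  Ps <- 0.5 / df                      # tone power density in its bin
  Pe <- sd_e^2 / (fs / 2)             # white density
  expected <- Ps^2 / ((Ps + Pe)^2)
  expect_equal(coh$msc[i1], expected, tolerance = 0.1)
})

test_that("gamma envelope demodulates amplitude modulation", {
  fs <- 1000; dur <- 120
  t <- (0:(fs * dur - 1)) / fs
  x <- (1 + 0.8 * cos(2 * pi * 0.1 * t)) * cos(2 * pi * 50 * t)
  env <- gamma_envelope(x, fs = fs)
  expect_equal(env$dt, 0.5)
  es <- envelope_spectrum(env, correct_1f = FALSE)
  sel <- es$freq > 0.02 & es$freq < 0.6
  expect_equal(es$freq[sel][which.max(es$power[sel])], 0.10,
               tolerance = 0.02)
  # constant-amplitude tone: envelope variance negligible vs its mean
  x0 <- cos(2 * pi * 50 * t)
  e0 <- gamma_envelope(x0, fs = fs)
  expect_lt(sd(e0$power) / mean(e0$power), 0.01)
})

test_that("1/f correction flattens a white gamma-power envelope spectrum", {
  set.seed(31)
  fits <- vapply(1:5, function(s) {
    env <- structure(list(power = abs(rnorm(480, 5, 1)), dt = 0.5,
                          band = c(30, 70)),
                     class = "envelope_series")
    es <- envelope_spectrum(env, correct_1f = TRUE)
    sel <- es$freq >= 0.02 & es$freq <= 0.5 & es$power > 0
    coef(lm(log10(es$power[sel]) ~ log10(es$freq[sel])))[2]
  }, numeric(1))
  expect_lt(abs(mean(fits)), 0.25)
})

test_that("ultra-slow envelope coherence: identity, independence, construction", {
  set.seed(32)
  mk_env <- function(p) structure(list(power = p, dt = 0.5),
                                  class = "envelope_series")
  shared <- 2 + cos(2 * pi * 0.1 * seq(0, 239.5, by = 0.5))
  e1 <- mk_env(shared + rnorm(480, sd = 0.1))
  expect_equal(ultraslow_envelope_coherence(e1, e1)$coherence, 1,
               tolerance = 1e-6)
  e2 <- mk_env(2 + rnorm(480, sd = 0.5))
  ind <- ultraslow_envelope_coherence(e1, e2)
  expect_lt(ind$coherence, 3 / ind$n_segments)
  # shared infra-slow modulation, independent fast noise: coherence
  # concentrated in the 0.02-0.5 Hz band
  e3 <- mk_env(shared + rnorm(480, sd = 0.3))
  e4 <- mk_env(shared + rnorm(480, sd = 0.3))
  res <- ultraslow_envelope_coherence(e3, e4)
  # the single 0.1 Hz line is near-perfectly coherent; the band integral
  # dilutes it across null bins but must still clearly exceed independence
  expect_gt(res$msc[which.min(abs(res$freq - 0.1))], 0.8)
  expect_gt(res$coherence, ind$coherence + 0.05)
})

test_that("instantaneous phase follows the stated peak/trough convention", {
  fs <- 1000
  x <- tone(2, fs, 30)
  ph <- instantaneous_phase(x, "delta", fs = fs)
  expect_true(all(ph$phase > -pi & ph$phase <= pi))
  # peaks of cos(2 pi 2 t) at t = k/2: phase 0; troughs at t = k/2 + 1/4: pi
  peak_t <- seq(2, 27, by = 0.5)
  trough_t <- peak_t + 0.25
  expect_lt(max(abs(wrap_pi(ph$phase[round(peak_t * fs) + 1]))), 0.05)
  expect_lt(max(abs(wrap_pi(ph$phase[round(trough_t * fs) + 1] - pi))), 0.05)
  # unwrapped phase advances at 2 pi f
  up <- slowsync:::unwrap_phase(ph$phase[5000:25000])
  slope <- unname(coef(lm(up ~ seq_along(up)))[2]) * fs
  expect_equal(slope, 2 * pi * 2, tolerance = 0.01)
  expect_warning(instantaneous_phase(tone(60, fs, 30), "delta", fs = fs),
                 "unreliable")
})

test_that("lfp_plv equals the printed formula and its limit cases", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:1000, 1)
    t1 <- runif(n, -pi, pi); t2 <- runif(n, -pi, pi)
    expect_equal(lfp_plv(t1, t2)$plv, plv_direct(t1, t2),
                 tolerance = 1e-12)
  }
  t1 <- runif(300, -pi, pi)
  expect_equal(lfp_plv(t1, t1)$plv, 1)
  expect_equal(lfp_plv(t1 + 0.7, t1)$plv, 1, tolerance = 1e-12)
  eq <- seq(-pi + 2 * pi / 360, pi, length.out = 360)
  expect_equal(lfp_plv(eq, numeric(360))$plv, 0, tolerance = 1e-12)
})

test_that("surrogate significance: strong coupling flagged, null controlled", {
  fs <- 250
  s <- tone(2.5, fs, 24)
  x <- s + rnorm(6000, sd = 0.2)
  res <- plv_significance(x, x, band = "delta", fs = fs,
                          n_surrogates = 40, rng_seed = 1)
  expect_true(res$significant)
  expect_equal(res$plv, 1, tolerance = 1e-9)
  # independent noise pairs: conjunctive rule keeps the rate near nominal
  set.seed(52)
  flags <- vapply(1:40, function(i) {
    r <- plv_significance(rnorm(2500), rnorm(2500), band = "delta",
                          fs = fs, n_surrogates = 25, rng_seed = 100 + i)
    # the absolute floor is conjunctive: plv <= 0.1 can never be significant
    if (r$plv <= 0.1) expect_false(isTRUE(r$significant))
    r$significant
  }, logical(1))
  expect_lte(mean(flags), 0.15)
  expect_error(plv_significance(rep(1, 2500), rnorm(2500), band = "delta",
                                fs = fs), "degenerate")
})

test_that("preferred phase difference: lags, zero, and degenerate mixtures", {
  th <- runif(1000, -pi, pi)
  d <- preferred_phase_difference(th, wrap_pi(th - pi / 2))
  expect_equal(d$mean, pi / 2, tolerance = 1e-9)
  expect_equal(d$resultant, 1, tolerance = 1e-9)
  expect_equal(preferred_phase_difference(th, th)$mean, 0)
  # invariance under adding the same constant to both series
  d2 <- preferred_phase_difference(wrap_pi(th + 1), wrap_pi(th + 1 - pi / 2))
  expect_equal(d2$mean, pi / 2, tolerance = 1e-9)
  expect_warning(
    da <- preferred_phase_difference(c(rep(0, 500), rep(pi, 500)),
                                     numeric(1000)),
    "unreliable")
  expect_lt(da$resultant, 0.05)
})

test_that("spike phase locking: limits and histogram normalization", {
  fs <- 1000
  ph <- phase_series(wrap_pi(2 * pi * 1 * (0:(20 * fs - 1)) / fs), fs)
  st1 <- spike_train(seq(0.5, 19.5, by = 1))    # all at the trough (pi)
  r1 <- spike_phase_locking(st1, ph)
  expect_equal(r1$plv, 1, tolerance = 1e-6)
  expect_equal(abs(r1$preferred), pi, tolerance = 0.01)
  st2 <- spike_train(seq(0.05, 19.9, by = 1 / 8))  # uniform phase grid
  r2 <- spike_phase_locking(st2, ph)
  expect_lt(r2$plv, 0.02)
  expect_equal(sum(r2$histogram$prob), 1)
  expect_true(all(r2$histogram$prob >= 0))
  expect_true(is.na(spike_phase_locking(spike_train(0.5), ph)$plv))
})

test_that("phase-lag recovery through the full filter chain", {
  # injected lags at 2 Hz with SNR >= 3 recovered within 0.1 rad
  for (lag in c(0, pi / 4, pi / 2, pi)) {
    spec <- lfp_spec(list(list(frequency = 2, amplitude = 1,
                               phase = c(0, -lag))),
                     noise_sd = 0.33, duration = 30, sampling_rate = 500,
                     n_channels = 2, rng_seed = round(100 * lag) + 3)
    x <- gen_coupled_lfp(spec)
    p1 <- instantaneous_phase(x, "delta", channel = 1)
    p2 <- instantaneous_phase(x, "delta", channel = 2)
    d <- preferred_phase_difference(p1, p2)
    expect_lt(abs(wrap_pi(d$mean - lag)), 0.1)
  }
})
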