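# Interareal and spike-field coupling statistics: Welch power coherence,
# gamma-envelope infra-slow coherence, instantaneous phase, LFP-LFP PLV
# with surrogate significance, preferred-phase differences, and spike
# phase locking.

#' Welch magnitude-squared coherence between two channels
#'
#' `msc(f) = |S_xy|^2 / (S_xx * S_yy)` from Hann-windowed overlapping
#' segments (default 2 s, 50% overlap).
#'
#' @param x,y equal-length numeric vectors, or an [mc_signal()] plus
#'   channel indices via `channels`.
#' @param fs sampling rate (Hz); taken from `x` when it is an `mc_signal`.
#' @param segment_s segment length (s), default 2.
#' @param overlap overlap fraction, default 0.5.
#' @param channels length-2 channel indices when `x` is multichannel.
#' @return a [coherence_spectrum()].
#' @export
power_coherence <- function(x, y = NULL, fs = NULL, segment_s = 2,
                            overlap = 0.5, channels = c(1, 2)) {
  if (inherits(x, "mc_signal")) {
    fs <- x$fs
    y <- x$samples[channels[2], ]
    x <- x$samples[channels[1], ]
  }
  assert_that(!is.null(fs), "fs required")
  assert_that(length(x) == length(y), "signals must have equal length")
  assert_that(length(x) / fs >= 2 * segment_s,
              "need at least 4 s (two segments) of signal")
  nseg <- round(segment_s * fs)
  w <- welch_spectra(x, y, fs = fs, nseg = nseg, overlap = overlap)
  msc <- Mod(w$Pxy)^2 / (w$Pxx * w$Pyy)
  msc[!is.finite(msc)] <- 0
  coherence_spectrum(w$freq, msc, w$n_segments, segment_s, overlap)
}

#' Band-median summary of a coherence spectrum
#' @param coh a [coherence_spectrum()].
#' @param band band name or `[low, high)` pair (Hz).
#' @return median msc over the band.
#' @export
coherence_band_median <- function(coh, band) {
  b <- band_lookup(band)
  sel <- coh$freq >= b[1] & coh$freq < b[2]
  assert_that(any(sel), "band does not overlap the coherence grid")
  stats::median(coh$msc[sel])
}

#' Gamma-band power envelope at 0.5 s resolution
#'
#' Spectrogram with 2 s windows and 75% overlap (0.5 s steps), power
#' integrated over 30-70 Hz per step.
#'
#' @param x numeric vector (one LFP channel) or an [mc_signal()].
#' @param fs sampling rate (Hz) when `x` is a bare vector.
#' @param band integration band (Hz), default gamma 30-70.
#' @param window_s,overlap spectrogram window (s) and overlap fraction.
#' @param min_duration minimum record length (s); 60 s resolves 0.02 Hz.
#' @return object of class `envelope_series`: `power` (one value per step),
#'   `dt` (s), `band`.
#' @export
gamma_envelope <- function(x, fs = NULL, band = c(30, 70), window_s = 2,
                           overlap = 0.75, min_duration = 60) {
  if (inherits(x, "mc_signal")) { fs <- x$fs; x <- x$samples[1, ] }
  assert_that(!is.null(fs), "fs required")
  assert_that(length(x) / fs >= min_duration,
              sprintf("record must be >= %g s", min_duration))
  sp <- compute_spectrogram(x, fs = fs, window_s = window_s,
                            overlap = overlap, df = 1 / window_s,
                            fmax = band[2] + 5)
  structure(list(power = band_power(sp, band), dt = window_s * (1 - overlap),
                 band = band, time = sp$time),
            class = "envelope_series")
}

#' Spectrum of a power envelope, optionally 1/f-corrected
#'
#' Welch spectrum of the (mean-removed) envelope; the 1/f correction fits
#' log-power against log-frequency over `fit_band` by least squares and
#' subtracts the fit in log space. The correction matters for locating the
#' infra-slow spectral peak; it cancels identically in magnitude-squared
#' coherence.
#'
#' @param env an `envelope_series` from [gamma_envelope()].
#' @param correct_1f apply the log-log linear detrending (default TRUE).
#' @param fit_band frequency range of the fit (Hz).
#' @param segment_s Welch segment length (s).
#' @return list with `freq`, `power` (corrected when requested), `raw`,
#'   and the fitted `slope`.
#' @export
envelope_spectrum <- function(env, correct_1f = TRUE,
                              fit_band = c(0.02, 0.5), segment_s = 50) {
  fs <- 1 / env$dt
  x <- env$power - mean(env$power)
  nseg <- min(length(x), round(segment_s * fs))
  w <- welch_spectra(x, NULL, fs = fs, nseg = nseg, overlap = 0.5)
  sel <- w$freq >= fit_band[1] & w$freq <= fit_band[2] & w$Pxx > 0
  slope <- NA_real_
  power <- w$Pxx
  if (correct_1f && sum(sel) >= 3) {
    fit <- stats::lm.fit(cbind(1, log10(w$freq[sel])),
                         log10(w$Pxx[sel]))
    slope <- fit$coefficients[2]
    pred <- fit$coefficients[1] + fit$coefficients[2] *
      log10(pmax(w$freq, w$freq[w$freq > 0][1]))
    power <- 10^(log10(pmax(w$Pxx, .Machine$double.xmin)) - pred)
  }
  list(freq = w$freq, power = power, raw = w$Pxx, slope = slope)
}

#' Ultra-slow coherence between two gamma envelopes
#'
#' Welch magnitude-squared coherence between the mean-removed envelopes,
#' averaged over the infra-slow band (default 0.02-0.5 Hz).
#'
#' @param e1,e2 aligned `envelope_series`.
#' @param band integration band (Hz).
#' @param segment_s Welch segment length (s).
#' @return list with the scalar `coherence`, plus the full `freq`/`msc`.
#' @export
ultraslow_envelope_coherence <- function(e1, e2, band = c(0.02, 0.5),
                                         segment_s = 50) {
  assert_that(length(e1$power) == length(e2$power) && e1$dt == e2$dt,
              "envelopes must be aligned")
  fs <- 1 / e1$dt
  nseg <- min(floor(length(e1$power) / 2), round(segment_s * fs))
  coh <- power_coherence(e1$power - mean(e1$power),
                         e2$power - mean(e2$power), fs = fs,
                         segment_s = nseg / fs, overlap = 0.5)
  sel <- coh$freq >= band[1] & coh$freq <= band[2]
  assert_that(any(sel), "band does not overlap the envelope spectrum")
  list(coherence = mean(coh$msc[sel]), freq = coh$freq, msc = coh$msc,
       n_segments = coh$n_segments)
}

#' Instantaneous band-limited phase
#'
#' Zero-phase 3rd-order Butterworth band-pass followed by the angle of the
#' analytic (Hilbert) signal. Convention: 0 rad at oscillation peaks, pi at
#' troughs.
#'
#' @param x numeric vector or [mc_signal()] (first channel, or `channel`).
#' @param band band name or `[low, high)` pair (Hz).
#' @param fs sampling rate (Hz) when `x` is a bare vector.
#' @param order Butterworth order, default 3.
#' @param channel channel index for multichannel input.
#' @return a [phase_series()]; `reliable = FALSE` (with a warning) when the
#'   band holds a negligible share of signal variance.
#' @export
instantaneous_phase <- function(x, band, fs = NULL, order = 3, channel = 1) {
  if (inherits(x, "mc_signal")) { fs <- x$fs; x <- x$samples[channel, ] }
  assert_that(!is.null(fs), "fs required")
  b <- band_lookup(band)
  assert_that(b[2] <= fs / 2, "band exceeds the signal bandwidth")
  vx <- stats::var(x)
  # a narrow band at an extreme normalized frequency makes the polynomial
  # Butterworth numerically degenerate (poles clustered at z = 1), so
  # decimate first to keep the upper band edge above ~fs/50, filter and
  # take the analytic phase at the reduced rate, then interpolate the
  # unwrapped phase back onto the input grid (exact for band-limited
  # phase evolution)
  q <- max(1L, floor(fs / (50 * b[2])))
  xd <- if (q > 1) decimate_by(x, q, fs) else x
  fsd <- fs / q
  d <- butter_design(order, b, fsd, "pass")
  pad <- min(length(xd) - 1, ceiling(3 * fsd / b[1]))
  xf <- iir_filtfilt(d$b, d$a, xd, pad = pad)
  reliable <- TRUE
  # judge band power on the interior: zero-phase IIR filtering leaves
  # edge transients (~1 filter time constant) even with matched padding
  trim <- min(pad, floor(length(xd) / 5))
  core <- xf[(trim + 1):(length(xf) - trim)]
  if (vx == 0 || stats::var(core) / vx < 1e-6) {
    warning("negligible band power: phase flagged unreliable")
    reliable <- FALSE
  }
  ph <- Arg(hilbert_analytic(xf))
  if (q > 1) {
    up <- unwrap_phase(ph)
    ph <- stats::approx((seq_along(up) - 1) / fsd, up,
                        xout = (seq_along(x) - 1) / fs, rule = 2)$y
  }
  phase_series(ph, fs, band = b, reliable = reliable)
}

#' Phase-locking value between two phase series
#'
#' `PLV = (1/N) |sum_j exp(i (theta1_j - theta2_j))|`: the resultant length
#' of the phase-difference distribution.
#'
#' @param p1,p2 [phase_series()] of equal length (bare numeric vectors also
#'   accepted).
#' @return a [plv_result()].
#' @export
lfp_plv <- function(p1, p2) {
  t1 <- if (inherits(p1, "phase_series")) p1$phase else p1
  t2 <- if (inherits(p2, "phase_series")) p2$phase else p2
  assert_that(length(t1) == length(t2), "phase series must have equal length")
  assert_that(length(t1) >= 2, "need at least two samples")
  cs <- circ_stats(t1 - t2)
  band <- if (inherits(p1, "phase_series")) p1$band else NULL
  plv_result(cs$r, n = cs$n, band = band)
}

#' Surrogate-based significance of an LFP-LFP PLV
#'
#' Surrogates time-shuffle one raw signal *before* filtering (default: a
#' circular time shift by a uniform offset of at least `min_shift_s`,
#' preserving the spectrum; `"permute"` shuffles samples). The pair is
#' significant iff the observed PLV exceeds the surrogate 95th percentile
#' AND exceeds 0.1 (conjunctive rule).
#'
#' @param x,y raw channel vectors (pre-filtering), or an [mc_signal()] with
#'   `channels`.
#' @param band band name or `[low, high)` pair.
#' @param fs sampling rate (Hz).
#' @param n_surrogates number of surrogates (>= 20; default 200).
#' @param rng_seed integer seed.
#' @param method `"shift"` (default) or `"permute"`.
#' @param min_shift_s minimum circular shift (s).
#' @param plv_floor absolute PLV floor of the conjunctive rule.
#' @param channels channel pair for multichannel input.
#' @return a [plv_result()] with the surrogate distribution and flag.
#' @export
plv_significance <- function(x, y = NULL, band, fs = NULL,
                             n_surrogates = 200, rng_seed = NULL,
                             method = c("shift", "permute"),
                             min_shift_s = 1, plv_floor = 0.1,
                             channels = c(1, 2)) {
  method <- match.arg(method)
  if (inherits(x, "mc_signal")) {
    fs <- x$fs
    y <- x$samples[channels[2], ]
    x <- x$samples[channels[1], ]
  }
  assert_that(n_surrogates >= 20, "need at least 20 surrogates")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "degenerate (constant) signal")
  p1 <- instantaneous_phase(x, band, fs = fs)
  p2 <- instantaneous_phase(y, band, fs = fs)
  obs <- lfp_plv(p1, p2)
  n <- length(y)
  sur <- with_seed(rng_seed, {
    vapply(seq_len(n_surrogates), function(s) {
      ys <- if (method == "shift") {
        k <- sample(ceiling(min_shift_s * fs):(n - ceiling(min_shift_s * fs)), 1)
        c(y[(k + 1):n], y[1:k])
      } else y[sample.int(n)]
      lfp_plv(p1, instantaneous_phase(ys, band, fs = fs))$plv
    }, numeric(1))
  })
  q95 <- stats::quantile(sur, 0.95, names = FALSE)
  plv_result(obs$plv, n = obs$n, band = obs$band, surrogate = sur,
             significant = (obs$plv > q95) && (obs$plv > plv_floor))
}

#' Preferred phase difference between two channels
#'
#' Circular mean of the pointwise phase differences; the resultant length
#' is reported as reliability and the mean flagged unreliable below 0.05.
#'
#' @param p1,p2 [phase_series()] (or numeric vectors) of equal length.
#' @return list with `mean` (radians), `resultant`, `n`, `reliable`.
#' @export
preferred_phase_difference <- function(p1, p2) {
  t1 <- if (inherits(p1, "phase_series")) p1$phase else p1
  t2 <- if (inherits(p2, "phase_series")) p2$phase else p2
  assert_that(length(t1) == length(t2), "phase series must have equal length")
  cs <- circ_stats(t1 - t2)
  reliable <- is.finite(cs$r) && cs$r >= 0.05
  if (!reliable) warning("resultant < 0.05: circular mean unreliable")
  list(mean = cs$mean, resultant = cs$r, n = cs$n, reliable = reliable)
}

#' Spike-field phase locking
#'
#' Samples the LFP phase at each spike time; spike PLV = 1 minus the
#' circular variance of that phase distribution (equivalently its
#' resultant length). Also returns the firing-probability histogram over
#' phase bins (normalized to sum 1).
#'
#' @param train a [spike_train()].
#' @param phase a [phase_series()] covering the spikes.
#' @param n_bins number of phase histogram bins (default 16).
#' @return a [plv_result()] with `histogram` (data.frame phase, prob) and
#'   the preferred phase in `preferred`; `plv` is NA with fewer than two
#'   spikes.
#' @export
spike_phase_locking <- function(train, phase, n_bins = 16) {
  stopifnot(inherits(train, "spike_train"), inherits(phase, "phase_series"))
  tmax <- (length(phase$phase) - 1) / phase$fs
  assert_that(!length(train$times) ||
                (min(train$times) >= 0 &&
                   max(train$times) <= tmax + 1 / phase$fs),
              "spikes outside the phase record")
  if (length(train$times) < 2) {
    return(plv_result(NA_real_, n = length(train$times)))
  }
  idx <- pmin(round(train$times * phase$fs) + 1L, length(phase$phase))
  th <- phase$phase[idx]
  cs <- circ_stats(th)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  counts <- graphics::hist(th, breaks = edges, plot = FALSE)$counts
  hist <- data.frame(phase = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                     prob = counts / sum(counts))
  out <- plv_result(cs$r, n = cs$n, band = phase$band, histogram = hist)
  out$preferred <- cs$mean
  out
}
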