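# Time-frequency decomposition, band power, the modulation index, and
# power spectra of kernel-smoothed spike trains.

#' Canonical frequency-band table
#'
#' slow \[0.1, 1), delta \[1, 4), theta \[4, 8), alpha \[8, 12),
#' beta \[12, 30), gamma \[30, 70) Hz.
#'
#' @return data.frame with columns name, low, high.
#' @export
band_defs <- function() {
  data.frame(name = c("slow", "delta", "theta", "alpha", "beta", "gamma"),
             low  = c(0.1, 1, 4, 8, 12, 30),
             high = c(1, 4, 8, 12, 30, 70),
             stringsAsFactors = FALSE)
}

band_lookup <- function(band) {
  if (is.character(band)) {
    tb <- band_defs()
    assert_that(band %in% tb$name, sprintf("unknown band '%s'", band))
    as.numeric(tb[tb$name == band, c("low", "high")])
  } else {
    stopifnot(length(band) == 2, band[2] > band[1])
    as.numeric(band)
  }
}

#' Kaiser-window spectrogram
#'
#' Sliding Kaiser windows (default 6 s, 50% overlap) with the spectrum
#' zero-padded onto a fixed frequency grid (default 0.15 Hz spacing).
#' Multichannel inputs are channel-averaged by default, as in the
#' channel-averaged spectrograms used for modulation indices.
#'
#' @param lfp an [lfp_signal()] / [mc_signal()], or a numeric vector with
#'   `fs` supplied.
#' @param window_s window length (s).
#' @param overlap overlap fraction.
#' @param df frequency-grid spacing (Hz), achieved by zero-padding.
#' @param fmax truncate the grid above this frequency (Hz); keeps the
#'   median filter and band summaries cheap.
#' @param beta Kaiser shape parameter (default the 60 dB design value).
#' @param fs sampling rate when `lfp` is a bare vector.
#' @param channel_average average power across channels (default TRUE);
#'   otherwise a list of per-channel spectrograms is returned.
#' @return a [spectrogram()] (or list of them).
#' @export
compute_spectrogram <- function(lfp, window_s = 6, overlap = 0.5, df = 0.15,
                                fmax = 100, beta = kaiser_beta(60), fs = NULL,
                                channel_average = TRUE) {
  if (is.numeric(lfp)) {
    assert_that(!is.null(fs), "fs required for a bare numeric input")
    lfp <- mc_signal(lfp, fs)
  }
  fs <- lfp$fs
  nwin <- round(window_s * fs)
  assert_that(ncol(lfp$samples) >= nwin,
              sprintf("record shorter than one %g s window", window_s))
  nfft <- max(nwin, round(fs / df))
  w <- kaiser_window(nwin, beta)
  scale <- 1 / (fs * sum(w^2))
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, ncol(lfp$samples) - nwin + 1L, by = step)
  nf <- floor(nfft / 2) + 1
  freq <- (0:(nf - 1)) * fs / nfft
  keep <- freq <= fmax
  per_channel <- lapply(seq_len(nrow(lfp$samples)), function(ch) {
    x <- lfp$samples[ch, ]
    S <- vapply(starts, function(s) {
      seg <- x[s:(s + nwin - 1L)]
      seg <- (seg - mean(seg)) * w
      P <- (Mod(stats::fft(c(seg, rep(0, nfft - nwin))))^2)[1:nf]
      mult <- rep(2, nf); mult[1] <- 1
      if (nfft %% 2 == 0) mult[nf] <- 1
      (P * mult * scale)[keep]
    }, numeric(sum(keep)))
    S
  })
  times <- (starts - 1 + nwin / 2) / fs
  wd <- sprintf("kaiser(beta=%.3f)", beta)
  if (channel_average || length(per_channel) == 1) {
    P <- Reduce(`+`, per_channel) / length(per_channel)
    spectrogram(P, freq[keep], times, window = wd)
  } else {
    lapply(per_channel, spectrogram, freq = freq[keep], time = times,
           window = wd)
  }
}

#' Median smoothing of a spectrogram
#'
#' 2-D running-median filter with a kernel of `time_res` seconds by
#' `freq_res` Hz (converted to odd bin counts); edges are handled by
#' reflection.
#'
#' @param spec a [spectrogram()].
#' @param time_res kernel extent in time (s), default 30.
#' @param freq_res kernel extent in frequency (Hz), default 1.
#' @return the smoothed [spectrogram()].
#' @export
median_smooth <- function(spec, time_res = 30, freq_res = 1) {
  stopifnot(inherits(spec, "spectrogram"))
  hop <- if (length(spec$time) > 1) diff(spec$time[1:2]) else Inf
  dfr <- if (length(spec$freq) > 1) diff(spec$freq[1:2]) else Inf
  kt <- odd_bins(time_res / hop)
  kf <- odd_bins(freq_res / dfr)
  assert_that(kt <= length(spec$time) && kf <= length(spec$freq),
              "median kernel larger than the spectrogram grid")
  spec$power <- median_filter_2d(spec$power, kf, kt)
  spec
}

odd_bins <- function(k) {
  k <- max(1L, round(k))
  if (k %% 2 == 0) k + 1L else as.integer(k)
}

# 2-D median filter via stacked shifted copies + matrixStats::rowMedians.
median_filter_2d <- function(M, kf, kt) {
  nr <- nrow(M); nc <- ncol(M)
  rf <- (kf - 1) %/% 2; rt <- (kt - 1) %/% 2
  ridx <- reflect_idx(nr, rf); cidx <- reflect_idx(nc, rt)
  P <- M[ridx, cidx, drop = FALSE]
  shifts <- expand.grid(i = 0:(kf - 1), j = 0:(kt - 1))
  stack <- vapply(seq_len(nrow(shifts)), function(s) {
    as.vector(P[shifts$i[s] + seq_len(nr), shifts$j[s] + seq_len(nc),
                drop = FALSE])
  }, numeric(nr * nc))
  matrix(matrixStats::rowMedians(stack), nr, nc)
}

reflect_idx <- function(n, r) {
  if (r == 0) return(seq_len(n))
  c(rev(seq_len(min(r, n - 1)) + 1), seq_len(n),
    n - seq_len(min(r, n - 1)))
}

#' Integrated band power per time bin
#'
#' Power integrated over `[low, high)` (trapezoid-free simple sum times the
#' grid spacing).
#'
#' @param spec a [spectrogram()].
#' @param band band name from [band_defs()] or a `[low, high)` pair (Hz).
#' @return numeric vector, one value per time bin.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectrogram"))
  b <- band_lookup(band)
  sel <- spec$freq >= b[1] & spec$freq < b[2]
  assert_that(any(sel), sprintf("band [%g, %g) does not overlap the grid",
                                b[1], b[2]))
  dfr <- if (length(spec$freq) > 1) diff(spec$freq[1:2]) else 1
  colSums(spec$power[sel, , drop = FALSE]) * dfr
}

#' Modulation index (post - base) / (post + base)
#'
#' Bounded in \[-1, 1\]; computed on linear power. Vectorized; the value is
#' missing wherever both operands are zero. The same contrast is reused for
#' coherence and PLV normalization.
#'
#' @param post_value,base_value non-negative statistic in the active and
#'   baseline epochs (same length, or either scalar).
#' @return numeric vector of modulation indices.
#' @export
modulation_index <- function(post_value, base_value) {
  assert_that(all(post_value >= 0, na.rm = TRUE) &&
                all(base_value >= 0, na.rm = TRUE),
              "modulation index operands must be non-negative")
  s <- post_value + base_value
  out <- (post_value - base_value) / s
  out[s == 0] <- NA_real_
  out
}

#' Power spectrum of a kernel-smoothed spike train
#'
#' The train is binarized at 1 ms, convolved with a Gaussian kernel
#' (width = SD, default 100 ms), and the multitaper PSD of the result is
#' returned (time-bandwidth 4, 7 tapers by default).
#'
#' @param train a [spike_train()].
#' @param epoch_length epoch duration (s).
#' @param kernel_width Gaussian kernel SD (s).
#' @param fs binarization rate (Hz), default 1000 (1 ms bins).
#' @param nw,k multitaper time-bandwidth product and taper count.
#' @return list with `freq`, `psd`, and `rate_series` (the smoothed train).
#' @export
spike_psd <- function(train, epoch_length, kernel_width = 0.1, fs = 1000,
                      nw = 4, k = 7) {
  stopifnot(inherits(train, "spike_train"))
  assert_that(epoch_length > 0, "epoch_length must be > 0")
  n <- round(epoch_length * fs)
  x <- numeric(n)
  if (!length(train$times)) {
    warning("empty spike train: flat zero spectrum")
    nf <- floor(next_fast_len(2L * n) / 2) + 1
    freq <- (0:(nf - 1)) * fs / next_fast_len(2L * n)
    return(list(freq = freq, psd = numeric(nf), rate_series = x))
  }
  idx <- pmin(pmax(round(train$times * fs) + 1L, 1L), n)
  for (i in idx) x[i] <- x[i] + 1     # duplicates within one bin accumulate
  if (kernel_width > 0) {
    half <- max(1L, ceiling(4 * kernel_width * fs))
    kt <- (-half):half
    g <- exp(-0.5 * (kt / (kernel_width * fs))^2)
    g <- g / sum(g)
    xp <- c(numeric(half), x, numeric(half))
    sm <- stats::convolve(xp, rev(g), type = "open")
    x <- sm[(2 * half + 1):(2 * half + n)]
  }
  mt <- multitaper_psd(x, fs, nw = nw, k = k)
  list(freq = mt$freq, psd = mt$psd, rate_series = x)
}

#' Relative spectral power in a band
#'
#' Band power as a fraction of the total power of the spectrum (DC bin
#' excluded on both sides).
#'
#' @param freq,psd spectrum as returned by [spike_psd()].
#' @param band `[low, high)` pair in Hz.
#' @return scalar fraction in \[0, 1\].
#' @export
relative_power <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq < band[2]
  tot <- sum(psd[freq > 0])
  if (tot == 0) return(NA_real_)
  sum(psd[sel & freq > 0]) / tot
}
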