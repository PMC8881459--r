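# Signal-processing primitives used throughout the package.
#
# These are deliberately self-contained: the filtering recipes (two-step LFP
# extraction, Kaiser-window band-passes, zero-phase Butterworth phase
# estimation, Welch coherence, DPSS multitaper) are the methods under study,
# and no DSP package ships with the supported environment. Designs are
# validated in the test suite against frozen scipy reference coefficients.

# ---- windows -----------------------------------------------------------

# Kaiser window beta for a given stopband attenuation (dB), standard
# empirical design equations.
kaiser_beta <- function(atten) {
  if (atten > 50) 0.1102 * (atten - 8.7)
  else if (atten >= 21) 0.5842 * (atten - 21)^0.4 + 0.07886 * (atten - 21)
  else 0
}

kaiser_window <- function(n, beta) {
  if (n == 1) return(1)
  m <- seq(0, n - 1)
  x <- beta * sqrt(pmax(0, 1 - ((2 * m - (n - 1)) / (n - 1))^2))
  besselI(x, 0, expon.scaled = TRUE) * exp(x - beta) /
    besselI(beta, 0, expon.scaled = TRUE)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# ---- FIR design (Kaiser windowed sinc) ---------------------------------

# Number of taps for a Kaiser design: N ~ (A - 7.95) / (2.285 * dw),
# dw the transition width in rad/sample. Returned length is odd so the
# filter has an exact linear-phase center.
kaiser_ntaps <- function(atten, transition_hz, fs) {
  dw <- 2 * pi * transition_hz / fs
  n <- ceiling((atten - 7.95) / (2.285 * dw)) + 1
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

#' Design a Kaiser-window FIR filter
#'
#' Windowed-sinc design with the ideal cutoffs placed mid-transition.
#' `f_lo <= 0` gives a low-pass, `f_hi >= fs/2` a high-pass.
#'
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi passband edges (Hz).
#' @param transition transition bandwidth (Hz).
#' @param atten stopband attenuation (dB); also sets the Kaiser beta.
#' @return numeric vector of filter taps (odd length, symmetric).
#' @keywords internal
fir_kaiser <- function(fs, f_lo, f_hi, transition, atten = 60) {
  stopifnot(fs > 0, transition > 0)
  n <- kaiser_ntaps(atten, transition, fs)
  m <- seq(0, n - 1) - (n - 1) / 2
  sinc <- function(fc) {       # 2*fc/fs * sinc(2*fc*m/fs), fc in Hz
    w <- 2 * pi * fc / fs
    h <- sin(w * m) / (pi * m)
    h[m == 0] <- w / pi
    h
  }
  lo <- f_lo - transition / 2
  hi <- f_hi + transition / 2
  hi <- min(hi, fs / 2)
  if (f_lo <= 0) h <- sinc(hi)                       # low-pass
  else if (f_hi >= fs / 2) {                         # high-pass
    h <- -sinc(lo); h[m == 0] <- 1 - 2 * lo / fs
  } else h <- sinc(hi) - sinc(lo)                    # band-pass
  h * kaiser_window(n, kaiser_beta(atten))
}

# ---- zero-phase FFT filtering ------------------------------------------

next_fast_len <- function(n) stats::nextn(n, c(2, 3, 5))

# Apply an FIR filter forward and backward (exact zero phase, magnitude
# response |H|^2) via the frequency domain. Edges are odd-reflected by the
# filter length to suppress transients; circular wrap-around lands inside
# the discarded pads.
fir_filtfilt <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  assert_that(n > nh, "record shorter than the filter warm-up")
  p <- nh
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  L <- next_fast_len(length(xp) + 2 * nh)
  H <- stats::fft(c(h, rep(0, L - nh)))
  # |H|^2 is real: convolution with conv(h, rev(h)), support centered at
  # lag 0, hence exactly zero phase and zero delay; circular wrap-around
  # only touches the first/last nh-1 samples, which lie inside the pads.
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, L - length(xp)))) * (Mod(H)^2),
                     inverse = TRUE)) / L
  y[(p + 1):(p + n)]
}

# Soft-edged frequency-domain band-pass (zero phase). Used where the
# series is short relative to any realizable FIR (e.g. BOLD at TR 1 s).
# Transition edges are raised-cosine of width `transition` Hz.
fft_bandpass <- function(x, fs, f_lo, f_hi, transition = NULL) {
  n <- length(x)
  transition <- transition %||% max((f_hi - f_lo) * 0.1, fs / n)
  p <- min(n - 1, ceiling(fs / max(f_lo, fs / n)))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  L <- next_fast_len(length(xp))
  f <- (seq_len(L) - 1) * fs / L
  f <- pmin(f, fs - f)                         # two-sided frequency axis
  ramp <- function(fr, edge, up) {             # raised-cosine edge
    t <- (fr - (edge - transition / 2)) / transition
    t <- pmin(pmax(t, 0), 1)
    g <- 0.5 - 0.5 * cos(pi * t)
    if (up) g else 1 - g
  }
  G <- rep(1, L)
  if (f_lo > 0) G <- G * ramp(f, f_lo, up = TRUE)
  if (f_hi < fs / 2) G <- G * ramp(f, f_hi, up = FALSE)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, L - length(xp)))) * G,
                     inverse = TRUE)) / L
  y[(p + 1):(p + n)]
}

# ---- IIR (Butterworth) design ------------------------------------------

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  p
}

#' Butterworth digital filter design
#'
#' Analog prototype + bilinear transform with frequency prewarping,
#' matching the conventional (scipy/MATLAB) `butter` coefficients.
#'
#' @param n filter order.
#' @param fc cutoff (Hz): scalar for low/high-pass, length-2 for band-pass.
#' @param fs sampling rate (Hz).
#' @param type "low", "high" or "pass".
#' @return list with numerator `b` and denominator `a` coefficients.
#' @keywords internal
butter_design <- function(n, fc, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot(n >= 1, all(fc > 0), all(fc < fs / 2))
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # prototype poles, gain 1
  z <- complex(0)
  g <- 1
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "low") {
    w0 <- warp(fc); p <- p * w0; g <- g * w0^n
  } else if (type == "high") {
    w0 <- warp(fc)
    g <- 1                    # k / prod(-p) = 1: Butterworth constant term is 1
    p <- w0 / p
    z <- rep(0 + 0i, n)
  } else {
    w1 <- warp(fc[1]); w2 <- warp(fc[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    g <- g * bw^n
    ph <- p * bw / 2
    p <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
    z <- rep(0 + 0i, n)
  }
  fs2 <- 2 * fs
  gd <- g * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c((fs2 + z) / (fs2 - z), rep(-1 + 0i, length(p) - length(z)))
  pd <- (fs2 + p) / (fs2 - p)
  b <- Re(poly_from_roots(zd)) * gd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Direct-form IIR filtering using stats::filter (C speed): MA part by
# one-sided convolution, AR part by the recursive filter.
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  v
}

# Zero-phase IIR filtering (forward-backward) with symmetric (even)
# reflection padding. Even reflection keeps the pads free of the DC
# offset that odd reflection introduces (2*x[1] - x), which would drive
# a large low-frequency transient through narrow band-pass filters; the
# price is a slope discontinuity at the junction, whose transient is
# orders of magnitude smaller for the slow bands this package filters.
iir_filtfilt <- function(b, a, x, pad = NULL) {
  n <- length(x)
  pad <- pad %||% min(n - 1, 50 * (max(length(a), length(b)) - 1))
  assert_that(n > pad && n > 3 * (max(length(a), length(b)) - 1),
              "record shorter than the filter warm-up")
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# ---- resampling --------------------------------------------------------

#' Integer-factor decimation with zero-phase anti-alias filtering
#'
#' The anti-alias low-pass cuts at 0.8x the target Nyquist (Kaiser FIR,
#' 60 dB) and is applied forward-backward, then the signal is subsampled.
#'
#' @param x numeric vector.
#' @param q integer decimation factor.
#' @param fs input sampling rate (Hz).
#' @param antialias skip the filter when the caller knows the band is clear.
#' @keywords internal
decimate_by <- function(x, q, fs, antialias = TRUE) {
  stopifnot(q >= 1, q == round(q))
  if (q == 1) return(x)
  if (antialias) {
    nyq_t <- fs / (2 * q)
    x <- fir_filtfilt(x, fir_kaiser(fs, 0, 0.8 * nyq_t,
                                    transition = 0.3 * nyq_t, atten = 60))
  }
  x[seq(1, length(x), by = q)]
}

# Linear-interpolation resampling to an arbitrary rate (used to upsample
# synthetic LFPs onto the raw extracellular grid).
resample_linear <- function(x, fs_from, fs_to, n_out = NULL) {
  t_in <- (seq_along(x) - 1) / fs_from
  n_out <- n_out %||% (floor(t_in[length(t_in)] * fs_to) + 1)
  stats::approx(t_in, x, xout = (seq_len(n_out) - 1) / fs_to,
                rule = 2)$y
}

# ---- Hilbert / analytic signal -----------------------------------------

#' Analytic signal via the FFT Hilbert transform
#' @param x real-valued numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  m <- numeric(n)
  if (n %% 2 == 0) {
    m[1] <- 1; m[n / 2 + 1] <- 1; m[2:(n / 2)] <- 2
  } else {
    m[1] <- 1; m[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * m, inverse = TRUE) / n
}

# ---- Welch spectra and coherence ---------------------------------------

# Segment a vector into K windows of length nseg with the given overlap
# fraction; returns a matrix nseg x K.
segment_matrix <- function(x, nseg, overlap) {
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  vapply(starts, function(s) x[s:(s + nseg - 1L)], numeric(nseg))
}

#' Welch auto-/cross-spectra
#'
#' Hann-windowed, mean-removed overlapping segments; one-sided density
#' scaling (power/Hz).
#'
#' @param x,y equal-length numeric vectors (`y = NULL` for auto-spectrum).
#' @param fs sampling rate (Hz).
#' @param nseg segment length in samples.
#' @param overlap overlap fraction in \[0, 1).
#' @return list with `freq`, `Pxx`, and when `y` is given `Pyy`, `Pxy`
#'   (complex), plus `n_segments`.
#' @keywords internal
welch_spectra <- function(x, y = NULL, fs, nseg, overlap = 0.5) {
  assert_that(is.null(y) || length(x) == length(y),
              "signals must have equal length")
  nseg <- min(nseg, length(x))
  w <- hann_window(nseg)
  scale <- 1 / (fs * sum(w^2))
  fft_segs <- function(v) {
    S <- segment_matrix(v, nseg, overlap)
    S <- sweep(S, 2, colMeans(S))
    stats::mvfft(S * w)
  }
  X <- fft_segs(x)
  nf <- floor(nseg / 2) + 1
  one_sided <- function(P) {
    P <- P[1:nf, , drop = FALSE]
    mult <- rep(2, nf); mult[1] <- 1
    if (nseg %% 2 == 0) mult[nf] <- 1
    P * mult * scale
  }
  out <- list(freq = (0:(nf - 1)) * fs / nseg,
              Pxx = rowMeans(one_sided(Mod(X)^2)),
              n_segments = ncol(X))
  if (!is.null(y)) {
    Y <- fft_segs(y)
    out$Pyy <- rowMeans(one_sided(Mod(Y)^2))
    Pxy <- one_sided(Conj(X) * Y)
    out$Pxy <- rowMeans(Re(Pxy)) + 1i * rowMeans(Im(Pxy))
  }
  out
}

# ---- DPSS tapers and multitaper PSD ------------------------------------

.dpss_cache <- new.env(parent = emptyenv())

# Discrete prolate spheroidal sequences from the symmetric tridiagonal
# formulation (Percival & Walden). For long series the tapers are computed
# at base length 1024 and spline-interpolated, the standard large-n trick.
dpss_tapers <- function(n, nw = 4, k = 7) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  base_n <- 1024L
  nc <- if (n > 1200L) base_n else as.integer(n)
  W <- nw / nc
  i <- 0:(nc - 1)
  d <- ((nc - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (1:(nc - 1)) * (nc - (1:(nc - 1))) / 2
  A <- matrix(0, nc, nc)
  A[cbind(1:nc, 1:nc)] <- d
  A[cbind(1:(nc - 1), 2:nc)] <- e
  A[cbind(2:nc, 1:(nc - 1))] <- e
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  if (n > 1200L) {
    V <- apply(V, 2, function(v)
      stats::spline(seq(0, 1, length.out = nc), v,
                    xout = seq(0, 1, length.out = n))$y)
  }
  V <- apply(V, 2, function(v) v / sqrt(sum(v^2)))
  .dpss_cache[[key]] <- V
  V
}

#' Multitaper power spectral density
#'
#' DPSS (Slepian) tapers, eigenvalue-unweighted average, one-sided density
#' scaling. The series mean is removed first.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nw time-bandwidth product (default 4).
#' @param k number of tapers (default 7 = 2*nw - 1).
#' @param nfft FFT length (zero-padded; default next fast length >= 2n).
#' @return list with `freq` and `psd`.
#' @export
multitaper_psd <- function(x, fs, nw = 4, k = 7, nfft = NULL) {
  n <- length(x)
  assert_that(n >= 8, "series too short for a multitaper estimate")
  x <- x - mean(x)
  nfft <- nfft %||% next_fast_len(2L * n)
  V <- dpss_tapers(n, nw, k)
  P <- Mod(stats::mvfft(rbind(x * V,
                              matrix(0, nfft - n, k))))^2
  nf <- floor(nfft / 2) + 1
  psd <- rowMeans(P[1:nf, , drop = FALSE]) / fs
  mult <- rep(2, nf); mult[1] <- 1
  if (nfft %% 2 == 0) mult[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / nfft, psd = psd * mult)
}
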