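# Shared helpers and independent oracles used across the suite.

# Adjusted Rand index between two labelings (closed form on the
# contingency table); 1 = identical partitions up to relabeling.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Direct (brute-force) evaluation of the printed PLV formula.
plv_direct <- function(th1, th2) {
  n <- length(th1)
  Mod(sum(exp(1i * (th1 - th2)))) / n
}

# Direct Welch magnitude-squared coherence, re-implemented independently
# of the package internals (plain loops over segments).
msc_direct <- function(x, y, fs, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  step <- round(nseg * (1 - overlap))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  Sxx <- Syy <- numeric(nseg)
  Sxy <- complex(real = numeric(nseg))
  for (s in starts) {
    xs <- x[s:(s + nseg - 1)]; ys <- y[s:(s + nseg - 1)]
    X <- fft((xs - mean(xs)) * w); Y <- fft((ys - mean(ys)) * w)
    Sxx <- Sxx + Mod(X)^2; Syy <- Syy + Mod(Y)^2; Sxy <- Sxy + Conj(X) * Y
  }
  nf <- floor(nseg / 2) + 1
  list(freq = (0:(nf - 1)) * fs / nseg,
       msc = (Mod(Sxy)^2 / (Sxx * Syy))[1:nf],
       K = length(starts))
}

# Sinusoid helper.
tone <- function(f, fs, dur, amp = 1, phase = 0)
  amp * cos(2 * pi * f * (0:(round(fs * dur) - 1)) / fs + phase)

# Relative amplitude (power ratio in dB) of output vs input sinusoid,
# measured away from the edges.
atten_db <- function(x_in, x_out, frac = 0.25) {
  n <- length(x_in)
  i <- seq(floor(n * frac), ceiling(n * (1 - frac)))
  10 * log10(mean(x_out[i]^2) / mean(x_in[i]^2))
}
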