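# Synthetic-data generators: coupled LFPs, von Mises phase-locked spike
# trains, raw extracellular mixtures, BOLD datasets, and the two-scenario
# spike-locking simulation. All draws flow from per-call seeds; the
# caller's RNG stream is never disturbed.

# ---- LFP specification --------------------------------------------------

#' Specification for coupled sinusoidal LFPs
#'
#' Each component is a sinusoid shared across channels up to per-channel
#' phase offsets (and, optionally, per-channel amplitudes), plus independent
#' Gaussian noise per channel.
#'
#' @param components list of components, each a list with `frequency` (Hz),
#'   `amplitude` (scalar, or one value per channel), and `phase` (radians;
#'   scalar or one value per channel; default 0).
#' @param noise_sd independent Gaussian noise SD per channel.
#' @param duration record duration (s).
#' @param sampling_rate sampling rate (Hz).
#' @param n_channels number of channels.
#' @param rng_seed integer seed.
#' @return object of class `lfp_spec`.
#' @export
lfp_spec <- function(components, noise_sd = 0, duration, sampling_rate = 1000,
                     n_channels = 2, rng_seed = NULL) {
  assert_that(duration > 0, "duration must be > 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(n_channels >= 1, "need at least one channel")
  components <- lapply(components, function(cm) {
    assert_that(is.list(cm) && !is.null(cm$frequency) && !is.null(cm$amplitude),
                "each component needs frequency and amplitude")
    assert_that(cm$frequency > 0 && cm$frequency < sampling_rate / 2,
                sprintf("component frequency %g Hz outside (0, Nyquist)",
                        cm$frequency))
    cm$phase <- rep_len(cm$phase %||% 0, n_channels)
    cm$amplitude <- rep_len(cm$amplitude, n_channels)
    cm
  })
  structure(list(components = components, noise_sd = noise_sd,
                 duration = duration, sampling_rate = sampling_rate,
                 n_channels = n_channels, rng_seed = rng_seed),
            class = "lfp_spec")
}

#' Generate coupled multichannel LFPs from a spec
#'
#' Channel k is `sum_j A_jk * cos(2 pi f_j t + phi_jk)` plus independent
#' Gaussian noise. Byte-identical for identical specs and seeds.
#'
#' @param spec an [lfp_spec()].
#' @return an [mc_signal()] at `spec$sampling_rate`.
#' @export
gen_coupled_lfp <- function(spec) {
  stopifnot(inherits(spec, "lfp_spec"))
  n <- round(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  S <- matrix(0, spec$n_channels, n)
  for (cm in spec$components)
    for (ch in seq_len(spec$n_channels))
      S[ch, ] <- S[ch, ] +
        cm$amplitude[ch] * cos(2 * pi * cm$frequency * t + cm$phase[ch])
  if (spec$noise_sd > 0)
    S <- S + with_seed(spec$rng_seed,
                       matrix(stats::rnorm(length(S), sd = spec$noise_sd),
                              nrow(S), ncol(S)))
  mc_signal(S, spec$sampling_rate)
}

#' Generate band-limited stochastic coupled LFPs
#'
#' Sibling of [gen_coupled_lfp()] for components that must span a band
#' rather than sit on a line: each component is Gaussian noise band-passed
#' to `[f_lo, f_hi]`, shared across channels with a per-channel constant
#' phase rotation (applied on the analytic signal, so every frequency in
#' the band is shifted by the same angle), scaled by a per-channel
#' amplitude. Needed to give Welch coherence something other than 0/1 to
#' estimate; a pure shared tone has coherence 1 at any amplitude.
#'
#' @param components list of lists with `band` (length 2, Hz), `amplitude`
#'   (scalar or per channel), `phase` (radians; scalar or per channel),
#'   and optional `ind_amplitude` (SD of additional *independent*
#'   per-channel noise restricted to the same band; keeps the in-band
#'   coherence away from 1 so amplitude changes are visible in msc).
#' @param noise_sd independent white noise SD per channel.
#' @param duration,sampling_rate,n_channels,rng_seed as in [lfp_spec()].
#' @return an [mc_signal()].
#' @export
gen_band_coupled_lfp <- function(components, noise_sd = 0, duration,
                                 sampling_rate = 1000, n_channels = 2,
                                 rng_seed = NULL) {
  n <- round(duration * sampling_rate)
  with_seed(rng_seed, {
    S <- matrix(0, n_channels, n)
    for (cm in components) {
      stopifnot(length(cm$band) == 2, cm$band[1] > 0,
                cm$band[2] < sampling_rate / 2)
      amp <- rep_len(cm$amplitude, n_channels)
      ph <- rep_len(cm$phase %||% 0, n_channels)
      iamp <- rep_len(cm$ind_amplitude %||% 0, n_channels)
      base <- fft_bandpass(stats::rnorm(n), sampling_rate,
                           cm$band[1], cm$band[2])
      base <- base / stats::sd(base)          # unit-SD band signal
      an <- hilbert_analytic(base)
      for (ch in seq_len(n_channels)) {
        S[ch, ] <- S[ch, ] + amp[ch] * Re(an * exp(-1i * ph[ch]))
        if (iamp[ch] > 0) {
          u <- fft_bandpass(stats::rnorm(n), sampling_rate,
                            cm$band[1], cm$band[2])
          S[ch, ] <- S[ch, ] + iamp[ch] * u / stats::sd(u)
        }
      }
    }
    if (noise_sd > 0)
      S <- S + matrix(stats::rnorm(length(S), sd = noise_sd),
                      nrow(S), ncol(S))
    mc_signal(S, sampling_rate)
  })
}

# ---- von Mises spikes ---------------------------------------------------

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` degenerates to the uniform
#' circular distribution.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  assert_that(kappa >= 0, "kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_pi(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.3) + 10
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3[keep] - 0.5) * acos(f[keep])
    out <- c(out, theta)
  }
  wrap_pi(mu + out[seq_len(n)])
}

#' Generate spikes phase-locked to a carrier oscillation
#'
#' Draws `n_spikes` phases from von Mises(`preferred_phase`, `kappa`) and
#' places each spike at a time where the carrier attains that phase, the
#' cycle being chosen uniformly at random over the epoch (pooled-over-epoch
#' convention). No refractory pruning is applied here.
#'
#' @param phase a [phase_series()] covering the epoch.
#' @param n_spikes number of spikes (>= 0).
#' @param kappa von Mises concentration (>= 0).
#' @param preferred_phase mean phase (radians).
#' @param rng_seed integer seed.
#' @return a [spike_train()] (sorted, duplicates possible).
#' @export
gen_vonmises_spikes <- function(phase, n_spikes, kappa, preferred_phase = pi,
                                rng_seed = NULL) {
  stopifnot(inherits(phase, "phase_series"))
  assert_that(kappa >= 0, "kappa must be >= 0")
  assert_that(n_spikes >= 0, "n_spikes must be >= 0")
  if (n_spikes == 0) return(spike_train(numeric(0)))
  tgrid <- (seq_along(phase$phase) - 1) / phase$fs
  with_seed(rng_seed, {
    theta <- rvonmises(n_spikes, preferred_phase, kappa)
    phi <- unwrap_phase(phase$phase)
    if (all(diff(phi) > 0)) {
      # monotone carrier: invert the unwrapped phase per randomly chosen cycle
      u <- (theta - phi[1]) %% (2 * pi)
      first <- phi[1] + u
      n_cyc <- pmax(1, floor((phi[length(phi)] - first) / (2 * pi)) + 1)
      targ <- first + 2 * pi * floor(stats::runif(n_spikes) * n_cyc)
      times <- stats::approx(phi, tgrid, xout = targ, rule = 2)$y
    } else {
      # non-monotone phase (stochastic carrier): bin the phase axis once,
      # then sample a time point uniformly among those whose wrapped
      # phase falls in the drawn phase's bin (or the nearest occupied bin)
      nb <- 512L
      bin_of <- function(p) pmin(nb, 1L + floor((p + pi) / (2 * pi) * nb))
      occupied <- split(seq_along(phase$phase), bin_of(phase$phase))
      occ_keys <- as.integer(names(occupied))
      times <- vapply(bin_of(theta), function(b) {
        if (is.null(occupied[[as.character(b)]])) {
          b <- occ_keys[which.min(pmin(abs(occ_keys - b),
                                       nb - abs(occ_keys - b)))]
        }
        cand <- occupied[[as.character(b)]]
        tgrid[cand[sample.int(length(cand), 1)]]
      }, numeric(1))
    }
    spike_train(times)
  })
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Default biphasic spike waveform template
#'
#' A Gaussian-enveloped single-cycle sine (~1.3 kHz carrier) of ~1 ms: a
#' biphasic shape whose spectrum sits well inside the 400-3000 Hz
#' detection band, so the zero-phase detection filter passes it with
#' negligible ringing (a hard-edged template rings at the 400 Hz band
#' edge and produces spurious threshold crossings beyond the refractory
#' window).
#'
#' @param fs sampling rate (Hz).
#' @param amplitude peak amplitude (signal units).
#' @param duration_s template duration (s).
#' @return numeric vector of template samples.
#' @export
biphasic_waveform <- function(fs, amplitude = 1, duration_s = 0.001) {
  n <- max(8L, round(fs * duration_s))
  if (n %% 2 == 0) n <- n + 1L               # odd: well-defined center
  t <- seq(-0.5, 0.5, length.out = n)
  w <- sin(2 * pi * 1.5 * t * duration_s * 1000) * exp(-0.5 * (t / 0.14)^2)
  amplitude * w / max(abs(w))
}

#' Mix LFP, spikes and noise into a raw extracellular recording
#'
#' @param lfp an [mc_signal()] (any rate; linearly resampled onto the raw
#'   grid).
#' @param spikes a [spike_train()] or a list of them, one per channel
#'   (position in the list = channel index).
#' @param waveform spike template (default [biphasic_waveform()] at 8x a
#'   unit noise threshold).
#' @param noise_sd Gaussian noise SD added at the raw rate.
#' @param sampling_rate raw sampling rate (Hz), nominal 20000.
#' @param rng_seed integer seed for the noise.
#' @param events optional named event times passed through.
#' @param regions optional per-channel region labels passed through.
#' @return a [raw_recording()].
#' @export
gen_extracellular <- function(lfp, spikes = NULL, waveform = NULL,
                              noise_sd = 0, sampling_rate = 20000,
                              rng_seed = NULL, events = NULL,
                              regions = NULL) {
  stopifnot(inherits(lfp, "mc_signal"))
  n_ch <- nrow(lfp$samples)
  n_out <- round(signal_duration(lfp) * sampling_rate)
  R <- matrix(0, n_ch, n_out)
  for (ch in seq_len(n_ch))
    R[ch, ] <- resample_linear(lfp$samples[ch, ], lfp$fs, sampling_rate,
                               n_out = n_out)
  if (!is.null(spikes)) {
    if (inherits(spikes, "spike_train")) spikes <- list(spikes)
    waveform <- waveform %||% biphasic_waveform(sampling_rate)
    nw <- length(waveform)
    half <- (nw - 1L) %/% 2L                 # template centered on the spike
    for (ch in seq_along(spikes)) {
      st <- spikes[[ch]]
      if (is.null(st) || !length(st$times)) next
      idx <- round(st$times * sampling_rate) + 1L - half
      assert_that(all(idx >= 1 & idx + nw - 1L <= n_out),
                  "spike time outside the record")
      for (i in idx) R[ch, i:(i + nw - 1L)] <- R[ch, i:(i + nw - 1L)] + waveform
    }
  }
  if (noise_sd > 0)
    R <- R + with_seed(rng_seed,
                       matrix(stats::rnorm(length(R), sd = noise_sd),
                              nrow(R), ncol(R)))
  raw_recording(R, fs = sampling_rate, regions = regions, events = events)
}

# ---- spike-locking simulation spec --------------------------------------

#' Specification of the spike-locking simulation
#'
#' Defaults restate the simulated experiment: 10 s epochs of spikes locked
#' to a 1 Hz cosine carrier; a "locked" scenario of 100 spikes tightly
#' concentrated (kappa = 20) around the preferred phase pi, and a "mixed"
#' scenario adding 100 near-uniform spikes (kappa = 0.5); spike trains are
#' smoothed with a 100 ms Gaussian kernel before spectral analysis.
#'
#' @param epoch_length epoch duration (s).
#' @param carrier_frequency carrier frequency (Hz).
#' @param n_locked_spikes,kappa_locked locked-population size and
#'   concentration.
#' @param n_diffuse_spikes,kappa_diffuse diffuse-population size and
#'   concentration.
#' @param preferred_phase preferred phase (radians); pi = carrier trough.
#' @param diffuse_phase mean phase of the diffuse ("asynchronous,
#'   off-preferred-phase") population; default the antiphase of
#'   `preferred_phase`.
#' @param kernel_width Gaussian kernel width (s), interpreted as its SD.
#' @param rng_seed integer seed.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(epoch_length = 10, carrier_frequency = 1,
                     n_locked_spikes = 100, kappa_locked = 20,
                     n_diffuse_spikes = 100, kappa_diffuse = 0.5,
                     preferred_phase = pi, diffuse_phase = NULL,
                     kernel_width = 0.1, rng_seed = NULL) {
  assert_that(epoch_length > 0, "epoch_length must be > 0")
  assert_that(kappa_locked >= 0 && kappa_diffuse >= 0, "kappa must be >= 0")
  assert_that(n_locked_spikes >= 0 && n_diffuse_spikes >= 0,
              "spike counts must be >= 0")
  structure(list(epoch_length = epoch_length,
                 carrier_frequency = carrier_frequency,
                 n_locked_spikes = n_locked_spikes,
                 kappa_locked = kappa_locked,
                 n_diffuse_spikes = n_diffuse_spikes,
                 kappa_diffuse = kappa_diffuse,
                 preferred_phase = preferred_phase,
                 diffuse_phase = diffuse_phase %||% wrap_pi(preferred_phase + pi),
                 kernel_width = kernel_width, rng_seed = rng_seed),
            class = "sim_spec")
}

#' Build the two spike-locking scenarios
#'
#' The locked-only train stands for the chemogenetic-inhibition condition
#' (only spikes at the excitable phase survive); the mixed train for the
#' sham condition (locked plus near-uniform spikes).
#'
#' @param spec a [sim_spec()].
#' @param fs carrier sampling rate (Hz).
#' @return list with `locked_train`, `mixed_train`, `carrier`
#'   (an [mc_signal()]) and `carrier_phase` (a [phase_series()]).
#' @export
make_sim_scenarios <- function(spec, fs = 1000) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- round(spec$epoch_length * fs)
  t <- (seq_len(n) - 1) / fs
  carrier <- mc_signal(cos(2 * pi * spec$carrier_frequency * t), fs)
  ph <- phase_series(wrap_pi(2 * pi * spec$carrier_frequency * t), fs)
  locked <- gen_vonmises_spikes(ph, spec$n_locked_spikes, spec$kappa_locked,
                                spec$preferred_phase,
                                rng_seed = derive_seed(spec$rng_seed, 1))
  diffuse <- gen_vonmises_spikes(ph, spec$n_diffuse_spikes,
                                 spec$kappa_diffuse, spec$diffuse_phase,
                                 rng_seed = derive_seed(spec$rng_seed, 2))
  mixed <- spike_train(c(locked$times, diffuse$times))
  list(locked_train = locked, mixed_train = mixed, carrier = carrier,
       carrier_phase = ph)
}

# ---- BOLD generator -----------------------------------------------------

#' Specification for a synthetic BOLD dataset
#'
#' Regional time courses are latent low-frequency (< 0.1 Hz) Gaussian
#' signals with correlation structure given by `coupling` (a valid
#' correlation matrix over the named regions); every voxel of a region
#' carries its regional signal plus drift and white noise. The ventricle
#' mask carries an independent nuisance signal, and six smooth motion
#' regressors are emitted alongside (with a small leakage into the data so
#' nuisance regression has something to remove).
#'
#' @param dims grid dimensions (length 3).
#' @param masks named list of masks (see [make_box_mask()]); a mask named
#'   `"ventricle"` is treated as the nuisance compartment.
#' @param coupling correlation matrix across the non-ventricle regions
#'   (dimnames must match mask names); entries in \[0, 1\].
#' @param TR repetition time (s).
#' @param n_volumes number of volumes.
#' @param noise_sd voxel white-noise SD (scalar), optionally overridden per
#'   region via `region_noise`.
#' @param region_noise named list of per-region noise SD overrides.
#' @param drift_sd SD of the per-voxel linear drift over the record.
#' @param motion_sd amplitude of motion leakage into voxel time courses.
#' @param hrf convolve latent signals with a canonical double-gamma
#'   hemodynamic kernel (identical for all regions, so correlations are
#'   preserved).
#' @param rng_seed integer seed.
#' @return object of class `bold_spec`.
#' @export
bold_spec <- function(dims, masks, coupling, TR = 1, n_volumes = 420,
                      noise_sd = 0.5, region_noise = list(), drift_sd = 0.3,
                      motion_sd = 0.1, hrf = TRUE, rng_seed = NULL) {
  stopifnot(length(dims) == 3, n_volumes > 1)
  masks <- lapply(masks, normalize_mask, dims = dims)
  regions <- setdiff(names(masks), "ventricle")
  coupling <- as.matrix(coupling)
  assert_that(!is.null(dimnames(coupling)) &&
                setequal(rownames(coupling), regions),
              "coupling dimnames must match the non-ventricle mask names")
  coupling <- coupling[regions, regions, drop = FALSE]
  assert_that(all(coupling >= 0 & coupling <= 1),
              "coupling weights must lie in [0, 1]")
  ev <- eigen(coupling, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8,
              "coupling matrix must be positive semi-definite")
  structure(list(dims = dims, masks = masks, coupling = coupling, TR = TR,
                 n_volumes = n_volumes, noise_sd = noise_sd,
                 region_noise = region_noise, drift_sd = drift_sd,
                 motion_sd = motion_sd, hrf = hrf, rng_seed = rng_seed),
            class = "bold_spec")
}

# Canonical double-gamma HRF sampled at TR.
hrf_kernel <- function(TR, length_s = 32) {
  t <- seq(0, length_s, by = TR)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

# Low-frequency (0.005-0.08 Hz) unit-SD latent signal.
lowfreq_signal <- function(n, fs) {
  x <- fft_bandpass(stats::rnorm(max(n, 64)), fs, 0.005, 0.08)
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

#' Generate a synthetic BOLD dataset
#'
#' @param spec a [bold_spec()].
#' @return a [bold_series()] with masks and motion regressors attached, and
#'   the ground-truth latent signals in attribute `"latent"`.
#' @export
gen_bold_dataset <- function(spec) {
  stopifnot(inherits(spec, "bold_spec"))
  d <- spec$dims; nt <- spec$n_volumes; fs <- 1 / spec$TR
  regions <- rownames(spec$coupling)
  with_seed(spec$rng_seed, {
    F0 <- vapply(seq_along(regions), function(i) lowfreq_signal(nt, fs),
                 numeric(nt))
    L <- chol(spec$coupling + diag(1e-10, length(regions)))
    latent <- F0 %*% L                       # nt x regions, corr = coupling
    colnames(latent) <- regions
    if (spec$hrf) {
      k <- hrf_kernel(spec$TR)
      latent <- apply(latent, 2, function(v)
        stats::convolve(v, rev(k), type = "open")[seq_len(nt)])
      latent <- scale(latent)
    }
    vent <- lowfreq_signal(nt, fs)           # independent nuisance signal
    motion <- vapply(1:6, function(i) lowfreq_signal(nt, fs), numeric(nt))
    nvox <- prod(d)
    Y <- matrix(stats::rnorm(nvox * nt, sd = spec$noise_sd), nt, nvox)
    drift <- stats::rnorm(nvox, sd = spec$drift_sd)
    Y <- Y + outer(seq_len(nt) / nt - 0.5, drift)
    Y <- Y + motion %*% matrix(stats::rnorm(6 * nvox, sd = spec$motion_sd),
                               6, nvox)
    for (rg in regions) {
      fl <- mask_flat(spec$masks[[rg]], d)
      ns <- spec$region_noise[[rg]]
      if (!is.null(ns))                      # re-draw region noise at its SD
        Y[, fl] <- matrix(stats::rnorm(length(fl) * nt, sd = ns), nt,
                          length(fl)) +
          outer(seq_len(nt) / nt - 0.5, drift[fl]) +
          motion %*% matrix(stats::rnorm(6 * length(fl),
                                         sd = spec$motion_sd),
                            6, length(fl))
      Y[, fl] <- Y[, fl] + latent[, rg]
    }
    if (!is.null(spec$masks$ventricle)) {
      fl <- mask_flat(spec$masks$ventricle, d)
      Y[, fl] <- Y[, fl] + 2 * vent
    }
    arr <- array(t(Y), dim = c(d, nt))
    out <- bold_series(arr, TR = spec$TR, masks = spec$masks,
                       motion = motion)
    attr(out, "latent") <- latent
    out
  })
}
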