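# S3 containers for the analysis objects. All signal containers store
# samples as a channels x time matrix plus a sampling rate in Hz.

#' Multichannel signal container
#'
#' @param samples numeric matrix, channels x time (a vector is promoted to
#'   one channel).
#' @param fs sampling rate (Hz).
#' @param regions optional character vector of per-channel region labels
#'   (e.g. "PFC", "Rs", "Th").
#' @param events optional named numeric vector of event times (s), e.g.
#'   `c(injection = 900)`.
#' @return an object of class `mc_signal`.
#' @export
mc_signal <- function(samples, fs, regions = NULL, events = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), fs > 0)
  assert_that(all(is.finite(samples)), "samples must be finite")
  if (!is.null(regions))
    assert_that(length(regions) == nrow(samples),
                "one region label per channel required")
  if (!is.null(events))
    assert_that(all(events >= 0 & events <= ncol(samples) / fs),
                "event times must lie within the record")
  structure(list(samples = samples, fs = fs, regions = regions,
                 events = events),
            class = "mc_signal")
}

#' Raw extracellular recording (nominal 20 kHz)
#' @inheritParams mc_signal
#' @return an `mc_signal` with subclass `raw_recording`.
#' @export
raw_recording <- function(samples, fs = 20000, regions = NULL,
                          events = NULL) {
  x <- mc_signal(samples, fs, regions, events)
  class(x) <- c("raw_recording", class(x))
  x
}

#' Band-limited LFP signal (1 kHz after the two-step extraction)
#' @inheritParams mc_signal
#' @param band numeric length-2 retained band (Hz).
#' @return an `mc_signal` with subclass `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs = 1000, regions = NULL, events = NULL,
                       band = c(1, 250)) {
  x <- mc_signal(samples, fs, regions, events)
  x$band <- band
  class(x) <- c("lfp_signal", class(x))
  x
}

#' @export
print.mc_signal <- function(x, ...) {
  cat(sprintf("<%s> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              class(x)[1], nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  if (!is.null(x$regions)) cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  if (!is.null(x$events))
    cat("  events:", paste(names(x$events), x$events, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

signal_duration <- function(x) ncol(x$samples) / x$fs

#' Spike train
#'
#' Sorted spike times in seconds. Outputs of [detect_spikes()] additionally
#' satisfy the >1 ms separation rule.
#'
#' @param times numeric vector of spike times (s).
#' @param channel channel index the train belongs to.
#' @param threshold detection threshold that produced the train, if any.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, channel = 1L, threshold = NULL) {
  times <- sort(as.numeric(times))
  structure(list(times = times, channel = channel, threshold = threshold),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes on channel %s", length(x$times),
              paste(x$channel, collapse = ",")))
  if (length(x$times))
    cat(sprintf(" over [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Instantaneous-phase series
#'
#' Phase convention: 0 = oscillation peak, pi (=180 deg) = trough; values
#' wrapped to (-pi, pi].
#'
#' @param phase numeric vector of phases (radians).
#' @param fs sampling rate (Hz).
#' @param band numeric length-2 band the phase was extracted in (Hz).
#' @param reliable logical; FALSE when the band power was negligible.
#' @return object of class `phase_series`.
#' @export
phase_series <- function(phase, fs, band = NULL, reliable = TRUE) {
  structure(list(phase = wrap_pi(phase), fs = fs, band = band,
                 reliable = reliable),
            class = "phase_series")
}

#' Epoch windows around the injection event
#'
#' @param baseline,transition,active numeric length-2 `[start, end)` times
#'   in seconds; must be contiguous and ordered. `transition` may be empty
#'   (zero length) at desk scale.
#' @return object of class `epoch_windows`.
#' @export
epoch_windows <- function(baseline, transition, active) {
  w <- list(baseline = baseline, transition = transition, active = active)
  for (nm in names(w)) {
    assert_that(length(w[[nm]]) == 2 && w[[nm]][2] >= w[[nm]][1],
                sprintf("window '%s' must be an ordered [start, end) pair", nm))
  }
  assert_that(baseline[2] == transition[1] && transition[2] == active[1],
              "windows must be contiguous (baseline|transition|active)")
  assert_that(baseline[2] > baseline[1] && active[2] > active[1],
              "baseline and active windows must be non-empty")
  structure(w, class = "epoch_windows")
}

#' @export
print.epoch_windows <- function(x, ...) {
  cat(sprintf("<epoch_windows> baseline [%g, %g) | transition [%g, %g) | active [%g, %g) s\n",
              x$baseline[1], x$baseline[2], x$transition[1], x$transition[2],
              x$active[1], x$active[2]))
  invisible(x)
}

#' Spectrogram container
#' @param power frequency x time matrix of power density (units^2/Hz).
#' @param freq strictly increasing frequency grid (Hz).
#' @param time strictly increasing window-center times (s).
#' @param window descriptor string.
#' @return object of class `spectrogram`.
#' @export
spectrogram <- function(power, freq, time, window = "kaiser") {
  stopifnot(is.matrix(power), nrow(power) == length(freq),
            ncol(power) == length(time))
  assert_that(all(power >= 0), "spectrogram power must be non-negative")
  assert_that(all(diff(freq) > 0) && all(diff(time) > 0),
              "grids must be strictly increasing")
  structure(list(power = power, freq = freq, time = time, window = window),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freqs [%.3g, %.3g] Hz x %d windows, %s window\n",
              length(x$freq), min(x$freq), max(x$freq), length(x$time),
              x$window))
  invisible(x)
}

#' Coherence spectrum (Welch magnitude-squared coherence)
#' @param freq frequency grid (Hz).
#' @param msc magnitude-squared coherence in \[0, 1\].
#' @param n_segments number of averaged segments.
#' @param segment_s segment length (s).
#' @param overlap overlap fraction.
#' @return object of class `coherence_spectrum`.
#' @export
coherence_spectrum <- function(freq, msc, n_segments, segment_s = 2,
                               overlap = 0.5) {
  assert_that(all(msc >= 0 & msc <= 1 + 1e-9), "msc must lie in [0, 1]")
  structure(list(freq = freq, msc = pmin(msc, 1), n_segments = n_segments,
                 segment_s = segment_s, overlap = overlap),
            class = "coherence_spectrum")
}

#' Phase-locking result
#' @param plv phase-locking value in \[0, 1\].
#' @param n number of samples (or spikes) entering the estimate.
#' @param band band annotation.
#' @param surrogate optional numeric vector of surrogate PLVs.
#' @param significant logical flag (see [plv_significance()]).
#' @param histogram optional normalized phase histogram (spike locking).
#' @return object of class `plv_result`.
#' @export
plv_result <- function(plv, n, band = NULL, surrogate = NULL,
                       significant = NA, histogram = NULL) {
  assert_that(is.na(plv) || (plv >= 0 && plv <= 1 + 1e-9),
              "PLV must lie in [0, 1]")
  structure(list(plv = min(plv, 1), n = n, band = band,
                 surrogate = surrogate, significant = significant,
                 histogram = histogram),
            class = "plv_result")
}

#' @export
print.plv_result <- function(x, ...) {
  cat(sprintf("<plv_result> PLV = %.4f (n = %d)%s\n", x$plv, x$n,
              if (!is.na(x$significant))
                sprintf(", significant = %s", x$significant) else ""))
  invisible(x)
}

#' 4D BOLD series container
#'
#' @param data numeric 4D array `x * y * z * t`.
#' @param TR repetition time (s).
#' @param masks named list of voxel-index matrices (n x 3, 1-based) or
#'   logical 3D arrays; see [make_box_mask()].
#' @param motion optional t x 6 matrix of motion regressors.
#' @param zooms voxel sizes in mm (length 3).
#' @return object of class `bold_series`.
#' @export
bold_series <- function(data, TR = 1, masks = list(), motion = NULL,
                        zooms = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 4, TR > 0)
  dims <- dim(data)[1:3]
  masks <- lapply(masks, normalize_mask, dims = dims)
  if (!is.null(motion))
    stopifnot(nrow(motion) == dim(data)[4], ncol(motion) == 6)
  structure(list(data = data, TR = TR, masks = masks, motion = motion,
                 zooms = zooms),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels x %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$TR))
  if (length(x$masks))
    cat("  masks:", paste(sprintf("%s(%d)", names(x$masks),
                                  vapply(x$masks, nrow, 1L)), collapse = ", "), "\n")
  invisible(x)
}

# Accept logical arrays or n x 3 index matrices; store as index matrix.
normalize_mask <- function(m, dims) {
  if (is.array(m) && is.logical(m)) {
    stopifnot(all(dim(m) == dims))
    m <- which(m, arr.ind = TRUE)
  }
  m <- as.matrix(m)
  stopifnot(ncol(m) == 3)
  assert_that(all(m >= 1) && all(sweep(m, 2, dims, "<=")),
              "mask exceeds the volume grid")
  storage.mode(m) <- "integer"
  m
}

#' Build a box-shaped voxel mask
#'
#' Boxes are given in 0-based voxel indices, inclusive-exclusive
#' `[x0, x1) x [y0, y1) x [z0, z1)` (the convention used for the 5x5x2 and
#' 6x6x2 seeds).
#'
#' @param dims grid dimensions (length 3).
#' @param x0,x1,y0,y1,z0,z1 box bounds.
#' @return integer matrix of 1-based voxel indices (n x 3).
#' @export
make_box_mask <- function(dims, x0, x1, y0, y1, z0, z1) {
  stopifnot(x1 > x0, y1 > y0, z1 > z0)
  g <- expand.grid(x = (x0 + 1):x1, y = (y0 + 1):y1, z = (z0 + 1):z1)
  normalize_mask(as.matrix(g), dims)
}

# Flat (linear) indices of a mask in a 3D grid.
mask_flat <- function(mask, dims) {
  mask[, 1] + dims[1] * (mask[, 2] - 1) + dims[1] * dims[2] * (mask[, 3] - 1)
}

#' Seed connectivity map
#' @param r 3D array of Pearson correlations in \[-1, 1\] (NA allowed).
#' @param seed seed identifier.
#' @param band band-pass used during preprocessing.
#' @return object of class `connectivity_map`.
#' @export
connectivity_map <- function(r, seed = "seed", band = NULL) {
  assert_that(all(abs(r) <= 1 + 1e-9, na.rm = TRUE), "|r| must be <= 1")
  structure(list(r = r, seed = seed, band = band),
            class = "connectivity_map")
}
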