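# Flat-file I/O: raw recordings as little-endian float32 channel-major
# binary with a JSON sidecar, spike trains as CSV, specs as YAML.

#' Write a recording as flat binary + JSON sidecar
#'
#' Samples are little-endian float32, channel-major (channel 1 samples,
#' then channel 2, ...). The sidecar `<stem>.json` holds `fs`, `channels`,
#' `n_samples`, `regions` and `events`.
#'
#' @param x an [mc_signal()] (or subclass).
#' @param stem output path without extension; writes `<stem>.bin` and
#'   `<stem>.json`.
#' @return the binary path, invisibly.
#' @export
write_recording <- function(x, stem) {
  stopifnot(inherits(x, "mc_signal"))
  bin <- paste0(stem, ".bin")
  con <- file(bin, "wb")
  writeBin(as.numeric(t(x$samples)), con, size = 4, endian = "little")
  close(con)
  meta <- list(fs = x$fs, channels = nrow(x$samples),
               n_samples = ncol(x$samples),
               regions = x$regions, events = as.list(x$events %||% list()))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(bin)
}

#' Read a recording written by [write_recording()]
#' @param stem path stem (without extension).
#' @param class_fn constructor to apply ([raw_recording()] by default when
#'   fs >= 4 kHz, else [mc_signal()]).
#' @return the reconstructed signal object.
#' @export
read_recording <- function(stem, class_fn = NULL) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".bin"), "rb")
  v <- readBin(con, "numeric", meta$channels * meta$n_samples, size = 4,
               endian = "little")
  close(con)
  samples <- t(matrix(v, meta$n_samples, meta$channels))
  events <- if (length(meta$events)) unlist(meta$events) else NULL
  cf <- class_fn %||% if (meta$fs >= 4000) raw_recording else mc_signal
  cf(samples, fs = meta$fs, regions = meta$regions, events = events)
}

#' Write spike trains as CSV (channel, time_s)
#' @param trains a [spike_train()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    if (length(tr$times))
      data.frame(channel = tr$channel, time_s = tr$times) else NULL))
  df <- df %||% data.frame(channel = integer(0), time_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV (channel, time_s)
#' @param path CSV path.
#' @return list of [spike_train()]s, one per channel present.
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  assert_that(all(c("channel", "time_s") %in% names(df)),
              "CSV must have columns channel, time_s")
  lapply(split(df$time_s, df$channel), spike_train)
}

#' Serialize a generator spec to YAML
#' @param spec an `lfp_spec`, `sim_spec` or `bold_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spec_yaml <- function(spec, path) {
  x <- unclass(spec)
  x$.class <- class(spec)[1]
  if (!is.null(x$masks)) x$masks <- lapply(x$masks, function(m)
    as.data.frame(m))
  if (!is.null(x$coupling)) x$coupling <- list(
    regions = rownames(x$coupling), values = as.vector(x$coupling))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a spec written by [write_spec_yaml()]
#' @param path YAML path.
#' @return the reconstructed spec object.
#' @export
read_spec_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class; x$.class <- NULL
  if (!is.null(x$masks)) x$masks <- lapply(x$masks, function(m)
    as.matrix(as.data.frame(m)))
  if (!is.null(x$coupling)) {
    r <- x$coupling$regions
    x$coupling <- matrix(unlist(x$coupling$values), length(r), length(r),
                         dimnames = list(r, r))
  }
  switch(cls,
         lfp_spec = do.call(lfp_spec, x),
         sim_spec = do.call(sim_spec, x),
         bold_spec = do.call(bold_spec, x),
         stop("unknown spec class ", cls))
}

#' Write a spectrogram as flat binary + JSON sidecar
#'
#' Power is little-endian float64 in frequency-major order; the sidecar
#' holds the grids and window descriptor.
#'
#' @param spec a [spectrogram()].
#' @param stem output path stem.
#' @return the binary path, invisibly.
#' @export
write_spectrogram <- function(spec, stem) {
  stopifnot(inherits(spec, "spectrogram"))
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(as.numeric(spec$power), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(freq = spec$freq, time = spec$time,
                            window = spec$window),
                       paste0(stem, ".json"), digits = NA)
  invisible(paste0(stem, ".bin"))
}

#' Read a spectrogram written by [write_spectrogram()]
#' @param stem path stem.
#' @return a [spectrogram()].
#' @export
read_spectrogram <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".bin"), "rb")
  v <- readBin(con, "numeric", length(meta$freq) * length(meta$time),
               size = 8, endian = "little")
  close(con)
  spectrogram(matrix(v, length(meta$freq), length(meta$time)),
              meta$freq, meta$time, window = meta$window[1])
}
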