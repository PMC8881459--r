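# Study-scale orchestration: epoch binning, rank-sum + FDR statistics,
# the spike-locking simulation experiment, the coherence-connectivity
# correlation step, and the end-to-end virtual-inhibition scenario.

#' Assign epoch windows around the injection event
#'
#' Builds baseline / transition / active windows from the recording's
#' injection event (baseline = start to injection; transition =
#' `transition_s` after injection; active = remainder) and assigns each
#' analysis bin to the window containing its midpoint.
#'
#' @param recording an [mc_signal()] carrying an `injection` event.
#' @param bin_s bin width (s), default 60.
#' @param transition_s drug-equilibration window length (s), default 900
#'   (15 min).
#' @return list with `windows` (an [epoch_windows()]) and `bins`
#'   (data.frame start, end, mid, window).
#' @export
epoch_bin <- function(recording, bin_s = 60, transition_s = 900) {
  stopifnot(inherits(recording, "mc_signal"))
  inj <- unname(recording$events["injection"])
  assert_that(length(inj) == 1 && is.finite(inj),
              "recording must carry an 'injection' event")
  dur <- signal_duration(recording)
  t2 <- min(inj + transition_s, dur)
  if (t2 >= dur)
    warning("record ends inside the transition window: active window empty")
  windows <- epoch_windows(c(0, inj), c(inj, t2), c(t2, max(dur, t2 + 1e-9)))
  starts <- seq(0, dur - bin_s, by = bin_s)
  mids <- starts + bin_s / 2
  assign_w <- function(m) {
    if (m < inj) "baseline" else if (m < t2) "transition" else "active"
  }
  bins <- data.frame(start = starts, end = starts + bin_s, mid = mids,
                     window = vapply(mids, assign_w, character(1)))
  list(windows = windows, bins = bins)
}

#' Wilcoxon rank-sum tests with Benjamini-Hochberg correction
#'
#' One two-sample rank-sum test per family member, with BH-adjusted q
#' values across the family.
#'
#' @param samplesA,samplesB numeric vectors (single test) or named lists of
#'   vectors (one per family member; names must match).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (the coherence contrasts use one-sided tests).
#' @param exact force exact/normal p computation (default: R's heuristic).
#' @return data.frame with member, n_a, n_b, statistic, p, q.
#' @export
ranksum_fdr <- function(samplesA, samplesB, alternative = "two.sided",
                        exact = NULL) {
  if (!is.list(samplesA)) samplesA <- list(value = samplesA)
  if (!is.list(samplesB)) samplesB <- list(value = samplesB)
  assert_that(identical(names(samplesA), names(samplesB)),
              "family member names must match between groups")
  rows <- lapply(names(samplesA), function(nm) {
    a <- samplesA[[nm]]; b <- samplesB[[nm]]
    assert_that(length(a) >= 3 && length(b) >= 3,
                "need at least 3 values per group")
    if (stats::sd(c(a, b)) == 0) {
      warning(sprintf("'%s': all values tied; p = 1", nm))
      return(data.frame(member = nm, n_a = length(a), n_b = length(b),
                        statistic = NA_real_, p = 1))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative, exact = exact))
    data.frame(member = nm, n_a = length(a), n_b = length(b),
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Run the spike-locking simulation experiment
#'
#' For each seed, generates the locked-only ("inhibited") and mixed
#' ("sham") scenarios, computes the smoothed-train multitaper spectrum of
#' each, and reports the relative power at the carrier frequency and in
#' the 1-4 Hz band.
#'
#' @param spec a [sim_spec()] (its `rng_seed` seeds seed 1; subsequent
#'   seeds are derived).
#' @param n_seeds number of independent repetitions (default 20).
#' @param carrier_halfwidth half-width (Hz) of the integration window
#'   around the carrier frequency.
#' @return list with `per_seed` (data.frame) and `summary` (means across
#'   seeds).
#' @export
run_locking_simulation <- function(spec, n_seeds = 20,
                                   carrier_halfwidth = 0.5) {
  stopifnot(inherits(spec, "sim_spec"))
  f0 <- spec$carrier_frequency
  cb <- c(f0 - carrier_halfwidth, f0 + carrier_halfwidth)
  rows <- lapply(seq_len(n_seeds), function(s) {
    sp <- spec
    sp$rng_seed <- derive_seed(spec$rng_seed %||% 0, s)
    sc <- make_sim_scenarios(sp)
    res <- lapply(list(locked = sc$locked_train, mixed = sc$mixed_train),
                  function(tr) {
      ps <- spike_psd(tr, sp$epoch_length, kernel_width = sp$kernel_width)
      c(carrier = relative_power(ps$freq, ps$psd, cb),
        delta = relative_power(ps$freq, ps$psd, c(1, 4)))
    })
    data.frame(seed = s,
               n_locked = length(sc$locked_train$times),
               n_mixed = length(sc$mixed_train$times),
               locked_carrier = res$locked["carrier"],
               mixed_carrier = res$mixed["carrier"],
               locked_delta = res$locked["delta"],
               mixed_delta = res$mixed["delta"])
  })
  per_seed <- do.call(rbind, rows)
  rownames(per_seed) <- NULL
  list(per_seed = per_seed,
       summary = data.frame(
         locked_carrier = mean(per_seed$locked_carrier),
         mixed_carrier = mean(per_seed$mixed_carrier),
         locked_minus_mixed = mean(per_seed$locked_carrier -
                                     per_seed$mixed_carrier),
         sd_diff = stats::sd(per_seed$locked_carrier -
                               per_seed$mixed_carrier)))
}

#' Per-band linear relation between coherence and connectivity changes
#'
#' Ordinary least-squares R^2 of pairwise connectivity differences against
#' pairwise coherence modulation indices, per band, with BH correction of
#' the regression p values across bands.
#'
#' @param coherence_diffs data.frame with columns pair, band, value.
#' @param fc_diffs data.frame with columns pair, value.
#' @return data.frame with band, n_pairs, slope, r_squared, p, q.
#' @export
coherence_fc_correlation <- function(coherence_diffs, fc_diffs) {
  assert_that(all(c("pair", "band", "value") %in% names(coherence_diffs)) &&
                all(c("pair", "value") %in% names(fc_diffs)),
              "inputs must be tidy (pair, band, value) tables")
  rows <- lapply(split(coherence_diffs, coherence_diffs$band), function(cd) {
    m <- merge(cd, fc_diffs, by = "pair", suffixes = c("_coh", "_fc"))
    assert_that(nrow(m) >= 3, "need at least 3 pairs per band")
    fit <- stats::lm(value_fc ~ value_coh, data = m)
    sf <- summary(fit)
    p <- if (nrow(m) > 2 && sf$fstatistic[1] > 0)
      stats::pf(sf$fstatistic[1], sf$fstatistic[2], sf$fstatistic[3],
                lower.tail = FALSE) else NA_real_
    data.frame(band = cd$band[1], n_pairs = nrow(m),
               slope = unname(stats::coef(fit)[2]),
               r_squared = sf$r.squared, p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

# ---- virtual inhibition end-to-end harness ------------------------------

#' Configuration of the end-to-end virtual-inhibition study
#'
#' Desk-scale defaults: two groups (control / manipulated) of
#' `n_per_group` subjects; each ephys record holds a baseline epoch, a
#' short transition, and an active epoch over three regions (A = PFC,
#' B = Rs, C = Th). The manipulation (active epoch, manipulated group
#' only) removes off-preferred-phase spikes at node A (locked-only firing),
#' raises the shared slow and delta components, and suppresses the node-A
#' gamma component. The BOLD arm raises the seed-target coupling.
#'
#' @param n_per_group subjects per group.
#' @param epoch_s baseline/active epoch length (s).
#' @param transition_s transition gap (s).
#' @param fs_raw raw sampling rate (Hz; >= 8 kHz for the MUA band).
#' @param slow_gain,delta_gain multiplicative increase of the shared
#'   slow/delta amplitudes in the manipulated active epoch.
#' @param gamma_gain multiplicative change of node-A gamma amplitude.
#' @param spike_rate_locked,spike_rate_diffuse baseline locked/diffuse
#'   firing rates at node A (spikes/s).
#' @param kappa_locked,kappa_diffuse von Mises concentrations.
#' @param fc_base,fc_active seed-target BOLD coupling in the two groups'
#'   active states.
#' @param seed master integer seed.
#' @return a list of class `vd_config`.
#' @export
virtual_dreadd_config <- function(n_per_group = 3, epoch_s = 90,
                                  transition_s = 10, fs_raw = 8000,
                                  slow_gain = 2.5, delta_gain = 2.5,
                                  gamma_gain = 0.4,
                                  spike_rate_locked = 4,
                                  spike_rate_diffuse = 4,
                                  kappa_locked = 20, kappa_diffuse = 0.5,
                                  fc_base = 0.35, fc_active = 0.75,
                                  seed = 1) {
  assert_that(fs_raw >= 8000, "fs_raw must be >= 8 kHz for the MUA band")
  structure(as.list(environment()), class = "vd_config")
}

# One subject's ephys record: band-limited shared slow/delta components,
# per-channel theta/beta, gamma with a controllable node-A amplitude, and
# node-A spikes locked to the shared delta phase. Returns raw recording,
# ground-truth delta phase, and the epoch windows.
vd_ephys_subject <- function(cfg, manipulated, seed) {
  E <- cfg$epoch_s; TR <- cfg$transition_s
  segs <- list(baseline = c(FALSE, 1), transition = c(FALSE, 2),
               active = c(manipulated, 3))
  seg_dur <- c(E, TR, E)
  lfps <- list(); spikes <- numeric(0); t0 <- 0
  delta_phase <- list()
  for (i in seq_along(segs)) {
    active_manip <- segs[[i]][1]
    sg <- if (active_manip) cfg$slow_gain else 1
    dg <- if (active_manip) cfg$delta_gain else 1
    gg <- if (active_manip) c(cfg$gamma_gain, 1, 1) else c(1, 1, 1)
    comps <- list(
      # slow component kept in the upper slow band: a 6 s spectrogram
      # window cannot resolve power below ~0.3 Hz, so at desk-scale epoch
      # lengths the lowest decade would add pure estimation noise
      list(band = c(0.35, 0.9), amplitude = 1.0 * sg, phase = c(0, 0.4, 0.8),
           ind_amplitude = 1.2),
      list(band = c(1.2, 3.8), amplitude = 1.0 * dg, phase = c(0, 0.6, 1.2),
           ind_amplitude = 1.2),
      list(band = c(4.5, 7.5), amplitude = 0.4, phase = c(0, 1, 2)),
      list(band = c(13, 28), amplitude = 0.35, phase = c(0, 1, 2)),
      list(band = c(31, 69), amplitude = 0.6 * gg, phase = c(0, 1.5, 3)),
      # independent broadband floor, band-limited below 80 Hz: white noise
      # at the LFP rate would fold interpolation images into the MUA band
      list(band = c(0.1, 80), amplitude = 0, ind_amplitude = 0.5))
    lfp <- gen_band_coupled_lfp(comps, noise_sd = 0,
                                duration = seg_dur[i], sampling_rate = 1000,
                                n_channels = 3,
                                rng_seed = derive_seed(seed, 10 + i))
    lfps[[i]] <- lfp
    # spikes at node A locked to the realized delta-band phase
    dph <- instantaneous_phase(lfp$samples[1, ], "delta", fs = 1000)
    n_locked <- round(cfg$spike_rate_locked * seg_dur[i])
    n_diffuse <- if (active_manip) 0L
    else round(cfg$spike_rate_diffuse * seg_dur[i])
    st_l <- gen_vonmises_spikes(dph, n_locked, cfg$kappa_locked, pi,
                                rng_seed = derive_seed(seed, 20 + i))
    st_d <- gen_vonmises_spikes(dph, n_diffuse, cfg$kappa_diffuse, pi,
                                rng_seed = derive_seed(seed, 30 + i))
    spikes <- c(spikes, t0 + st_l$times, t0 + st_d$times)
    delta_phase[[i]] <- dph
    t0 <- t0 + seg_dur[i]
  }
  samples <- do.call(cbind, lapply(lfps, `[[`, "samples"))
  lfp_all <- mc_signal(samples, 1000)
  # clamp spike times away from the record end (template insertion)
  dur <- signal_duration(lfp_all)
  spikes <- spikes[spikes > 0.002 & spikes < dur - 0.002]
  # expected detection threshold: 4 * (in-band SD of the raw noise);
  # white noise of SD 0.25 keeps fraction (3000-400)/(fs/2) of its
  # variance inside the MUA band
  thr <- 4 * 0.25 * sqrt((3000 - 400) / (cfg$fs_raw / 2))
  raw <- gen_extracellular(
    lfp_all, spikes = list(spike_train(sort(spikes))),
    waveform = biphasic_waveform(cfg$fs_raw, amplitude = 8 * thr),
    noise_sd = 0.25, sampling_rate = cfg$fs_raw,
    rng_seed = derive_seed(seed, 40),
    events = c(injection = E), regions = c("PFC", "Rs", "Th"))
  windows <- epoch_windows(c(0, E), c(E, E + TR), c(E + TR, 2 * E + TR))
  list(raw = raw, windows = windows)
}

# Analyze one subject: band-power MIs per region, pairwise band-median
# coherence MIs, node-A spike-PLV MI.
vd_ephys_analyze <- function(cfg, subj) {
  raw <- subj$raw; w <- subj$windows
  # low-pass-only LFP variant: the printed 1 Hz high-pass would remove
  # the very slow band whose modulation is under test
  lfp <- extract_lfp(raw, f_lo = 0)
  fs <- lfp$fs
  seg <- function(x, win) x[(round(win[1] * fs) + 1):(round(win[2] * fs))]
  bands <- band_defs()
  band_pairs <- Map(c, bands$low, bands$high)
  names(band_pairs) <- bands$name
  # band-power MI per region: one spectrogram per channel x epoch,
  # median band power per epoch, then the modulation index
  power_mi <- lapply(1:3, function(ch) {
    bp <- function(win) {
      sp <- compute_spectrogram(seg(lfp$samples[ch, ], win), fs = fs,
                                fmax = 80)
      vapply(band_pairs, function(b) stats::median(band_power(sp, b)),
             numeric(1))
    }
    modulation_index(bp(w$active), bp(w$baseline))
  })
  names(power_mi) <- raw$regions
  # pairwise coherence MI; the slow band needs long (10 s) Welch segments
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  coh_mi <- lapply(pairs, function(pr) {
    cm <- function(win) {
      x <- seg(lfp$samples[pr[1], ], win)
      y <- seg(lfp$samples[pr[2], ], win)
      # 6 s segments for the slow band: just enough resolution for the
      # generated 0.35-0.9 Hz component, maximizing segment averaging
      c6 <- power_coherence(x, y, fs = fs, segment_s = 6)
      c2 <- power_coherence(x, y, fs = fs, segment_s = 2)
      vapply(names(band_pairs), function(nm) coherence_band_median(
        if (band_pairs[[nm]][1] < 1) c6 else c2, band_pairs[[nm]]),
        numeric(1))
    }
    modulation_index(cm(w$active), cm(w$baseline))
  })
  names(coh_mi) <- vapply(pairs, function(pr)
    paste(raw$regions[pr], collapse = ":"), character(1))
  # node-A spike PLV MI in the delta band
  mua <- extract_mua_signal(mc_signal(raw$samples[1, , drop = FALSE],
                                      raw$fs))
  train <- detect_spikes(mua)
  dph <- instantaneous_phase(lfp$samples[1, ], "delta", fs = fs)
  plv_epoch <- function(win) {
    sel <- train$times >= win[1] & train$times < win[2]
    sub <- spike_train(train$times[sel] - win[1])
    ph <- phase_series(seg(dph$phase, win), fs, band = dph$band)
    spike_phase_locking(sub, ph)$plv
  }
  plv_mi <- modulation_index(plv_epoch(w$active), plv_epoch(w$baseline))
  list(power_mi = power_mi, coh_mi = coh_mi, plv_mi = plv_mi,
       n_spikes = length(train$times))
}

# One group's BOLD cohort and its seed maps.
vd_bold_group <- function(cfg, manipulated, seed) {
  dims <- c(14, 14, 4)
  masks <- list(
    seed = make_box_mask(dims, 1, 6, 1, 6, 0, 2),
    cg = make_box_mask(dims, 8, 12, 1, 5, 0, 2),
    rs = make_box_mask(dims, 8, 13, 8, 13, 0, 2),
    thal_med = make_box_mask(dims, 1, 5, 8, 11, 2, 4),
    thal_lat = make_box_mask(dims, 6, 10, 8, 11, 2, 4),
    ventricle = make_box_mask(dims, 12, 14, 6, 8, 3, 4))
  # one-factor loadings: correlations lambda_i * lambda_j are a valid
  # (positive semi-definite) correlation structure by construction; the
  # manipulation raises the target loadings so seed-target r rises from
  # ~fc_base to ~fc_active while thal_lat stays decoupled
  wfc <- if (manipulated) cfg$fc_active else cfg$fc_base
  rg <- c("seed", "cg", "rs", "thal_med", "thal_lat")
  lam <- c(seed = 0.95, cg = wfc / 0.95, rs = wfc / 0.95,
           thal_med = 0.9 * wfc / 0.95, thal_lat = 0.1)
  W <- outer(lam, lam)
  diag(W) <- 1
  dimnames(W) <- list(rg, rg)
  lapply(seq_len(cfg$n_per_group), function(s) {
    sp <- bold_spec(dims, masks, W, TR = 1, n_volumes = 420,
                    noise_sd = 0.6, drift_sd = 0.3, motion_sd = 0.08,
                    rng_seed = derive_seed(seed, 100 + s))
    pre <- preprocess_bold(gen_bold_dataset(sp), drop = 120)
    seed_map(pre, "seed")
  })
}

#' Run the end-to-end virtual-inhibition study
#'
#' Generates control and manipulated cohorts, runs the full
#' ephys -> spectral -> coupling branch and the BOLD -> seed-map branch,
#' and summarizes the qualitative sign pattern expected under inhibition
#' of the seed node: gamma power down and slow/delta power up at node A,
#' slow/delta coherence up for all three pairs, node-A spike PLV up, and
#' seed connectivity up in the coupled target regions.
#'
#' @param cfg a [virtual_dreadd_config()].
#' @return list with `signs` (named logical vector), `ephys`
#'   (per-group per-subject MI lists), `stats` (rank-sum + BH table of
#'   group contrasts), `fc` (target-mask mean Fisher-z difference), and
#'   `config`.
#' @export
run_virtual_dreadd <- function(cfg = virtual_dreadd_config()) {
  stopifnot(inherits(cfg, "vd_config"))
  groups <- list(control = FALSE, manipulated = TRUE)
  ephys <- lapply(names(groups), function(g) {
    manip <- groups[[g]]
    lapply(seq_len(cfg$n_per_group), function(s) {
      subj <- vd_ephys_subject(cfg, manip,
                               seed = derive_seed(cfg$seed,
                                                  1000 * manip + s))
      vd_ephys_analyze(cfg, subj)
    })
  })
  names(ephys) <- names(groups)
  manip <- ephys$manipulated
  med <- function(xs) stats::median(unlist(xs))
  gammaA <- med(lapply(manip, function(s) s$power_mi$PFC["gamma"]))
  slowA <- med(lapply(manip, function(s) s$power_mi$PFC["slow"]))
  deltaA <- med(lapply(manip, function(s) s$power_mi$PFC["delta"]))
  coh_ok <- all(vapply(names(manip[[1]]$coh_mi), function(pr) {
    med(lapply(manip, function(s) s$coh_mi[[pr]]["slow"])) > 0 &&
      med(lapply(manip, function(s) s$coh_mi[[pr]]["delta"])) > 0
  }, logical(1)))
  plv <- med(lapply(manip, function(s) s$plv_mi))
  mapsA <- vd_bold_group(cfg, TRUE, derive_seed(cfg$seed, 7))
  mapsB <- vd_bold_group(cfg, FALSE, derive_seed(cfg$seed, 8))
  gd <- group_diff_map(mapsA, mapsB)
  dims <- dim(gd$t)
  targets <- c("cg", "rs", "thal_med")
  # target masks rebuilt from the generator's fixed geometry
  tmask <- do.call(rbind, vd_bold_group_masks(dims)[targets])
  fc_diff <- mask_mean(gd$mean_diff, tmask)
  signs <- c(gamma_A_down = gammaA < 0,
             slow_delta_power_up = slowA > 0 && deltaA > 0,
             slow_delta_coherence_up = coh_ok,
             spike_plv_up = plv > 0,
             seed_fc_up = fc_diff > 0)
  # group contrast table (band x region power MIs, pair x band coherence);
  # rank-sum needs >= 3 subjects per group
  stats_tb <- if (cfg$n_per_group >= 3)
    ranksum_fdr(vd_family(ephys$manipulated), vd_family(ephys$control))
  else NULL
  list(signs = signs, ephys = ephys, stats = stats_tb,
       fc = list(mean_z_diff = fc_diff, group_map = gd), config = cfg)
}

# Fixed BOLD mask geometry (shared by generator and sign summary).
vd_bold_group_masks <- function(dims) {
  list(seed = make_box_mask(dims, 1, 6, 1, 6, 0, 2),
       cg = make_box_mask(dims, 8, 12, 1, 5, 0, 2),
       rs = make_box_mask(dims, 8, 13, 8, 13, 0, 2),
       thal_med = make_box_mask(dims, 1, 5, 8, 11, 2, 4),
       thal_lat = make_box_mask(dims, 6, 10, 8, 11, 2, 4))
}

# Collect per-subject statistics into a named family for ranksum_fdr.
# With tiny cohorts the p values are structural, not inferential; the
# table exercises the family/FDR mechanics.
vd_family <- function(group) {
  fam <- list()
  for (band in c("slow", "delta", "gamma"))
    fam[[paste0("power_PFC_", band)]] <-
      vapply(group, function(s) s$power_mi$PFC[band], numeric(1))
  for (pr in names(group[[1]]$coh_mi))
    for (band in c("slow", "delta"))
      fam[[paste0("coh_", pr, "_", band)]] <-
        vapply(group, function(s) s$coh_mi[[pr]][band], numeric(1))
  fam$plv_PFC_delta <- vapply(group, function(s) s$plv_mi, numeric(1))
  fam
}
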