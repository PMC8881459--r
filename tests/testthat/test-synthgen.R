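# Synthetic-data generators: validation, reproducibility, ground-truth
# recovery, and the von Mises machinery.

test_that("lfp_spec validates its invariants", {
  comp <- list(list(frequency = 2, amplitude = 1))
  expect_error(lfp_spec(comp, duration = -1, n_channels = 2),
               "duration")
  expect_error(lfp_spec(list(list(frequency = 600, amplitude = 1)),
                        duration = 1, sampling_rate = 1000), "Nyquist")
  expect_error(lfp_spec(comp, noise_sd = -1, duration = 1), "noise_sd")
})

test_that("gen_coupled_lfp is reproducible and carries its components", {
  spec <- lfp_spec(list(list(frequency = 2, amplitude = 1,
                             phase = c(0, pi / 2))),
                   noise_sd = 0.5, duration = 10, n_channels = 2,
                   rng_seed = 99)
  a <- gen_coupled_lfp(spec)
  b <- gen_coupled_lfp(spec)
  expect_identical(a$samples, b$samples)
  # noiseless pure tone: identical channels give msc = 1 at the tone
  spec0 <- lfp_spec(list(list(frequency = 1, amplitude = 1)),
                    duration = 20, n_channels = 2)
  x0 <- gen_coupled_lfp(spec0)
  coh <- power_coherence(x0, segment_s = 4)
  expect_equal(coh$msc[which.min(abs(coh$freq - 1))], 1, tolerance = 1e-6)
})

test_that("independent-noise channels show the 1/K Welch coherence bias", {
  # Monte-Carlo: mean msc over seeds vs the finite-sample bias level
  ms <- vapply(1:100, function(s) {
    spec <- lfp_spec(list(list(frequency = 5, amplitude = 0)), noise_sd = 1,
                     duration = 16, sampling_rate = 250, n_channels = 2,
                     rng_seed = s)
    x <- gen_coupled_lfp(spec)
    coh <- power_coherence(x, segment_s = 2)
    mean(coh$msc[coh$freq > 5 & coh$freq < 120])
  }, numeric(1))
  K <- 15  # segments for 16 s at 2 s / 50%
  expect_equal(mean(ms), 1 / K, tolerance = 0.35)
})

test_that("gen_coupled_lfp phase offsets drive the preferred phase difference", {
  spec <- lfp_spec(list(list(frequency = 1, amplitude = 1,
                             phase = c(0, -pi / 2))),
                   duration = 30, sampling_rate = 250, n_channels = 2)
  x <- gen_coupled_lfp(spec)
  # analytic-signal phases directly on the noiseless sinusoids
  p1 <- Arg(slowsync:::hilbert_analytic(x$samples[1, ]))
  p2 <- Arg(slowsync:::hilbert_analytic(x$samples[2, ]))
  d <- preferred_phase_difference(p1[500:7000], p2[500:7000])
  expect_equal(d$mean, pi / 2, tolerance = 0.05)
  expect_gt(d$resultant, 0.99)
})

test_that("rvonmises converges to its stated mean and concentration", {
  for (kap in c(4, 20)) {
    th <- with_seed(7, rvonmises(1e5, mu = 1, kappa = kap))
    cs <- circ_stats(th)
    expect_equal(cs$mean, 1, tolerance = 0.02)
    expect_equal(slowsync:::vm_kappa_mle(cs$r), kap, tolerance = 0.02 * kap)
  }
  expect_error(rvonmises(10, 0, -1), "kappa")
})

test_that("gen_vonmises_spikes respects kappa limits", {
  fs <- 1000
  ph <- phase_series(wrap_pi(2 * pi * 1 * (0:(10 * fs - 1)) / fs), fs)
  # degenerate concentration: every spike at the preferred phase
  st <- gen_vonmises_spikes(ph, 100, 1e6, 2, rng_seed = 1)
  spk_ph <- wrap_pi(2 * pi * st$times)
  expect_lt(max(abs(wrap_pi(spk_ph - 2))), 0.01)
  expect_gt(spike_phase_locking(st, ph)$plv, 0.999)
  # uniform: PLV ~ sqrt(pi / (4 n)) (expected resultant under uniformity)
  n <- 1e4
  plvs <- vapply(1:20, function(s)
    spike_phase_locking(gen_vonmises_spikes(ph, n, 0, 0, rng_seed = s),
                        ph)$plv, numeric(1))
  expect_equal(mean(plvs), sqrt(pi / (4 * n)), tolerance = 0.25)
})

test_that("sim scenarios carry the stated spike counts and rates", {
  spec <- sim_spec(rng_seed = 3)
  sc <- make_sim_scenarios(spec)
  expect_identical(length(sc$locked_train$times), 100L)
  expect_identical(length(sc$mixed_train$times), 200L)
  # mean rate 10 spikes/s over the 10 s epoch
  expect_equal(length(sc$locked_train$times) / spec$epoch_length, 10)
  # reproducibility
  sc2 <- make_sim_scenarios(spec)
  expect_identical(sc$mixed_train$times, sc2$mixed_train$times)
})

test_that("identical generating laws give indistinguishable 1 Hz power", {
  # kappa_diffuse = kappa_locked at the same phase: the two scenarios
  # differ only in spike count, so relative carrier power converges
  spec <- sim_spec(kappa_diffuse = 20, diffuse_phase = pi, rng_seed = 5)
  diffs <- vapply(1:10, function(s) {
    sp <- spec; sp$rng_seed <- s
    sc <- make_sim_scenarios(sp)
    p1 <- spike_psd(sc$locked_train, 10)
    p2 <- spike_psd(sc$mixed_train, 10)
    relative_power(p1$freq, p1$psd, c(0.5, 1.5)) -
      relative_power(p2$freq, p2$psd, c(0.5, 1.5))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("gen_extracellular: inserted spikes are recovered exactly without noise", {
  fs_raw <- 20000
  st <- spike_train(seq(0.05, 1.95, by = 0.05))
  lfp <- mc_signal(numeric(2000), fs = 1000)
  raw <- gen_extracellular(lfp, st, waveform = biphasic_waveform(fs_raw, 8),
                           noise_sd = 0, sampling_rate = fs_raw)
  # a small Gaussian floor fixes the detection threshold; size the
  # template at 8x the threshold measured on the filtered floor itself
  sdn <- 0.05
  mua0 <- extract_mua_signal(gen_extracellular(lfp, NULL, noise_sd = sdn,
                                               sampling_rate = fs_raw,
                                               rng_seed = 2))
  thr0 <- 4 * median(abs(mua0$samples)) / 0.6745
  raw2 <- gen_extracellular(lfp, st,
                            waveform = biphasic_waveform(fs_raw, 8 * thr0),
                            noise_sd = sdn, sampling_rate = fs_raw,
                            rng_seed = 2)
  det <- detect_spikes(extract_mua_signal(raw2))
  # every inserted spike recovered; a floor excursion just before a true
  # spike can claim the event via the keep-earlier refractory rule, so
  # the worst-case timing allowance is one refractory interval
  d <- vapply(st$times, function(t) min(abs(det$times - t)), numeric(1))
  expect_lte(quantile(d, 0.95, names = FALSE), 5e-4)
  expect_lte(max(d), 2e-3)
  # extras bounded by the expected 4-sigma crossing count of the floor
  expect_lte(length(det$times) - length(st$times), 8)
  expect_error(gen_extracellular(lfp, spike_train(5), noise_sd = 0),
               "outside")
})

test_that("detect_spikes false positives match a brute-force crossing oracle", {
  # same filtered noise, two independent code paths
  set.seed(21)
  fs <- 20000
  raw <- raw_recording(matrix(rnorm(fs * 5, sd = 0.3), 1), fs = fs)
  hf <- extract_mua_signal(raw)
  det <- detect_spikes(hf)
  x <- hf$samples[1, ]
  thr <- 4 * median(abs(x)) / 0.6745
  up <- which(abs(x) >= thr & c(FALSE, abs(x[-length(x)]) < thr))
  keep <- c()
  last <- -Inf
  for (i in up) if ((i - 1) / fs - last > 0.001) { keep <- c(keep, i); last <- (i - 1) / fs }
  expect_equal(det$times, (keep - 1) / fs)
  expect_equal(det$threshold, thr)
})

test_that("pure LFP input survives the round trip through the raw rate", {
  spec <- lfp_spec(list(list(frequency = 7, amplitude = 1),
                        list(frequency = 40, amplitude = 0.5)),
                   duration = 12, n_channels = 1)
  lfp0 <- gen_coupled_lfp(spec)
  raw <- gen_extracellular(lfp0, NULL, noise_sd = 0, sampling_rate = 20000)
  lfp1 <- extract_lfp(raw)
  n <- min(ncol(lfp0$samples), ncol(lfp1$samples))
  i <- 2000:(n - 2000)
  expect_gt(cor(lfp0$samples[1, i], lfp1$samples[1, i]), 0.99)
})

test_that("BOLD generator recovers its coupling ground truth", {
  dims <- c(8, 8, 2)
  masks <- list(seed = make_box_mask(dims, 0, 3, 0, 3, 0, 1),
                target = make_box_mask(dims, 4, 8, 4, 8, 0, 2),
                ventricle = make_box_mask(dims, 4, 6, 0, 2, 1, 2))
  W1 <- matrix(c(1, 1, 1, 1), 2, 2,
               dimnames = list(c("seed", "target"), c("seed", "target")))
  sp <- bold_spec(dims, masks, W1, n_volumes = 200, noise_sd = 0,
                  drift_sd = 0, motion_sd = 0, rng_seed = 5)
  b <- gen_bold_dataset(sp)
  pre <- preprocess_bold(b, band = NULL, drop = 20)
  cm <- seed_map(pre, "seed")
  expect_equal(mean(cm$r[masks$target]), 1, tolerance = 1e-6)
  # uncoupled: null r distribution within the Fisher bound
  W0 <- diag(2); dimnames(W0) <- dimnames(W1)
  rs <- unlist(lapply(1:8, function(s) {
    sp0 <- bold_spec(dims, masks, W0, n_volumes = 220, noise_sd = 1,
                     drift_sd = 0, motion_sd = 0, rng_seed = s)
    pre0 <- preprocess_bold(gen_bold_dataset(sp0), band = c(0.01, 0.1),
                            drop = 20)
    seed_map(pre0, "seed")$r[masks$target]
  }))
  # band-passed series have fewer effective dof than n_volumes; the
  # empirical null should still be small and roughly symmetric
  expect_lt(quantile(abs(rs), 0.95), 0.6)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("two orthogonally coupled thalamic clusters are recovered by k-means", {
  dims <- c(10, 10, 2)
  masks <- list(seed = make_box_mask(dims, 0, 4, 0, 4, 0, 1),
                thal_a = make_box_mask(dims, 5, 10, 5, 10, 0, 1),
                thal_b = make_box_mask(dims, 5, 10, 0, 4, 1, 2),
                ventricle = make_box_mask(dims, 0, 2, 8, 10, 1, 2))
  rg <- c("seed", "thal_a", "thal_b")
  W <- diag(3); dimnames(W) <- list(rg, rg)
  W["seed", "thal_a"] <- W["thal_a", "seed"] <- 0.9
  sp <- bold_spec(dims, masks, W, n_volumes = 320, noise_sd = 0.3,
                  rng_seed = 12)
  pre <- preprocess_bold(gen_bold_dataset(sp), drop = 20)
  cm <- seed_map(pre, "seed")
  vox <- rbind(masks$thal_a, masks$thal_b)
  truth <- rep(1:2, c(nrow(masks$thal_a), nrow(masks$thal_b)))
  # profile features: seed r plus the voxel's correlation with each
  # cluster's mean (simple, sufficient for orthogonal profiles)
  Y <- t(matrix(pre$data, prod(dims), dim(pre$data)[4]))
  fl <- slowsync:::mask_flat(vox, dims)
  prof <- cbind(cm$r[vox])
  labels <- kmeans_partition(prof, 2, rng_seed = 9)
  expect_equal(adjusted_rand(labels, truth), 1)
})

test_that("spec YAML round-trips", {
  sp <- sim_spec(rng_seed = 4)
  f <- tempfile(fileext = ".yaml")
  write_spec_yaml(sp, f)
  sp2 <- read_spec_yaml(f)
  expect_equal(sp2$kappa_locked, sp$kappa_locked)
  expect_equal(sp2$diffuse_phase, sp$diffuse_phase)
  expect_s3_class(sp2, "sim_spec")
})
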