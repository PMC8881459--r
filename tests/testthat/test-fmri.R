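# BOLD preprocessing, seed maps, profiles, partitions, group contrasts,
# and the NIfTI / flat-binary round trips.

mk_bold <- function(seed = 1, dims = c(8, 8, 2), n_volumes = 260,
                    coupling = 0.8, noise = 0.5) {
  masks <- list(seed = make_box_mask(dims, 0, 3, 0, 3, 0, 1),
                target = make_box_mask(dims, 4, 8, 4, 8, 0, 2),
                ventricle = make_box_mask(dims, 4, 6, 0, 2, 1, 2))
  W <- matrix(c(1, coupling, coupling, 1), 2, 2,
              dimnames = list(c("seed", "target"), c("seed", "target")))
  gen_bold_dataset(bold_spec(dims, masks, W, n_volumes = n_volumes,
                             noise_sd = noise, rng_seed = seed))
}

test_that("preprocessing drops volumes and orthogonalizes nuisance regressors", {
  b <- mk_bold(2)
  pre <- preprocess_bold(b, band = NULL, drop = 60)
  expect_identical(dim(pre$data)[4], dim(b$data)[4] - 60L)
  keep <- 61:dim(b$data)[4]
  d <- dim(b$data)
  Y <- t(matrix(pre$data, prod(d[1:3]), length(keep)))
  vent <- rowMeans(t(matrix(b$data, prod(d[1:3]),
                            d[4]))[keep, slowsync:::mask_flat(b$masks$ventricle,
                                                              d[1:3])])
  X <- cbind(b$motion[keep, ], vent)
  # residuals orthogonal to every nuisance regressor used in the fit
  pre2 <- preprocess_bold(b, band = NULL, drop = 60)
  R <- t(matrix(pre2$data, prod(d[1:3]), length(keep)))
  vent_pre <- rowMeans(R[, slowsync:::mask_flat(b$masks$ventricle, d[1:3])])
  cors <- abs(cor(b$motion[keep, ], R))
  expect_lt(max(cors, na.rm = TRUE), 1e-10)
  expect_error(preprocess_bold(b, drop = 500), "too few")
})

test_that("band-pass attenuates slow drift by 20 dB or more", {
  fs <- 1
  drift <- tone(0.005, fs, 1000)
  out <- slowsync:::fft_bandpass(drift, fs, 0.01, 0.1)
  expect_lt(atten_db(drift, out), -20)
})

test_that("seed maps hit the Pearson limit cases and attenuation formula", {
  dims0 <- c(8, 8, 2)
  masks0 <- list(seed = make_box_mask(dims0, 0, 3, 0, 3, 0, 1),
                 target = make_box_mask(dims0, 4, 8, 4, 8, 0, 2),
                 ventricle = make_box_mask(dims0, 4, 6, 0, 2, 1, 2))
  W1 <- matrix(1, 2, 2, dimnames = list(c("seed", "target"),
                                        c("seed", "target")))
  b <- gen_bold_dataset(bold_spec(dims0, masks0, W1, n_volumes = 260,
                                  noise_sd = 0, drift_sd = 0,
                                  motion_sd = 0, rng_seed = 3))
  pre <- preprocess_bold(b, band = NULL, drop = 20)
  cm <- seed_map(pre, "seed")
  expect_equal(mean(cm$r[pre$masks$target]), 1, tolerance = 1e-8)
  # negated voxel
  d <- dim(pre$data)
  pre$data[8, 8, 2, ] <- -pre$data[1, 1, 1, ]
  cm2 <- seed_map(pre, "seed")
  expect_equal(cm2$r[8, 8, 2], -cm$r[1, 1, 1], tolerance = 1e-8)
  # zero-variance voxel -> NA
  pre$data[8, 8, 1, ] <- 0
  expect_true(is.na(seed_map(pre, "seed")$r[8, 8, 1]))
  # analytic attenuation: target = w s + e -> r = w / sqrt(w^2 + sigma^2/Ps)
  dims <- c(8, 8, 2)
  masks <- list(seed = make_box_mask(dims, 0, 3, 0, 3, 0, 1),
                target = make_box_mask(dims, 4, 8, 4, 8, 0, 2),
                ventricle = make_box_mask(dims, 4, 6, 0, 2, 1, 2))
  w <- 0.6; sigma <- 0.8
  W <- matrix(c(1, w, w, 1), 2, 2,
              dimnames = list(c("seed", "target"), c("seed", "target")))
  rs <- vapply(1:12, function(s) {
    sp <- bold_spec(dims, masks, W, n_volumes = 800, noise_sd = sigma,
                    drift_sd = 0, motion_sd = 0, hrf = FALSE,
                    region_noise = list(seed = 1e-8), rng_seed = s)
    pre <- preprocess_bold(gen_bold_dataset(sp), band = NULL, drop = 40)
    mean(seed_map(pre, "seed")$r[masks$target])
  }, numeric(1))
  # latent signals are unit-SD, so Ps = 1; coupling w means the target
  # carries w*s + sqrt(1-w^2)*u in addition to its own white noise
  expected <- 1 / sqrt(1 + sigma^2)  # corr(target_signal+noise, s)/... times w
  expected <- w / sqrt(1 + sigma^2)
  expect_equal(mean(rs), expected, tolerance = 0.1)
})

test_that("antero-posterior profile tracks the coupling gradient", {
  dims <- c(6, 18, 2)
  seed <- make_box_mask(dims, 0, 6, 0, 3, 0, 2)
  chain <- lapply(0:3, function(k)
    make_box_mask(dims, 0, 6, 4 + 3 * k, 7 + 3 * k, 0, 2))
  rg <- c("seed", paste0("m", 1:4))
  lam <- c(0.95, 0.9, 0.75, 0.55, 0.35)       # decaying loadings
  W <- outer(lam, lam); diag(W) <- 1
  dimnames(W) <- list(rg, rg)
  masks <- c(list(seed = seed), setNames(chain, rg[-1]),
             list(ventricle = make_box_mask(dims, 0, 2, 0, 2, 1, 2)))
  sp <- bold_spec(dims, masks, W, n_volumes = 420, noise_sd = 0.4,
                  rng_seed = 11)
  pre <- preprocess_bold(gen_bold_dataset(sp), drop = 60)
  prof <- ap_profile(pre, "seed", chain)
  expect_identical(nrow(prof), 4L)
  expect_lt(cor(prof$position, prof$r, method = "spearman"), 0)
  # equal coupling: flat within a generous confidence band
  W2 <- outer(c(0.9, rep(0.8, 4)), c(0.9, rep(0.8, 4))); diag(W2) <- 1
  dimnames(W2) <- dimnames(W)
  sp2 <- bold_spec(dims, masks, W2, n_volumes = 420, noise_sd = 0.4,
                   rng_seed = 12)
  prof2 <- ap_profile(preprocess_bold(gen_bold_dataset(sp2), drop = 60),
                      "seed", chain)
  expect_lt(diff(range(prof2$r)), 0.35)
  # single-seed chain: one value
  expect_identical(nrow(ap_profile(pre, "seed", chain[1])), 1L)
  # overlap handling
  expect_warning(ap_profile(pre, "seed", list(seed)), "overlap")
})

test_that("k-means partition contracts: k=1, determinism, duplication", {
  set.seed(5)
  prof <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 5), 30, 2))
  expect_identical(kmeans_partition(prof, 1), rep(1L, 60))
  l1 <- kmeans_partition(prof, 2, rng_seed = 42)
  l2 <- kmeans_partition(prof, 2, rng_seed = 42)
  expect_identical(l1, l2)
  ld <- kmeans_partition(rbind(prof, prof), 2, rng_seed = 42)
  expect_equal(adjusted_rand(ld[1:60], ld[61:120]), 1)
  expect_equal(adjusted_rand(l1, rep(1:2, each = 30)), 1)
  expect_error(kmeans_partition(prof, 100), "k must be")
})

test_that("group difference maps: null rate, injected effect, degenerate input", {
  # null: suprathreshold fraction matches the t tail at |t| > 2
  set.seed(6)
  dims <- c(10, 10, 4)
  nullmap <- function() connectivity_map(array(tanh(rnorm(prod(dims),
                                                          sd = 0.2)), dims))
  rates <- vapply(1:20, function(i) {
    A <- replicate(6, nullmap(), simplify = FALSE)
    B <- replicate(6, nullmap(), simplify = FALSE)
    gd <- group_diff_map(A, B)
    mean(gd$mask)
  }, numeric(1))
  expected <- 2 * pt(-2, df = 10)
  expect_equal(mean(rates), expected, tolerance = 0.25)
  # injected increase in a target region: suprathreshold, positive t
  tgt <- make_box_mask(dims, 2, 6, 2, 6, 1, 3)
  bump <- array(0, dims); bump[tgt] <- 0.5
  A2 <- replicate(6, {
    m <- nullmap(); m$r <- tanh(atanh(m$r) + bump); m
  }, simplify = FALSE)
  B2 <- replicate(6, nullmap(), simplify = FALSE)
  gd2 <- group_diff_map(A2, B2, n_perm = 50, rng_seed = 3)
  expect_gt(mean(gd2$mask[tgt]), 0.8)
  expect_gt(mask_mean(gd2$t, tgt), 2)
  expect_lt(gd2$cluster_p, 0.05)
  # identical maps in both groups: zero variance -> NA t everywhere
  same <- replicate(3, nullmap()$r, simplify = FALSE)
  gd3 <- group_diff_map(lapply(same, connectivity_map),
                        lapply(same, connectivity_map))
  expect_true(all(gd3$t == 0 | is.na(gd3$t)))
  expect_true(all(gd3$mean_diff == 0))
  expect_error(group_diff_map(list(nullmap()), list(nullmap())),
               "at least two")
})

test_that("NIfTI-1 round trip preserves data, zooms and TR", {
  arr <- array(rnorm(6 * 5 * 4 * 10), c(6, 5, 4, 10))
  f <- tempfile(fileext = ".nii")
  write_nifti(arr, f, zooms = c(0.5, 0.5, 1), TR = 2)
  back <- read_nifti(f)
  expect_equal(back$data, arr, tolerance = 1e-6)    # float32 storage
  expect_equal(back$zooms, c(0.5, 0.5, 1), tolerance = 1e-6)
  expect_equal(back$TR, 2)
  # float64 is exact
  write_nifti(arr, f, datatype = "float64")
  expect_identical(read_nifti(f)$data, arr)
})

test_that("recording and spike-train flat files round-trip", {
  x <- raw_recording(matrix(rnorm(8000), 2), fs = 4000,
                     regions = c("PFC", "Rs"), events = c(injection = 0.7))
  stem <- tempfile()
  write_recording(x, stem)
  back <- read_recording(stem)
  expect_equal(back$samples, x$samples, tolerance = 1e-6)
  expect_identical(back$regions, x$regions)
  expect_equal(back$events, x$events)
  trains <- list(spike_train(c(0.1, 0.5), channel = 1),
                 spike_train(c(0.2), channel = 2))
  f <- tempfile(fileext = ".csv")
  write_spikes_csv(trains, f)
  back2 <- read_spikes_csv(f)
  expect_equal(back2[[1]]$times, c(0.1, 0.5))
  expect_equal(back2[[2]]$times, 0.2)
})

test_that("spectrogram flat files round-trip", {
  sp <- compute_spectrogram(tone(5, 1000, 12), fs = 1000, fmax = 30)
  stem <- tempfile()
  write_spectrogram(sp, stem)
  back <- read_spectrogram(stem)
  expect_equal(back$power, sp$power)
  expect_equal(back$freq, sp$freq)
})
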