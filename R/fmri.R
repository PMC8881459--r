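# Seed-based rsfMRI connectivity at desk scale: preprocessing, seed maps,
# antero-posterior profiles, k-means thalamic partitioning, group
# contrasts.

# Flatten the 4D array to a t x voxels matrix and back.
bold_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, prod(d[1:3]), d[4])   # voxels x t
}

#' Preprocess a BOLD series
#'
#' Drops the initial volumes, regresses out the 6 motion traces plus the
#' mean ventricular signal (plus, optionally, the global intracerebral
#' mean) from every voxel, band-pass filters (zero-phase, frequency
#' domain), and optionally smooths spatially.
#'
#' @param series a [bold_series()] with a `"ventricle"` mask and motion
#'   regressors.
#' @param band `[low, high]` pass band in Hz (default 0.01-0.1; use
#'   0.01-0.25 for the medetomidine-isoflurane variant); `NULL` skips
#'   filtering.
#' @param drop number of initial volumes to discard (default 120).
#' @param global_signal also regress the global mean over `brain_mask`
#'   (or the whole grid).
#' @param smooth_fwhm optional Gaussian smoothing FWHM in mm (uses
#'   `series$zooms`).
#' @return the preprocessed [bold_series()].
#' @export
preprocess_bold <- function(series, band = c(0.01, 0.1), drop = 120,
                            global_signal = FALSE, smooth_fwhm = NULL) {
  stopifnot(inherits(series, "bold_series"))
  d <- dim(series$data)
  assert_that(d[4] > drop + 8, "too few volumes after dropping")
  keep <- (drop + 1):d[4]
  Y <- t(bold_matrix(series))[keep, , drop = FALSE]   # t x voxels
  motion <- if (!is.null(series$motion))
    series$motion[keep, , drop = FALSE] else NULL
  X <- cbind(intercept = 1, motion)
  vent <- series$masks$ventricle
  if (!is.null(vent)) {
    assert_that(nrow(vent) > 0, "ventricle mask is empty")
    X <- cbind(X, ventricle = rowMeans(Y[, mask_flat(vent, d[1:3]),
                                         drop = FALSE]))
  }
  if (global_signal) {
    gm <- series$masks$brain
    g <- if (!is.null(gm)) rowMeans(Y[, mask_flat(gm, d[1:3]), drop = FALSE])
    else rowMeans(Y)
    X <- cbind(X, global = g)
  }
  Q <- qr.Q(qr(X))
  Y <- Y - Q %*% (t(Q) %*% Y)
  if (!is.null(band)) {
    fs <- 1 / series$TR
    Y <- apply(Y, 2, fft_bandpass, fs = fs, f_lo = band[1], f_hi = band[2])
  }
  arr <- array(t(Y), dim = c(d[1:3], length(keep)))
  out <- bold_series(arr, TR = series$TR, masks = series$masks,
                     motion = motion, zooms = series$zooms)
  if (!is.null(smooth_fwhm)) out <- smooth_bold(out, smooth_fwhm)
  out$band <- band
  out
}

# Separable Gaussian spatial smoothing, FWHM in mm converted per-axis via
# the voxel zooms.
smooth_bold <- function(series, fwhm_mm) {
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$zooms
  d <- dim(series$data)
  for (ax in 1:3) {
    s <- sig[ax]
    if (s < 0.25) next
    half <- max(1L, ceiling(3 * s))
    g <- stats::dnorm(-half:half, sd = s); g <- g / sum(g)
    series$data <- apply_along(series$data, ax, g)
  }
  series
}

apply_along <- function(arr, axis, kernel) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:4, axis))
  A <- aperm(arr, perm)
  M <- matrix(A, d[axis], prod(d[-axis]))
  half <- (length(kernel) - 1) / 2
  Mp <- rbind(M[rep(1, half), , drop = FALSE], M,
              M[rep(nrow(M), half), , drop = FALSE])
  Ms <- apply(Mp, 2, function(v)
    stats::filter(v, kernel, sides = 2))[(half + 1):(half + d[axis]), ,
                                         drop = FALSE]
  Ms[is.na(Ms)] <- M[is.na(Ms)]
  aperm(array(Ms, d[perm]), order(perm))
}

#' Seed-based connectivity map
#'
#' Pearson correlation between the seed-mean time course and every voxel.
#'
#' @param series a preprocessed [bold_series()].
#' @param seed_mask voxel mask (name of a stored mask, index matrix, or
#'   logical array).
#' @return a [connectivity_map()]; zero-variance voxels are NA.
#' @export
seed_map <- function(series, seed_mask = "seed") {
  stopifnot(inherits(series, "bold_series"))
  d <- dim(series$data)
  if (is.character(seed_mask)) {
    assert_that(seed_mask %in% names(series$masks),
                sprintf("no stored mask named '%s'", seed_mask))
    nm <- seed_mask
    seed_mask <- series$masks[[seed_mask]]
  } else {
    nm <- "seed"
    seed_mask <- normalize_mask(seed_mask, d[1:3])
  }
  Y <- t(bold_matrix(series))                       # t x voxels
  s <- rowMeans(Y[, mask_flat(seed_mask, d[1:3]), drop = FALSE])
  r <- suppressWarnings(as.vector(stats::cor(s, Y)))
  r[!is.finite(r)] <- NA_real_
  connectivity_map(array(r, d[1:3]), seed = nm, band = series$band)
}

#' Antero-posterior connectivity profile
#'
#' Pearson correlation between the reference (PFC) seed-mean time course
#' and each seed of an ordered midline chain. Voxels shared between the
#' reference and a chain seed are excluded from that seed with a warning.
#'
#' @param series a preprocessed [bold_series()].
#' @param ref_mask reference seed mask (or stored-mask name).
#' @param seed_chain ordered list of masks (anterior to posterior).
#' @return data.frame with position, n_voxels, r.
#' @export
ap_profile <- function(series, ref_mask, seed_chain) {
  stopifnot(inherits(series, "bold_series"))
  assert_that(length(seed_chain) >= 1, "need at least one midline seed")
  d <- dim(series$data)
  if (is.character(ref_mask)) ref_mask <- series$masks[[ref_mask]]
  ref_mask <- normalize_mask(ref_mask, d[1:3])
  Y <- t(bold_matrix(series))
  ref_fl <- mask_flat(ref_mask, d[1:3])
  s <- rowMeans(Y[, ref_fl, drop = FALSE])
  rows <- lapply(seq_along(seed_chain), function(i) {
    m <- normalize_mask(seed_chain[[i]], d[1:3])
    fl <- mask_flat(m, d[1:3])
    if (any(fl %in% ref_fl)) {
      warning(sprintf("seed %d overlaps the reference; overlap excluded", i))
      fl <- setdiff(fl, ref_fl)
    }
    r <- if (length(fl)) stats::cor(s, rowMeans(Y[, fl, drop = FALSE]))
    else NA_real_
    data.frame(position = i, n_voxels = length(fl), r = r)
  })
  do.call(rbind, rows)
}

#' k-means partition of voxel connectivity profiles
#'
#' Deterministic under a fixed seed and `n_init` restarts; supports
#' k in 1..3 (and beyond).
#'
#' @param profiles voxels x features matrix.
#' @param k number of clusters.
#' @param rng_seed integer seed.
#' @param n_init number of random restarts.
#' @return integer cluster labels (length = rows of `profiles`).
#' @export
kmeans_partition <- function(profiles, k, rng_seed = NULL, n_init = 20) {
  profiles <- as.matrix(profiles)
  assert_that(all(is.finite(profiles)), "profiles must be finite")
  assert_that(k >= 1 && k <= nrow(profiles),
              "k must be between 1 and the number of voxels")
  if (k == 1) return(rep(1L, nrow(profiles)))
  km <- with_seed(rng_seed,
                  stats::kmeans(profiles, centers = k, nstart = n_init,
                                iter.max = 100))
  as.integer(km$cluster)
}

#' Voxel-wise two-sample group difference of connectivity maps
#'
#' Student's t (pooled variance) per voxel on Fisher-z-transformed r
#' values; thresholded at `|t| > 2`. Optionally, a permutation test on the
#' maximum suprathreshold cluster size (6-connectivity, group-label
#' shuffles) provides a family-wise cluster p value.
#'
#' @param mapsA,mapsB lists of [connectivity_map()]s (>= 2 each).
#' @param t_thresh threshold on |t| (default 2).
#' @param fisher apply the Fisher z transform before testing (default TRUE).
#' @param n_perm number of label permutations (0 = skip).
#' @param rng_seed integer seed for the permutations.
#' @return list with `t` (3D array), `mask` (|t| > threshold), `df`,
#'   `mean_diff` (mean z difference A - B), and optionally `cluster_p`.
#' @export
group_diff_map <- function(mapsA, mapsB, t_thresh = 2, fisher = TRUE,
                           n_perm = 0, rng_seed = NULL) {
  assert_that(length(mapsA) >= 2 && length(mapsB) >= 2,
              "need at least two maps per group")
  get_z <- function(m) {
    r <- if (inherits(m, "connectivity_map")) m$r else m
    if (fisher) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) else r
  }
  dims <- dim(get_z(mapsA[[1]]))
  A <- vapply(mapsA, function(m) as.vector(get_z(m)), numeric(prod(dims)))
  B <- vapply(mapsB, function(m) as.vector(get_z(m)), numeric(prod(dims)))
  assert_that(all(vapply(c(mapsA, mapsB), function(m)
    identical(dim(if (inherits(m, "connectivity_map")) m$r else m), dims),
    logical(1))), "maps must share one grid")
  tv <- welch_t_pooled(A, B)
  tmap <- array(tv$t, dims)
  mask <- array(is.finite(tv$t) & abs(tv$t) > t_thresh, dims)
  out <- list(t = tmap, mask = mask, df = tv$df,
              mean_diff = array(tv$diff, dims), t_thresh = t_thresh)
  if (n_perm > 0) {
    obs_max <- max_cluster_size(mask)
    All <- cbind(A, B)
    nA <- ncol(A)
    perm_max <- with_seed(rng_seed, vapply(seq_len(n_perm), function(i) {
      sel <- sample.int(ncol(All), nA)
      tvp <- welch_t_pooled(All[, sel, drop = FALSE],
                            All[, -sel, drop = FALSE])
      max_cluster_size(array(is.finite(tvp$t) & abs(tvp$t) > t_thresh, dims))
    }, numeric(1)))
    out$cluster_p <- (1 + sum(perm_max >= obs_max)) / (1 + n_perm)
    out$max_cluster <- obs_max
  }
  out
}

# Pooled-variance two-sample t, vectorized over rows.
welch_t_pooled <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- matrixStats::rowVars(A); vB <- matrixStats::rowVars(B)
  sp <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[se == 0] <- NA_real_
  list(t = t, df = nA + nB - 2, diff = mA - mB)
}

# Largest 6-connected suprathreshold cluster (breadth-first labelling).
max_cluster_size <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(0L)
  d <- dim(mask)
  flat <- function(m) m[, 1] + d[1] * (m[, 2] - 1) + d[1] * d[2] * (m[, 3] - 1)
  inmask <- logical(prod(d)); inmask[flat(idx)] <- TRUE
  seen <- logical(prod(d))
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  best <- 0L
  for (s in seq_len(nrow(idx))) {
    f0 <- flat(idx[s, , drop = FALSE])
    if (seen[f0]) next
    queue <- idx[s, , drop = FALSE]
    seen[f0] <- TRUE
    size <- 0L
    while (nrow(queue)) {
      v <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (k in 1:6) {
        w <- v + nb[k, ]
        if (any(w < 1) || any(w > d)) next
        fw <- flat(w)
        if (inmask[fw] && !seen[fw]) {
          seen[fw] <- TRUE
          queue <- rbind(queue, w)
        }
      }
    }
    best <- max(best, size)
  }
  best
}

#' Mean value of a map statistic inside a mask
#' @param arr 3D array (e.g. t map or mean-difference map).
#' @param mask voxel mask.
#' @return mean over mask voxels (NA removed).
#' @export
mask_mean <- function(arr, mask) {
  mask <- normalize_mask(mask, dim(arr))
  mean(arr[mask], na.rm = TRUE)
}
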