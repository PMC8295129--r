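# Fidelity metrics (synthetic vs phantom): MAE, SSIM, FSIM, edge
# preservation/generation ratios. Realism metrics (synthetic vs reference
# style): radial NPS + NCC (see nps.R), noise magnitude, histogram
# correlation. SSIM/FSIM are computed per axial slice and averaged, matching
# slice-wise comparison of volumes that share a grid.

as_arr3 <- function(x) {
  if (inherits(x, "modality_volume")) x$intensities
  else if (inherits(x, "organ_label_volume")) x$labels
  else x
}

#' Mean absolute error excluding background
#'
#' @param a,b volumes (same shape).
#' @param background logical array marking background voxels to exclude;
#'   `NULL` uses all voxels.
#' @return Mean of `|a - b|` over non-background voxels.
#' @export
mae <- function(a, b, background = NULL) {
  a <- as_arr3(a); b <- as_arr3(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (is.null(background)) return(mean(abs(a - b)))
  if (!identical(dim(background), dim(a))) stop("mask shape mismatch")
  keep <- !background
  if (!any(keep)) stop("all voxels are background")
  mean(abs(a[keep] - b[keep]))
}

# ---- SSIM ----------------------------------------------------------------

# 2D Gaussian filtering of a matrix via separable band matrices.
filter2_gauss <- function(m, sigma) {
  gx <- gauss_band(nrow(m), sigma)
  gy <- gauss_band(ncol(m), sigma)
  gx %*% m %*% t(gy)
}

ssim_slice <- function(a, b, data_range, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03) {
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_a <- filter2_gauss(a, sigma)
  mu_b <- filter2_gauss(b, sigma)
  va <- filter2_gauss(a * a, sigma) - mu_a^2
  vb <- filter2_gauss(b * b, sigma) - mu_b^2
  cab <- filter2_gauss(a * b, sigma) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * cab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (va + vb + C2)
  mean(num / den)
}

#' Structural similarity index (slice-wise)
#'
#' Standard SSIM with Gaussian weighting (sigma 1.5) and stabilization
#' constants K1 = 0.01, K2 = 0.03, computed per axial slice and averaged
#' over the volume.
#'
#' @param a,b volumes of identical shape.
#' @param data_range intensity range of the data; defaults to 2 for
#'   normalized volumes, else the joint observed range.
#' @return SSIM in \[-1, 1\] (1 for identical volumes).
#' @export
ssim <- function(a, b, data_range = NULL) {
  av <- as_arr3(a); bv <- as_arr3(b)
  if (!identical(dim(av), dim(bv))) stop("shape mismatch")
  if (is.null(data_range)) {
    norm <- inherits(a, "modality_volume") && a$normalized
    data_range <- if (norm) 2 else max(max(av), max(bv)) -
      min(min(av), min(bv))
    if (data_range == 0) data_range <- 1
  }
  mean(vapply(seq_len(dim(av)[3]), function(k)
    ssim_slice(av[, , k], bv[, , k], data_range), numeric(1)))
}

# ---- FSIM ----------------------------------------------------------------

# Log-Gabor phase congruency (single slice). A compact variant of the
# standard multi-scale, multi-orientation construction: 4 scales x 4
# orientations, noise floor from the smallest-scale amplitude median.
phase_congruency <- function(m, nscale = 4, norient = 4,
                             min_wavelength = 6, mult = 2,
                             sigma_onf = 0.55) {
  nr <- nrow(m); nc <- ncol(m)
  M <- stats::fft(m)
  fx <- matrix(rep(fft_freq(nr, 1), nc), nr, nc)
  fy <- matrix(rep(fft_freq(nc, 1), each = nr), nr, nc)
  radius <- sqrt(fx^2 + fy^2); radius[1, 1] <- 1
  theta <- atan2(fy, fx)
  eps <- 1e-4
  pc_sum <- matrix(0, nr, nc)
  for (o in seq_len(norient) - 1) {
    ang <- o * pi / norient
    ds <- sin(theta) * cos(ang) - cos(theta) * sin(ang)
    dc <- cos(theta) * cos(ang) + sin(theta) * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * (pi / norient * 1.2)^2))
    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumA <- matrix(0, nr, nc)
    T0 <- 0
    for (s in seq_len(nscale) - 1) {
      wavelength <- min_wavelength * mult^s
      f0 <- 1 / wavelength
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2))
      lg[1, 1] <- 0
      filt <- lg * spread
      eo <- stats::fft(M * filt, inverse = TRUE) / (nr * nc)
      e <- Re(eo); oo <- Im(eo)
      amp <- sqrt(e^2 + oo^2)
      sumE <- sumE + e; sumO <- sumO + oo; sumA <- sumA + amp
      if (s == 0) T0 <- stats::median(amp) * 1.5
    }
    energy <- sqrt(sumE^2 + sumO^2)
    pc_sum <- pc_sum + pmax(energy - T0, 0) / (sumA + eps)
  }
  pc_sum / norient
}

scharr_gradmag <- function(m) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  gx <- conv2_same(m, kx)
  gy <- conv2_same(m, t(kx))
  sqrt(gx^2 + gy^2)
}

# "same" 2D cross-correlation with edge replication, small kernels only.
conv2_same <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  rk <- (nrow(k) - 1) %/% 2; ck <- (ncol(k) - 1) %/% 2
  ri <- pmin(pmax(seq_len(nr + 2 * rk) - rk, 1), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * ck) - ck, 1), nc)
  mp <- m[ri, ci]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
    out <- out + k[i, j] * mp[i:(i + nr - 1), j:(j + nc - 1)]
  }
  out
}

fsim_slice <- function(a, b) {
  # rescale to a 0..255-like range so the standard constants apply
  lo <- min(a, b); hi <- max(a, b)
  if (hi > lo) {
    a <- (a - lo) / (hi - lo) * 255
    b <- (b - lo) / (hi - lo) * 255
  }
  pc1 <- phase_congruency(a)
  pc2 <- phase_congruency(b)
  g1 <- scharr_gradmag(a)
  g2 <- scharr_gradmag(b)
  T1 <- 0.85; T2 <- 160
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / (sum(pcm) + 1e-12)
}

#' Feature similarity index (slice-wise)
#'
#' Phase-congruency- and gradient-magnitude-based feature similarity,
#' computed per axial slice and averaged. Phase congruency uses a log-Gabor
#' bank (4 scales, 4 orientations); gradients use the Scharr operator.
#'
#' @param a,b volumes of identical shape.
#' @return FSIM in \[0, 1\] (1 for identical volumes).
#' @export
fsim <- function(a, b) {
  av <- as_arr3(a); bv <- as_arr3(b)
  if (!identical(dim(av), dim(bv))) stop("shape mismatch")
  mean(vapply(seq_len(dim(av)[3]), function(k)
    fsim_slice(av[, , k], bv[, , k]), numeric(1)))
}

# ---- Canny edges and edge ratios ----------------------------------------

canny_slice <- function(m, sigma = 1.4, low = 0.1, high = 0.2) {
  ms <- filter2_gauss(m, sigma)
  kx <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3) / 4
  gx <- conv2_same(ms, kx)
  gy <- conv2_same(ms, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  magn <- mag / mx
  ang <- atan2(gy, gx)  # quantize to 4 directions
  sector <- (round(ang / (pi / 4)) %% 4) + 1
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(mm, di, dj) {
    out <- matrix(0, nr, nc)
    ri <- seq_len(nr) + di; ci <- seq_len(nc) + dj
    ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
    out[ok_r, ok_c] <- mm[ri[ok_r], ci[ok_c]]
    out
  }
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  nms <- matrix(FALSE, nr, nc)
  for (sct in 1:4) {
    o <- offs[[sct]]
    n1 <- shift(magn, o[1], o[2]); n2 <- shift(magn, -o[1], -o[2])
    nms <- nms | (sector == sct & magn >= n1 & magn >= n2)
  }
  strong <- nms & magn >= high
  weak <- nms & magn >= low
  # hysteresis: grow strong edges through weak ones
  repeat {
    grown <- strong
    for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      grown <- grown | (weak & shift(strong + 0, o[1], o[2]) > 0)
    }
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}

#' Edge preservation and edge generation ratios
#'
#' Binary Canny edge maps `E_ref` and `E_test` are computed slice-wise with
#' identical parameters, then
#' `EPR = |E_ref & E_test| / |E_ref|` (reference edges retained) and
#' `EGR = |E_test & !E_ref| / |E_ref|` (new edges introduced, relative to
#' the reference edge count; may exceed 1).
#'
#' @param reference,test volumes of identical shape.
#' @param sigma Gaussian pre-smoothing of the Canny detector.
#' @param low,high hysteresis thresholds (fractions of the max gradient).
#' @return Named numeric `c(EPR = ..., EGR = ...)`.
#' @export
edge_ratios <- function(reference, test, sigma = 1.4, low = 0.1,
                        high = 0.2) {
  a <- as_arr3(reference); b <- as_arr3(test)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  n_ref <- 0; n_kept <- 0; n_new <- 0
  for (k in seq_len(dim(a)[3])) {
    er <- canny_slice(a[, , k], sigma, low, high)
    et <- canny_slice(b[, , k], sigma, low, high)
    n_ref <- n_ref + sum(er)
    n_kept <- n_kept + sum(er & et)
    n_new <- n_new + sum(et & !er)
  }
  if (n_ref == 0) stop("reference volume has no edges")
  c(EPR = n_kept / n_ref, EGR = n_new / n_ref)
}

# ---- realism metrics -----------------------------------------------------

#' Noise magnitude over a region
#'
#' Sample standard deviation of the intensities inside a mask (typically
#' the liver, a large and mostly homogeneous organ).
#'
#' @param volume a volume or 3D array.
#' @param mask logical array, nonempty.
#' @return Scalar standard deviation.
#' @export
noise_magnitude <- function(volume, mask) {
  arr <- as_arr3(volume)
  if (!identical(dim(mask), dim(arr))) stop("mask shape mismatch")
  if (!any(mask)) stop("mask is empty")
  stats::sd(arr[mask])
}

#' Histogram correlation coefficient (HistCC)
#'
#' Intensity histograms of the two volumes over a common binning are
#' compared by Pearson correlation of the (count-normalized) bin heights.
#'
#' @param a,b volumes or 3D arrays.
#' @param bins number of bins.
#' @param range common intensity range; defaults to the joint observed
#'   range.
#' @param exclude_background_peak drop the single fullest bin of `a` (and
#'   the same bin of `b`) before correlating, a display-style option for
#'   data dominated by an air peak.
#' @return Pearson correlation in \[-1, 1\].
#' @export
histogram_correlation <- function(a, b, bins = 128, range = NULL,
                                  exclude_background_peak = FALSE) {
  av <- as.vector(as_arr3(a)); bv <- as.vector(as_arr3(b))
  if (is.null(range)) range <- c(min(av, bv), max(av, bv))
  if (range[1] >= range[2]) stop("degenerate intensity range")
  brk <- seq(range[1], range[2], length.out = bins + 1)
  ha <- graphics::hist(pmin(pmax(av, range[1]), range[2]), breaks = brk,
                       plot = FALSE)$counts
  hb <- graphics::hist(pmin(pmax(bv, range[1]), range[2]), breaks = brk,
                       plot = FALSE)$counts
  ha <- ha / sum(ha); hb <- hb / sum(hb)
  if (exclude_background_peak) {
    drop <- which.max(ha)
    ha <- ha[-drop]; hb <- hb[-drop]
  }
  if (sum(ha > 0) <= 1 || sum(hb > 0) <= 1)
    stop("degenerate histogram: a single occupied bin")
  stats::cor(ha, hb)
}

#' Monte-Carlo MAE/NM ratio for Gaussian noise
#'
#' For `X ~ Normal(0, sigma)` the ratio of the mean absolute deviation to
#' the standard deviation converges to `sqrt(2/pi) ~ 0.798` ("about 0.8"),
#' independent of `sigma`. Used as the yardstick for judging how much of a
#' mean absolute error between volumes is attributable to noise alone.
#'
#' @param n_samples Monte-Carlo sample size (>= 1e4).
#' @param sigma noise standard deviation.
#' @param seed integer seed.
#' @return The estimated ratio `E|X| / sd(X)`.
#' @export
mae_nm_gaussian_ratio <- function(n_samples = 1e6, sigma = 1, seed = 1L) {
  stopifnot(n_samples >= 1e4)
  set.seed(as.integer(seed))
  x <- stats::rnorm(n_samples, 0, sigma)
  mean(abs(x)) / stats::sd(x)
}

#' MAE-to-noise-magnitude ratio
#'
#' The bookkeeping step of the report pipeline: how many times larger the
#' mean absolute synthesis error is than the noise magnitude. A ratio well
#' above the Gaussian baseline [mae_nm_gaussian_ratio()] (~0.8) indicates
#' the error cannot be attributed to noise alone.
#'
#' @param mae_value mean absolute error (same units as `nm_value`).
#' @param nm_value noise magnitude.
#' @return `mae_value / nm_value`.
#' @export
mae_nm_ratio <- function(mae_value, nm_value) {
  stopifnot(nm_value > 0)
  mae_value / nm_value
}

#' Reference full-scale image-quality statistics
#'
#' Published mean +- sd image-quality values for a full-scale trained
#' synthesis system (per modality), shipped as a plain-text fixture. Used
#' to exercise the report arithmetic (e.g. MAE/NM ratios) without training.
#'
#' @return `data.frame` with columns `modality`, `metric`, `mean`, `sd`.
#' @export
reference_quality_metrics <- function() {
  path <- system.file("extdata", "reference_quality_metrics.csv",
                      package = "mmsynth")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a Table-style metric report
#'
#' For each modality, computes the fidelity metrics between each synthetic
#' volume and its phantom (MAE excluding background, SSIM, FSIM, EPR, EGR)
#' and the realism metrics between the synthetic set and a reference-style
#' set (NCC of radial liver NPS, NM of both, HistCC), then aggregates
#' mean +- sd over volumes and appends the MAE/NM ratio.
#'
#' @param synthetic,phantom,reference named lists (by modality) of lists of
#'   [modality_volume()]s; `phantom[[m]][[i]]` corresponds to
#'   `synthetic[[m]][[i]]`. `reference` provides style/noise exemplars and
#'   may have a different count.
#' @param masks named list per modality with `background` and `liver`
#'   logical arrays (shared across volumes of that modality).
#' @param nps_patch patch size for [radial_nps()].
#' @return `data.frame`, one row per modality, columns `<metric>_mean` /
#'   `<metric>_sd` plus `mae_nm_ratio`.
#' @export
build_metric_report <- function(synthetic, phantom, reference, masks,
                                nps_patch = 16) {
  stopifnot(identical(names(synthetic), names(phantom)))
  agg <- function(x) c(mean = mean(x), sd = if (length(x) > 1)
    stats::sd(x) else 0)
  rows <- lapply(names(synthetic), function(m) {
    syn <- synthetic[[m]]; pha <- phantom[[m]]; ref <- reference[[m]]
    stopifnot(length(syn) == length(pha))
    bg <- masks[[m]]$background; liver <- masks[[m]]$liver
    per <- function(f) vapply(seq_along(syn), function(i)
      f(syn[[i]], pha[[i]]), numeric(1))
    v_mae <- per(function(s, p) mae(as_arr3(s), as_arr3(p), bg))
    v_ssim <- per(ssim)
    v_fsim <- per(fsim)
    v_edges <- vapply(seq_along(syn), function(i)
      edge_ratios(pha[[i]], syn[[i]]), numeric(2))
    v_nm_syn <- vapply(syn, noise_magnitude, numeric(1), mask = liver)
    v_nm_ref <- vapply(ref, noise_magnitude, numeric(1), mask = liver)
    ref_nps <- radial_nps(ref[[1]], liver, patch_size = nps_patch)
    v_ncc <- vapply(syn, function(s)
      nps_correlation(radial_nps(s, liver, patch_size = nps_patch),
                      ref_nps), numeric(1))
    v_hist <- vapply(seq_along(syn), function(i)
      histogram_correlation(syn[[i]], ref[[min(i, length(ref))]]),
      numeric(1))
    stats <- c(SSIM = agg(v_ssim), FSIM = agg(v_fsim),
               EPR = agg(v_edges[1, ]), EGR = agg(v_edges[2, ]),
               MAE = agg(v_mae), NCC = agg(v_ncc),
               NM_synthetic = agg(v_nm_syn), NM_reference = agg(v_nm_ref),
               HistCC = agg(v_hist))
    names(stats) <- sub("\\.", "_", names(stats))
    out <- as.data.frame(as.list(stats))
    out$mae_nm_ratio <- if (mean(v_nm_syn) > 0)
      mae_nm_ratio(mean(v_mae), mean(v_nm_syn)) else NA_real_
    cbind(data.frame(modality = m), out)
  })
  do.call(rbind, rows)
}

#' Write a metric report
#'
#' @param report a `data.frame` from [build_metric_report()].
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
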