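# Radial noise power spectrum estimation from ROI patches, and the Pearson
# correlation between two radial spectra (NCC). Recipe: 2D axial patches
# fully inside the ROI, second-order polynomial detrending, Hann windowing,
# periodogram averaging, annular radial binning.

#' Estimate the radial noise power spectrum of a ROI
#'
#' Extracts square axial patches fully inside `roi` (typically the liver),
#' detrends each with a second-order 2D polynomial, applies a Hann window,
#' averages the periodograms and bins radially over in-plane spatial
#' frequency. Normalization is such that the integral of the 2D NPS over
#' frequency approximates the noise variance (Parseval, up to windowing).
#'
#' @param volume a [modality_volume()] or 3D array.
#' @param roi logical 3D array; patches are taken where it is all-`TRUE`.
#' @param patch_size patch side length in voxels.
#' @param detrend_order polynomial detrending order (0, 1 or 2).
#' @param spacing in-plane spacing in mm (taken from `volume` if available).
#' @param stride patch stride; defaults to `patch_size %/% 2` (overlapping).
#' @return A list of class `radial_nps` with `frequencies` (cycles/mm),
#'   `power`, `n_patches`, and the 2D spectrum used for binning.
#' @export
radial_nps <- function(volume, roi, patch_size = 16, detrend_order = 2,
                       spacing = NULL, stride = NULL) {
  arr <- if (inherits(volume, "modality_volume")) volume$intensities
  else volume
  if (is.null(spacing))
    spacing <- if (inherits(volume, "modality_volume"))
      volume$spacing[1:2] else c(1, 1)
  spacing <- rep_len(spacing, 2L)
  d <- dim(arr)
  stopifnot(identical(dim(roi)[1:3], d), patch_size >= 4)
  if (is.null(stride)) stride <- max(1L, patch_size %/% 2L)

  P <- proj_residual_matrix(patch_size, detrend_order)
  w <- hann2d(patch_size)
  wnorm <- sum(w^2)
  acc <- matrix(0, patch_size, patch_size)
  n_patches <- 0L

  for (k in seq_len(d[3])) {
    sl <- roi[, , k]
    if (!any(sl)) next
    # integral image for fast all-inside test
    ii <- apply(apply(sl + 0, 2, cumsum), 1, cumsum) # ii[j, i] = sum up to (i, j)
    ii <- t(ii)
    boxsum <- function(i, j) {  # sum of sl[i..i+p-1, j..j+p-1]
      p <- patch_size
      ii[i + p - 1, j + p - 1] -
        (if (i > 1) ii[i - 1, j + p - 1] else 0) -
        (if (j > 1) ii[i + p - 1, j - 1] else 0) +
        (if (i > 1 && j > 1) ii[i - 1, j - 1] else 0)
    }
    is <- seq(1, d[1] - patch_size + 1, by = stride)
    js <- seq(1, d[2] - patch_size + 1, by = stride)
    for (i in is) for (j in js) {
      if (boxsum(i, j) < patch_size^2) next
      p <- arr[i:(i + patch_size - 1), j:(j + patch_size - 1), k]
      r <- matrix(P %*% as.vector(p), patch_size, patch_size)
      spec <- Mod(stats::fft(r * w))^2
      acc <- acc + spec
      n_patches <- n_patches + 1L
    }
  }
  if (n_patches == 0L)
    stop("no fully interior patch fits the ROI; try a smaller `patch_size`")
  # NPS normalization: dx*dy / sum(w^2), periodogram-averaged
  nps2d <- acc / n_patches * prod(spacing) / wnorm

  fx <- fft_freq(patch_size, spacing[1])
  fy <- fft_freq(patch_size, spacing[2])
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  df <- 1 / (patch_size * max(spacing))
  bins <- floor(as.vector(fr) / df + 0.5)
  pw <- tapply(as.vector(nps2d), bins, mean)
  fq <- as.numeric(names(pw)) * df
  ord <- order(fq)
  structure(list(frequencies = fq[ord], power = unname(pw[ord]),
                 n_patches = n_patches, nps2d = nps2d,
                 spacing = spacing, patch_size = patch_size),
            class = "radial_nps")
}

# Residual projector for 2D polynomial detrending of a p x p patch.
proj_residual_matrix <- function(p, order) {
  u <- rep(seq_len(p) - (p + 1) / 2, times = p)
  v <- rep(seq_len(p) - (p + 1) / 2, each = p)
  X <- switch(as.character(order),
              "0" = cbind(1, u * 0)[, 1, drop = FALSE],
              "1" = cbind(1, u, v),
              "2" = cbind(1, u, v, u * v, u^2, v^2),
              stop("detrend_order must be 0, 1 or 2"))
  diag(p * p) - X %*% solve(crossprod(X)) %*% t(X)
}

hann2d <- function(p) {
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(p) - 1) / (p - 1)))
  outer(h, h)
}

#' @export
print.radial_nps <- function(x, ...) {
  cat(sprintf("radial_nps: %d frequency bins from %d patches (%d px)\n",
              length(x$frequencies), x$n_patches, x$patch_size))
  invisible(x)
}

#' NPS correlation coefficient (NCC)
#'
#' Pearson correlation between two radial noise power spectra, after
#' resampling `b` onto `a`'s frequency grid by linear interpolation.
#'
#' @param a,b [radial_nps()] objects (or lists with `frequencies`/`power`).
#' @return Scalar in \[-1, 1\].
#' @export
nps_correlation <- function(a, b) {
  pb <- stats::approx(b$frequencies, b$power, xout = a$frequencies,
                      rule = 2)$y
  if (stats::sd(a$power) == 0 || stats::sd(pb) == 0)
    stop("NPS correlation undefined for a constant spectrum")
  stats::cor(a$power, pb)
}
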