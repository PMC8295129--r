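# Spectrally shaped noise injection. Creates pseudo-"patient" volumes with
# controllable in-plane noise texture so the realism metrics (radial NPS,
# NCC, NM) and the registration harness can be exercised without trained
# networks or clinical data.

# Radial amplitude shapes |H(f)|, f in cycles/mm. The power spectrum of the
# injected noise is proportional to |H|^2.
radial_shape_fun <- function(shape) {
  if (is.function(shape)) return(shape)
  switch(match.arg(shape, c("flat", "lowpass", "ramp")),
         flat = function(f) rep(1, length(f)),
         # Gaussian low-pass, ~MRI-like smooth noise
         lowpass = function(f) exp(-(f / 0.15)^2),
         # band-pass ramp-apodized, ~CT reconstruction-kernel-like texture
         ramp = function(f) f * exp(-(f / 0.25)^2))
}

#' Inject spectrally shaped noise into a volume
#'
#' Adds zero-mean Gaussian noise whose in-plane (axial) power spectrum is
#' proportional to `|radial_shape|^2`, scaled so that the noise standard
#' deviation equals `magnitude` (in the volume's native units). Shaping is
#' performed per axial slice in the Fourier domain, matching the in-plane
#' radial NPS estimated by [radial_nps()].
#'
#' @param volume a [modality_volume()].
#' @param radial_shape `"flat"`, `"lowpass"`, `"ramp"`, or a function of
#'   radial frequency (cycles/mm) returning the amplitude `|H(f)|`.
#' @param magnitude target noise standard deviation (>= 0), native units.
#' @param seed integer seed.
#' @param clamp clip the result back into \[-1, 1\] when the volume is
#'   normalized (default `TRUE`).
#' @return The noisy [modality_volume()].
#' @export
inject_textured_noise <- function(volume, radial_shape = "flat", magnitude,
                                  seed = 1L, clamp = TRUE) {
  stopifnot(inherits(volume, "modality_volume"), magnitude >= 0)
  if (magnitude == 0) return(volume)
  arr <- volume$intensities
  d <- dim(arr)
  set.seed(as.integer(seed))
  noise <- array(stats::rnorm(prod(d)), dim = d)

  hfun <- radial_shape_fun(radial_shape)
  fx <- fft_freq(d[1], volume$spacing[1])
  fy <- fft_freq(d[2], volume$spacing[2])
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  H <- matrix(hfun(as.vector(fr)), d[1], d[2])
  if (all(H == 0)) stop("radial_shape is identically zero")

  shaped <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    s <- stats::fft(stats::fft(noise[, , k]) * H, inverse = TRUE)
    shaped[, , k] <- Re(s) / (d[1] * d[2])
  }
  shaped <- shaped * (magnitude / stats::sd(shaped))
  out <- arr + shaped
  if (clamp && volume$normalized) out <- pmin(pmax(out, -1), 1)
  volume$intensities <- out
  volume
}

# DFT frequency grid in cycles/mm for n samples at spacing dx (mm).
fft_freq <- function(n, dx) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) # like fftfreq
  k / (n * dx)
}
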