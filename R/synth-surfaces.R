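#' Specification of a synthetic calibration surface
#'
#' Calibration textures with controllable spatial correlation, used to
#' validate the scaling estimators: isotropic fractional Brownian (fBm)
#' surfaces with Hurst parameter `H`, and spatially independent uniform
#' noise.  Higher `H` gives smoother realizations, so estimated scaling
#' exponents must increase with `H`.
#'
#' @param kind `"fbm"` or `"iid_noise"`.
#' @param H Hurst parameter in (0, 1); required for `"fbm"`.
#' @param dims Surface `c(rows, cols)`.
#' @param seed RNG seed; identical spec + seed gives an identical surface.
#' @return A `surface_spec` list.
#' @export
surface_spec <- function(kind = c("fbm", "iid_noise"), H = NULL,
                         dims = c(256L, 256L), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(dims) == 2L, all(dims >= 8))
  if (kind == "fbm") {
    if (is.null(H) || !is.finite(H) || H <= 0 || H >= 1) {
      stop_dfa("spec", "fbm requires a Hurst parameter H strictly inside (0, 1)")
    }
  }
  structure(
    list(kind = kind, H = if (kind == "fbm") as.numeric(H) else NULL,
         dims = as.integer(dims), seed = as.integer(seed)),
    class = "surface_spec")
}

#' Generate a calibration surface
#'
#' fBm surfaces are synthesized spectrally: white Gaussian noise is shaped
#' in the Fourier domain by the amplitude filter
#' `|f|^-(H + 1)` (power spectral density proportional to
#' `|f|^(-2(H + 1))`, the isotropic fBm spectrum), transformed back, and
#' the real part rescaled linearly to 0-255.  `iid_noise` draws independent
#' uniform intensities on 0-255.
#'
#' @param spec A [surface_spec()].
#' @return `rows x cols` numeric matrix of intensities in 0-255.
#' @examples
#' rough <- generate_surface(surface_spec("fbm", H = 0.2, dims = c(64, 64), seed = 7))
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  M <- spec$dims[1L]
  N <- spec$dims[2L]
  withr::with_seed(spec$seed, {
    if (spec$kind == "iid_noise") {
      matrix(runif(M * N, 0, 255), M, N)
    } else {
      kx <- (seq_len(M) - 1) / M
      kx[kx > 0.5] <- kx[kx > 0.5] - 1
      ky <- (seq_len(N) - 1) / N
      ky[ky > 0.5] <- ky[ky > 0.5] - 1
      f <- sqrt(outer(kx^2, ky^2, "+"))
      amp <- f^(-(spec$H + 1))
      amp[1L, 1L] <- 0                       # zero-mean field
      noise <- matrix(rnorm(M * N), M, N)
      field <- Re(fft(fft(noise) * amp, inverse = TRUE)) / (M * N)
      rng <- range(field)
      if (rng[2L] > rng[1L]) {
        (field - rng[1L]) / (rng[2L] - rng[1L]) * 255
      } else {
        field * 0
      }
    }
  })
}
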