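#' Convert a raster image to grayscale intensities
#'
#' Collapses an RGB raster to a single intensity channel using the ITU-R
#' BT.601 luma weights `0.299 R + 0.587 G + 0.114 B`.  A matrix (already
#' grayscale) passes through unchanged, an `M x N x 1` array is dropped to a
#' matrix, and an alpha channel (RGBA or gray+alpha) is discarded with a
#' warning.  Intensities are treated as dimensionless; both 0-1 and 0-255
#' conventions are accepted and preserved.
#'
#' @param image A numeric matrix (`M x N`) or array (`M x N x C` with
#'   C in 1, 2, 3, 4).
#' @param weights Length-3 RGB weights; defaults to BT.601 luma.  They are
#'   recorded in [dfa2d()] provenance so alternative conventions can be
#'   compared.
#' @return An `M x N` numeric matrix of intensities.
#' @examples
#' rgb <- array(runif(12), dim = c(2, 2, 3))
#' to_grayscale(rgb)
#' @export
to_grayscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (is.data.frame(image)) {
    image <- as.matrix(image)
  }
  if (is.matrix(image)) {
    if (!is.numeric(image)) stop_dfa("format", "image matrix must be numeric")
    check_finite_matrix(image)
    return(image)
  }
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop_dfa("format", "image must be an M x N matrix or an M x N x C array")
  }
  ch <- dim(image)[3L]
  check_finite_matrix(image)
  as_plane <- function(x) matrix(x, dim(image)[1L], dim(image)[2L])
  if (ch == 1L) {
    return(as_plane(image[, , 1L]))
  }
  if (ch == 2L) {
    warn("dropping alpha channel of gray+alpha image")
    return(as_plane(image[, , 1L]))
  }
  if (ch == 4L) {
    warn("dropping alpha channel of RGBA image")
    image <- image[, , 1:3, drop = FALSE]
    ch <- 3L
  }
  if (ch != 3L) {
    stop_dfa("format", sprintf("unsupported channel count: %d (expected 1, 2, 3 or 4)", ch))
  }
  stopifnot(length(weights) == 3L, all(is.finite(weights)))
  as_plane(image[, , 1L] * weights[1L] + image[, , 2L] * weights[2L] +
             image[, , 3L] * weights[3L])
}
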