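#' Integrate a grayscale image in both directions
#'
#' Builds the integrated surface on which detrending operates: each pixel
#' accumulates the mean-centered intensities of its column prefix and its row
#' prefix,
#' \deqn{y(m,n) = \sum_{i=1}^{m} [B(i,n) - \bar B^c_n]
#'             + \sum_{j=1}^{n} [B(m,j) - \bar B^r_m],}
#' where \eqn{\bar B^c_n} is the mean of the full n-th column and
#' \eqn{\bar B^r_m} the mean of the full m-th row.  This is the 2D analogue
#' of the cumulative mean-centered profile of 1D DFA, applied independently
#' along rows and columns.  The transform is linear and mean-centered, so an
#' affine intensity change `a * B + c` scales the surface exactly by `a`.
#'
#' @param pixels Numeric `M x N` matrix of intensities (a grayscale image).
#' @return Numeric `M x N` matrix, the integrated surface.  Identically zero
#'   for a constant image.
#' @examples
#' integrate_image(matrix(c(1, 5, 3, 7), 2, 2))
#' @seealso [integrate_series()] for the 1D profile, [fluctuation_curve()].
#' @export
integrate_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_dfa("image", "pixels must be a numeric matrix")
  }
  if (nrow(pixels) == 0L || ncol(pixels) == 0L) {
    stop_dfa("image", "image has degenerate dimensions (M or N is zero)")
  }
  check_finite_matrix(pixels)
  col_centered <- sweep(pixels, 2L, colMeans(pixels))
  row_centered <- sweep(pixels, 1L, rowMeans(pixels))
  down <- col_centered
  down[] <- apply(col_centered, 2L, cumsum)
  right <- t(row_centered)
  right[] <- apply(t(row_centered), 2L, cumsum)
  down + t(right)
}

#' Integrate a 1D series (cumulative mean-centered profile)
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length: `cumsum(x - mean(x))`.  The
#'   final value is zero up to rounding.
#' @examples
#' integrate_series(c(1, 2, 3))
#' @export
integrate_series <- function(x) {
  if (length(x) == 0L) stop_dfa("series", "series is empty")
  if (!all(is.finite(x))) stop_dfa("series", "series contains non-finite values")
  cumsum(x - mean(x))
}
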