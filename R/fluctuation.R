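#' Detrended fluctuation of an integrated surface at one scale
#'
#' Root-mean-square detrended fluctuation
#' \deqn{F(s) = \sqrt{\frac{1}{M_s N_s} \sum_{k,l} E_{k,l}},}
#' where \eqn{E_{k,l}} is the mean squared residual of the least-squares
#' plane fit over segment \eqn{(k,l)} of the integrated surface (see
#' [fit_plane()]).
#'
#' @param surface Numeric matrix, an integrated surface from
#'   [integrate_image()].
#' @param s Segment side length (scale), see [segment_grid()].
#' @param relax_min Allow scales down to 2 (testing convenience).
#' @return Scalar `F(s) >= 0`.
#' @export
fluctuation <- function(surface, s, relax_min = FALSE) {
  if (!is.matrix(surface)) stop_dfa("image", "surface must be a numeric matrix")
  grid <- segment_grid(nrow(surface), ncol(surface), s, relax_min = relax_min)
  sqrt(mean(segment_mse(surface, grid)))
}

#' Fluctuation curve of a grayscale image over a scale set
#'
#' Integrates the image once ([integrate_image()]) and evaluates the
#' detrended fluctuation `F(s)` at each requested scale.  Points at
#' different scales are independent, so a subset of scales reproduces the
#' corresponding points exactly.
#'
#' @param pixels Numeric `M x N` matrix (grayscale image), or the output of
#'   [to_grayscale()].
#' @param scales Integer vector of segment side lengths; each must satisfy
#'   the [segment_grid()] bounds for the image's dimensions.
#' @param relax_min Allow scales down to 2.
#' @return A tibble of class `fluctuation_curve` with columns `scale` and
#'   `fluctuation`, sorted by scale.
#' @examples
#' img <- matrix(runif(32 * 32), 32, 32)
#' fluctuation_curve(img, 4:8)
#' @export
fluctuation_curve <- function(pixels, scales, relax_min = FALSE) {
  if (length(scales) == 0L) stop_dfa("config", "empty scale set")
  scales <- sort(unique(as.integer(scales)))
  surface <- integrate_image(pixels)
  f <- purrr::map_dbl(scales, function(s) fluctuation(surface, s, relax_min = relax_min))
  out <- tibble(scale = scales, fluctuation = f)
  class(out) <- c("fluctuation_curve", class(out))
  out
}

#' @method autoplot fluctuation_curve
#' @export
autoplot.fluctuation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "scale s (pixels)", y = "F(s)",
                  title = "Detrended fluctuation function") +
    ggplot2::theme_minimal()
}
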