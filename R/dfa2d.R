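#' Two-dimensional detrended fluctuation analysis of an image
#'
#' The full pipeline: grayscale conversion ([to_grayscale()]), row/column
#' integration ([integrate_image()]), the fluctuation function over the
#' configured scale set ([fluctuation_curve()]), and three log-log slope
#' fits ([fit_scaling_exponent()]):
#' * `alpha1` — short-range exponent, every integer scale in
#'   `alpha1_range` (default 4..11);
#' * `alpha2` — long-range exponent, log-spaced scales in
#'   `[12, min(M/4, N/4)]`;
#' * `alpha`  — global exponent over the union of both scale sets.
#'
#' When fewer than two scales exist above the alpha1 range (small images),
#' `alpha2` and the global `alpha` are omitted with a warning.  Exponents
#' are invariant under affine intensity changes `a * B + c` (the
#' fluctuation scales by `|a|`, shifting `log F` by a constant).  Larger
#' exponents correspond to smoother, more correlated surfaces.
#'
#' @param image Numeric matrix (grayscale) or `M x N x C` array (RGB/RGBA).
#'   A full analysis needs `min(M, N) >= 44` so that the whole 4..11 scale
#'   range is valid.
#' @param config A [dfa_config()].
#' @param id Optional image identifier recorded in provenance.
#' @return A `dfa2d_fit` object; see [tidy.dfa2d_fit()],
#'   [glance.dfa2d_fit()], [autoplot.dfa2d_fit()].
#' @examples
#' img <- generate_surface(surface_spec("fbm", H = 0.5, dims = c(64, 64), seed = 1))
#' fit <- dfa2d(img)
#' tidy(fit)
#' @export
dfa2d <- function(image, config = dfa_config(), id = NULL) {
  config <- as_dfa_config(config)
  gray <- to_grayscale(image, config$grayscale_weights)
  M <- nrow(gray)
  N <- ncol(gray)
  s_max <- floor(min(M, N) / 4)
  if (s_max < config$alpha1_range[2L]) {
    stop_dfa("dimension", sprintf(
      "image %d x %d too small: min(M/4, N/4) = %d but the short-range fit needs scales up to %d",
      M, N, s_max, config$alpha1_range[2L]))
  }
  scales1 <- seq.int(config$alpha1_range[1L], config$alpha1_range[2L])
  scales2 <- log_spaced_scales(config$alpha2_min, s_max, config$scales_per_octave)
  scales <- sort(unique(c(scales1, scales2)))
  curve <- fluctuation_curve(gray, scales, relax_min = config$relax_min_scale)

  if (all(curve$fluctuation <= config$zero_tol)) {
    stop_dfa("degenerate", paste(
      "fluctuation is zero at every scale: the image is constant (or its",
      "integrated surface is planar within every segment), so no scaling exponent exists"))
  }

  fits <- dplyr::bind_rows(
    dplyr::mutate(
      fit_scaling_exponent(curve, scales1[1L], scales1[length(scales1)],
                           zero_tol = config$zero_tol),
      term = "alpha1", .before = 1L))
  if (length(scales2) >= 2L) {
    fits <- dplyr::bind_rows(
      fits,
      dplyr::mutate(
        fit_scaling_exponent(curve, config$alpha2_min, s_max, zero_tol = config$zero_tol),
        term = "alpha2", .before = 1L),
      dplyr::mutate(
        fit_scaling_exponent(curve, scales1[1L], s_max, zero_tol = config$zero_tol),
        term = "alpha", .before = 1L))
  } else {
    warn(sprintf(
      "fewer than 2 scales above %d (min(M/4, N/4) = %d): alpha2 and the global alpha are omitted",
      config$alpha1_range[2L], s_max))
  }

  structure(
    list(exponents = fits,
         curve = curve,
         provenance = list(
           id = id,
           dims = c(M = M, N = N),
           grayscale = sprintf("%.3fR + %.3fG + %.3fB",
                               config$grayscale_weights[1L],
                               config$grayscale_weights[2L],
                               config$grayscale_weights[3L]),
           scales = as.integer(curve$scale),
           s_max = s_max),
         config = config),
    class = "dfa2d_fit")
}

#' @export
print.dfa2d_fit <- function(x, ...) {
  d <- x$provenance$dims
  cat(sprintf("2D DFA fit of a %d x %d image (%d scales, s = %d..%d)\n",
              d[["M"]], d[["N"]], nrow(x$curve),
              min(x$curve$scale), max(x$curve$scale)))
  for (i in seq_len(nrow(x$exponents))) {
    e <- x$exponents[i, ]
    cat(sprintf("  %-6s = %.4f  (s in [%d, %d], %d scales, R^2 = %.4f)\n",
                e$term, e$estimate, e$s_min, e$s_max, e$n_scales, e$r.squared))
  }
  invisible(x)
}

#' Tidy the exponent fits of a 2D DFA
#'
#' @param x A `dfa2d_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted exponent: `term` (`alpha1`,
#'   `alpha2`, `alpha`), `estimate`, `intercept`, `r.squared`, `n_scales`,
#'   `s_min`, `s_max`.
#' @method tidy dfa2d_fit
#' @export
tidy.dfa2d_fit <- function(x, ...) x$exponents

#' One-row summary of a 2D DFA
#'
#' @param x A `dfa2d_fit`.
#' @param ... Unused.
#' @return One-row tibble: `alpha`, `alpha1`, `alpha2` (NA when omitted),
#'   image dimensions and total number of scales evaluated.
#' @method glance dfa2d_fit
#' @export
glance.dfa2d_fit <- function(x, ...) {
  get_est <- function(term) {
    i <- match(term, x$exponents$term)
    if (is.na(i)) NA_real_ else x$exponents$estimate[i]
  }
  tibble(
    alpha = get_est("alpha"), alpha1 = get_est("alpha1"), alpha2 = get_est("alpha2"),
    n_scales = nrow(x$curve),
    rows = unname(x$provenance$dims["M"]), cols = unname(x$provenance$dims["N"]))
}

#' Log-log fluctuation plot with fitted slopes
#'
#' @param object A `dfa2d_fit`.
#' @param ... Unused.
#' @return A ggplot: points `(log10 s, log10 F)` with one fitted line per
#'   exponent range.
#' @method autoplot dfa2d_fit
#' @export
autoplot.dfa2d_fit <- function(object, ...) {
  seg <- dplyr::mutate(
    object$exponents,
    x = log10(.data$s_min), xend = log10(.data$s_max),
    y = (.data$intercept + .data$estimate * log(.data$s_min)) / log(10),
    yend = (.data$intercept + .data$estimate * log(.data$s_max)) / log(10))
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = log10(.data$scale), y = log10(.data$fluctuation))) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend,
                   colour = .data$term),
      inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::labs(x = "log10 s", y = "log10 F(s)", colour = "fit",
                  title = "2D DFA fluctuation function") +
    ggplot2::theme_minimal()
}
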