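#' One-dimensional detrended fluctuation analysis
#'
#' Classical DFA of a time series: integrate the mean-centered series
#' ([integrate_series()]), split the profile into disjoint windows of `n`
#' samples anchored at the start (the trailing remainder is discarded),
#' remove a least-squares line from each window, and form
#' \deqn{F(n) = \sqrt{\frac{1}{n K}\sum_{\mathrm{windows}}\sum_k
#'   [y(k) - y_n(k)]^2}}
#' over the `K` complete windows.  The scaling exponent is the OLS slope of
#' `log F(n)` versus `log n`.  White noise gives an exponent near 0.5,
#' Brownian motion near 1.5; larger exponents mean smoother series.
#'
#' This is the conceptual reference for [dfa2d()]: an image constant along
#' one axis yields the same fluctuations as its 1D profile at matching
#' scales.
#'
#' @param x Numeric series (length >= 16 for a meaningful analysis).
#' @param scales Integer window sizes; default log-spaced 4..`floor(N/4)`.
#' @param relax_min Allow windows down to 2 samples.
#' @return A `dfa1d_fit` with elements `exponent` (one-row fit tibble) and
#'   `curve` (`scale`, `fluctuation`); has `tidy()` and `glance()` methods.
#' @examples
#' fit <- dfa1d(rnorm(1024))
#' glance(fit)
#' @export
dfa1d <- function(x, scales = NULL, relax_min = FALSE) {
  if (length(x) == 0L) stop_dfa("series", "series is empty")
  if (!all(is.finite(x))) stop_dfa("series", "series contains non-finite values")
  N <- length(x)
  s_min <- if (isTRUE(relax_min)) 2L else 4L
  s_max <- N %/% 4L
  if (is.null(scales)) scales <- log_spaced_scales(4L, s_max, 8)
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) == 0L) stop_dfa("config", "empty scale set")
  if (any(scales < s_min) || any(scales > N %/% 1L) || any(N %/% scales < 1L)) {
    stop_dfa("scale", sprintf("window sizes must satisfy %d <= n and allow one full window", s_min))
  }
  profile <- integrate_series(x)
  f <- purrr::map_dbl(scales, function(n) fluctuation_1d(profile, n))
  curve <- tibble(scale = scales, fluctuation = f)
  class(curve) <- c("fluctuation_curve", class(curve))
  if (all(curve$fluctuation <= 1e-12)) {
    stop_dfa("degenerate", "fluctuation is zero at every window size (constant series?)")
  }
  fit <- fit_scaling_exponent(curve, min(scales), max(scales))
  structure(list(exponent = fit, curve = curve, n = N), class = "dfa1d_fit")
}

# F(n) over disjoint complete windows of an integrated profile; linear
# detrend per window via the orthogonal closed form.
fluctuation_1d <- function(profile, n) {
  K <- length(profile) %/% n
  Y <- matrix(profile[seq_len(n * K)], nrow = n)
  w <- seq_len(n) - (n + 1) / 2
  sww <- sum(w^2)
  ss <- colSums(Y^2) - colSums(Y)^2 / n - colSums(Y * w)^2 / sww
  sqrt(sum(pmax(ss, 0)) / (n * K))
}

#' @export
print.dfa1d_fit <- function(x, ...) {
  cat(sprintf("1D DFA fit (N = %d, %d window sizes %d..%d)\n",
              x$n, nrow(x$curve), min(x$curve$scale), max(x$curve$scale)))
  cat(sprintf("  exponent = %.4f  (R^2 = %.4f)\n",
              x$exponent$estimate, x$exponent$r.squared))
  invisible(x)
}

#' @rdname dfa1d
#' @param ... Unused.
#' @method tidy dfa1d_fit
#' @export
tidy.dfa1d_fit <- function(x, ...) dplyr::mutate(x$exponent, term = "alpha", .before = 1L)

#' @rdname dfa1d
#' @method glance dfa1d_fit
#' @export
glance.dfa1d_fit <- function(x, ...) {
  tibble(alpha = x$exponent$estimate, r.squared = x$exponent$r.squared,
         n = x$n, n_scales = x$exponent$n_scales)
}
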