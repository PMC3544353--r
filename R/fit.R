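#' Fit a scaling exponent on the log-log fluctuation curve
#'
#' Ordinary least squares of `log F(s)` on `log s` over the curve points
#' with `s_min <= s <= s_max`, one point per scale with equal weights
#' (natural log internally; the slope is base-invariant).  The slope is the
#' DFA scaling exponent over that range.
#'
#' Fluctuations at or below `zero_tol` are treated as exact zeros: the log
#' is undefined there, so the fit refuses with a degenerate-fluctuation
#' error rather than silently dropping points.
#'
#' @param curve A [fluctuation_curve()] tibble (columns `scale`,
#'   `fluctuation`).
#' @param s_min,s_max Inclusive scale range of the fit.
#' @param zero_tol Fluctuations below this are exact zeros (default 1e-12).
#' @return One-row tibble: `estimate` (the slope), `intercept` (in natural
#'   log units), `r.squared`, `n_scales`, `s_min`, `s_max` (the realized
#'   range).
#' @examples
#' curve <- tibble::tibble(scale = 4:11, fluctuation = (4:11)^0.7)
#' fit_scaling_exponent(curve, 4, 11)  # slope 0.7
#' @export
fit_scaling_exponent <- function(curve, s_min, s_max, zero_tol = 1e-12) {
  stopifnot(all(c("scale", "fluctuation") %in% names(curve)))
  pts <- curve[curve$scale >= s_min & curve$scale <= s_max, ]
  if (any(pts$fluctuation <= zero_tol)) {
    stop_dfa("degenerate", sprintf(
      "fluctuation is zero (<= %g) at %d scale(s) in [%g, %g]; log F is undefined there",
      zero_tol, sum(pts$fluctuation <= zero_tol), s_min, s_max))
  }
  if (nrow(pts) < 2L) {
    stop_dfa("scales", sprintf(
      "fewer than 2 usable scales in [%g, %g] (%d found); cannot fit a slope",
      s_min, s_max, nrow(pts)))
  }
  x <- log(pts$scale)
  y <- log(pts$fluctuation)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  tibble(
    estimate = slope, intercept = intercept, r.squared = r2,
    n_scales = nrow(pts), s_min = min(pts$scale), s_max = max(pts$scale))
}

# Log-spaced integer scales in [lo, hi], about `per_octave` per doubling,
# deduplicated after rounding.  Returns integer(0) when hi < lo.
log_spaced_scales <- function(lo, hi, per_octave = 8) {
  if (hi < lo) return(integer(0))
  if (hi == lo) return(as.integer(lo))
  n <- max(2L, ceiling(log2(hi / lo) * per_octave) + 1L)
  s <- round(exp(seq(log(lo), log(hi), length.out = n)))
  as.integer(unique(pmin(hi, pmax(lo, s))))
}
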