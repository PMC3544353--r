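#' Partition bookkeeping for square segments at one scale
#'
#' An `M x N` surface is partitioned into `floor(M/s) x floor(N/s)` disjoint
#' `s x s` segments anchored at the top-left corner; trailing rows/columns
#' that do not fill a segment are discarded.  Valid scales satisfy
#' `4 <= s <= min(M/4, N/4)` so that each fit has at least 16 pixels and at
#' least 16 segments exist.  `relax_min = TRUE` lowers the bound to
#' `s >= 2`, which is convenient for small cross-check instances; the
#' default keeps the standard bound.
#'
#' @param M,N Surface dimensions (rows, columns).
#' @param s Segment side length in pixels (integer-valued).
#' @param relax_min Allow `s >= 2` instead of `s >= 4`.
#' @return A `segment_grid` list: `s`, `M_s`, `N_s`, `discarded_rows`,
#'   `discarded_cols`.
#' @examples
#' segment_grid(100, 80, 8)
#' @export
segment_grid <- function(M, N, s, relax_min = FALSE) {
  stopifnot(length(M) == 1L, length(N) == 1L, length(s) == 1L)
  if (!is.finite(s) || s != round(s)) {
    stop_dfa("scale", "scale s must be a whole number")
  }
  s <- as.integer(s)
  s_min <- if (isTRUE(relax_min)) 2L else 4L
  s_max <- floor(min(M, N) / 4)
  if (s_max < s_min) {
    stop_dfa("dimension", sprintf(
      "image %d x %d too small: no valid scale (need min(M,N) >= %d)", M, N, 4L * s_min))
  }
  if (s < s_min || s > s_max) {
    stop_dfa("scale", sprintf(
      "scale s = %d outside the valid range [%d, %d] for a %d x %d surface",
      s, s_min, s_max, M, N))
  }
  M_s <- M %/% s
  N_s <- N %/% s
  structure(
    list(s = s, M_s = M_s, N_s = N_s,
         discarded_rows = M - M_s * s, discarded_cols = N - N_s * s),
    class = "segment_grid")
}

#' @export
print.segment_grid <- function(x, ...) {
  cat(sprintf("<segment_grid> s = %d: %d x %d segments (%d rows, %d cols discarded)\n",
              x$s, x$M_s, x$N_s, x$discarded_rows, x$discarded_cols))
  invisible(x)
}

#' Least-squares plane fit over one square segment
#'
#' Fits the additive plane `intercept + row_slope * o + col_slope * p` over
#' local 1-based coordinates `o, p = 1..s` (no cross term: the trend
#' decomposes into a row direction and a column direction, the 2D analogue
#' of first-order detrending in 1D DFA).  The mean squared residual is the
#' per-segment fluctuation contribution
#' \deqn{E = \frac{1}{s^2}\sum_{o,p} [z(o,p) - \hat z(o,p)]^2.}
#'
#' The centered coordinate columns are orthogonal on a square grid, so the
#' coefficients come from closed-form projections rather than a generic
#' solver.
#'
#' @param segment Numeric `s x s` matrix, `s >= 2`.
#' @return One-row tibble: `intercept`, `row_slope`, `col_slope`, `mse`.
#' @examples
#' o <- 1:4
#' fit_plane(outer(3 * o, 4 * o, "+") + 2)  # exact plane -> mse 0
#' @export
fit_plane <- function(segment) {
  if (!is.matrix(segment) || nrow(segment) != ncol(segment) || nrow(segment) < 2L) {
    stop_dfa("segment", "segment must be a square numeric matrix with s >= 2")
  }
  if (!all(is.finite(segment))) stop_dfa("segment", "segment contains non-finite values")
  s <- nrow(segment)
  w <- seq_len(s) - (s + 1) / 2          # centered coordinate
  sww <- s * sum(w^2)                    # total sum of squares of either coordinate
  mu <- mean(segment)
  row_slope <- sum(w * rowSums(segment)) / sww
  col_slope <- sum(w * colSums(segment)) / sww
  intercept <- mu - (row_slope + col_slope) * (s + 1) / 2
  fitted <- intercept + outer(row_slope * seq_len(s), col_slope * seq_len(s), "+")
  tibble(
    intercept = intercept, row_slope = row_slope, col_slope = col_slope,
    mse = mean((segment - fitted)^2))
}

# Segment-wise detrended MSE matrix (M_s x N_s) for an integrated surface at
# scale s, fully vectorized.  The plane coefficients come from the
# orthogonal projections (block sums S1 = sum z, So = sum (o - obar) z,
# Sp = sum (p - pbar) z with Sww = s * sum (o - obar)^2); residuals are then
# formed explicitly and squared, which keeps exactly planar segments at
# machine-epsilon MSE instead of the cancellation noise of the one-pass
# sum-of-squares identity.
segment_mse <- function(surface, grid) {
  s <- grid$s
  Z <- surface[seq_len(grid$M_s * s), seq_len(grid$N_s * s), drop = FALSE]
  rgrp <- rep(seq_len(grid$M_s), each = s)
  cgrp <- rep(seq_len(grid$N_s), each = s)
  w <- seq_len(s) - (s + 1) / 2
  wr <- rep(w, grid$M_s)
  wc <- rep(w, grid$N_s)
  sww <- s * sum(w^2)
  block_sum <- function(X) t(rowsum(t(rowsum(X, rgrp)), cgrp))
  mean_b <- block_sum(Z) / s^2
  slope_r <- block_sum(Z * wr) / sww
  slope_c <- block_sum(t(t(Z) * wc)) / sww
  fitted <- mean_b[rgrp, cgrp, drop = FALSE] +
    slope_r[rgrp, cgrp, drop = FALSE] * wr +
    t(t(slope_c[rgrp, cgrp, drop = FALSE]) * wc)
  block_sum((Z - fitted)^2) / s^2
}
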