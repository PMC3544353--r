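#' Analysis configuration for 2D DFA
#'
#' Bundles the tunable settings of [dfa2d()].  Defaults follow the standard
#' split of the fluctuation curve: the short-range exponent alpha1 is fitted
#' over every integer scale 4..11, the long-range exponent alpha2 over a
#' log-spaced subset of `[12, min(M/4, N/4)]` (about `scales_per_octave`
#' scales per doubling), and the global exponent over the union of both
#' scale sets.
#'
#' @param alpha1_range Integer length-2, inclusive scale range of the
#'   short-range fit (default `c(4, 11)`).
#' @param alpha2_min First scale of the long-range fit (default 12); its
#'   upper bound is always `floor(min(M/4, N/4))`.
#' @param scales_per_octave Density of the log-spaced long-range scale set.
#' @param grayscale_weights RGB luma weights (default BT.601), see
#'   [to_grayscale()].
#' @param relax_min_scale Allow scales down to 2 (testing convenience; the
#'   default enforces `s >= 4`).
#' @param zero_tol Fluctuations below this count as exact zeros.
#' @return A `dfa_config` list.
#' @export
dfa_config <- function(alpha1_range = c(4L, 11L),
                       alpha2_min = 12L,
                       scales_per_octave = 8,
                       grayscale_weights = c(0.299, 0.587, 0.114),
                       relax_min_scale = FALSE,
                       zero_tol = 1e-12) {
  alpha1_range <- as.integer(alpha1_range)
  alpha2_min <- as.integer(alpha2_min)
  stopifnot(length(alpha1_range) == 2L, length(alpha2_min) == 1L,
            length(grayscale_weights) == 3L, all(is.finite(grayscale_weights)),
            scales_per_octave >= 1, zero_tol >= 0)
  if (alpha1_range[1L] > alpha1_range[2L]) {
    stop_dfa("config", "alpha1_range must be ordered (min <= max)")
  }
  if (alpha1_range[2L] >= alpha2_min) {
    stop_dfa("config", "scale ranges must not overlap: max(alpha1_range) < alpha2_min")
  }
  structure(
    list(alpha1_range = alpha1_range,
         alpha2_min = alpha2_min,
         scales_per_octave = as.numeric(scales_per_octave),
         grayscale_weights = as.numeric(grayscale_weights),
         relax_min_scale = isTRUE(relax_min_scale),
         zero_tol = as.numeric(zero_tol)),
    class = "dfa_config")
}

#' Coerce a plain list (e.g. parsed JSON) back into a configuration
#'
#' `dfa_config()` objects serialize to JSON and round-trip through this
#' coercion unchanged, so batch runs can record and replay their settings.
#'
#' @param x A `dfa_config` or a named list of its fields (missing fields
#'   take their defaults).
#' @return A validated `dfa_config`.
#' @export
as_dfa_config <- function(x) {
  if (inherits(x, "dfa_config")) return(x)
  if (!is.list(x)) stop_dfa("config", "cannot interpret configuration")
  defaults <- dfa_config()
  known <- names(defaults)
  bad <- setdiff(names(x), known)
  if (length(bad)) stop_dfa("config", paste("unknown configuration fields:", paste(bad, collapse = ", ")))
  args <- utils::modifyList(unclass(defaults), x[intersect(names(x), known)])
  do.call(dfa_config, args)
}

#' @export
print.dfa_config <- function(x, ...) {
  cat("<dfa_config>\n")
  cat(sprintf("  alpha1 scales : %d..%d (all integers)\n", x$alpha1_range[1], x$alpha1_range[2]))
  cat(sprintf("  alpha2 scales : %d..min(M/4, N/4), ~%g per octave\n", x$alpha2_min, x$scales_per_octave))
  cat(sprintf("  grayscale     : %.3f R + %.3f G + %.3f B\n",
              x$grayscale_weights[1], x$grayscale_weights[2], x$grayscale_weights[3]))
  cat(sprintf("  min scale     : %d\n", if (x$relax_min_scale) 2L else 4L))
  invisible(x)
}
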