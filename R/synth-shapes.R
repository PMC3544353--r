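shape_palette <- list(
  white = c(255, 255, 255), black = c(0, 0, 0),
  red = c(255, 0, 0), green = c(0, 255, 0), blue = c(0, 0, 255))

#' Specification of a tiled-shape benchmark image
#'
#' Describes a synthetic test image: identical shapes (circles, or squares
#' whose diagonal equals the circle diameter, so both size classes are
#' comparable) tiled on a regular grid over a uniform background.  White
#' shapes are drawn on a black background; all other colors on white.  The
#' `"mix"` color assigns red/green/blue to tiles cyclically, in a
#' seed-shuffled order.
#'
#' Full-resolution defaults (a 3072 x 4080 canvas) use a characteristic
#' length of 600 px for the large class and 120 px for the small class,
#' with the tiling pitch at 1.5 times the characteristic length, so the
#' small class packs many more shapes than the large class.  `d` and
#' `pitch` scale linearly with the canvas when other `dims` are given.
#'
#' @param shape `"circle"` or `"square"`.
#' @param color `"white"`, `"black"`, `"red"`, `"green"`, `"blue"` or
#'   `"mix"`.
#' @param size_class `"large"` or `"small"`.
#' @param dims Canvas `c(rows, cols)`; default `c(768, 1020)` (quarter
#'   resolution).
#' @param d Characteristic length in pixels: circle diameter, or square
#'   diagonal.  Default derived from `size_class` and `dims`.
#' @param pitch Tile spacing in pixels (default `1.5 * d`); must be
#'   `>= d`.
#' @param seed Seed for the `"mix"` color order.
#' @return A `shape_spec` list.
#' @export
shape_spec <- function(shape = c("circle", "square"),
                       color = c("white", "black", "red", "green", "blue", "mix"),
                       size_class = c("large", "small"),
                       dims = c(768L, 1020L),
                       d = NULL, pitch = NULL, seed = 1L) {
  shape <- match.arg(shape)
  color <- match.arg(color)
  size_class <- match.arg(size_class)
  stopifnot(length(dims) == 2L, all(dims >= 16))
  sf <- dims[1L] / 3072
  if (is.null(d)) d <- (if (size_class == "large") 600 else 120) * sf
  if (is.null(pitch)) pitch <- 1.5 * d
  if (d <= 0 || pitch < d) stop_dfa("spec", "need 0 < d <= pitch")
  if (pitch > min(dims)) stop_dfa("spec", "pitch exceeds the canvas; no shape fits")
  background <- if (color == "white") "black" else "white"
  structure(
    list(shape = shape, color = color, size_class = size_class,
         dims = as.integer(dims), d = d, pitch = pitch,
         background = background, seed = as.integer(seed)),
    class = "shape_spec")
}

#' Render a tiled-shape image
#'
#' Rasterizes a [shape_spec()]: `floor(rows / pitch) * floor(cols / pitch)`
#' tiles, each holding one shape centered in its cell, with the tiling
#' block centered on the canvas so every shape lies fully inside.  A pixel
#' belongs to a circle when its center is within `d/2` of the tile center,
#' and to a square when `|dy| + |dx| <= d/2`: squares are drawn with their
#' diagonals of length `d` along the image axes, so circle and square share
#' the same `d x d` bounding box and the comparison isolates contour shape.
#' (Orientation matters: the short-range exponent of axis-aligned squares
#' is depressed because their edges coincide with the row/column
#' integration directions.)
#'
#' @param spec A [shape_spec()].
#' @return `rows x cols x 3` numeric array, intensities 0-255.  Identical
#'   spec (including seed) always yields an identical image.
#' @examples
#' img <- generate_shape_image(shape_spec("circle", "red", "small", dims = c(96, 128)))
#' dim(img)
#' @export
generate_shape_image <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  rows <- spec$dims[1L]
  cols <- spec$dims[2L]
  n_r <- floor(rows / spec$pitch)
  n_c <- floor(cols / spec$pitch)
  if (n_r < 1L || n_c < 1L) stop_dfa("spec", "canvas too small for one tile")
  off_r <- (rows - n_r * spec$pitch) / 2
  off_c <- (cols - n_c * spec$pitch) / 2

  if (spec$color == "mix") {
    order <- withr::with_seed(spec$seed, sample(c("red", "green", "blue")))
  }
  bg <- shape_palette[[spec$background]]
  img <- array(0, dim = c(rows, cols, 3L))
  for (ch in 1:3) img[, , ch] <- bg[ch]

  half <- spec$d / 2
  tile <- 0L
  for (a in seq_len(n_r)) {
    for (b in seq_len(n_c)) {
      tile <- tile + 1L
      cy <- off_r + (a - 0.5) * spec$pitch
      cx <- off_c + (b - 0.5) * spec$pitch
      fg_color <- if (spec$color == "mix") order[(tile - 1L) %% 3L + 1L] else spec$color
      fg <- shape_palette[[fg_color]]
      rr <- max(1L, ceiling(cy - half)):min(rows, floor(cy + half))
      cc <- max(1L, ceiling(cx - half)):min(cols, floor(cx + half))
      dy <- rr - cy
      dx <- cc - cx
      mask <- if (spec$shape == "circle") {
        outer(dy^2, dx^2, "+") <= half^2
      } else {
        outer(abs(dy), abs(dx), "+") <= half   # diagonal-d square
      }
      idx <- which(mask, arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      for (ch in 1:3) {
        img[cbind(rr[idx[, 1L]], cc[idx[, 2L]], ch)] <- fg[ch]
      }
    }
  }
  img
}

#' The full factorial suite of benchmark shape images
#'
#' All 24 combinations of shape (circle, square), color (white, black, red,
#' green, blue, mix) and size class (large, small), on a canvas scaled from
#' the full 3072 x 4080 resolution by `scale_factor`.  The default quarter
#' scale (768 x 1020) keeps a full analysis of the suite to well under a
#' minute per image.
#'
#' @param scale_factor Canvas scaling; `scale_factor * c(3072, 4080)` must
#'   be whole numbers divisible by 4.
#' @param seed Seed forwarded to every `"mix"` spec.
#' @return Tibble with columns `shape`, `color`, `size_class` and a
#'   list-column `spec` of [shape_spec()] objects, 24 rows.
#' @export
simulation_suite <- function(scale_factor = 0.25, seed = 1L) {
  dims <- c(3072, 4080) * scale_factor
  if (any(dims != round(dims)) || any(dims %% 4 != 0)) {
    stop_dfa("spec", "scale_factor must give integer canvas dimensions divisible by 4")
  }
  grid <- tidyr::expand_grid(
    shape = c("circle", "square"),
    color = c("white", "black", "red", "green", "blue", "mix"),
    size_class = c("large", "small"))
  dplyr::mutate(grid, spec = purrr::pmap(
    list(.data$shape, .data$color, .data$size_class),
    function(sh, co, si) shape_spec(sh, co, si, dims = as.integer(dims), seed = seed)))
}
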