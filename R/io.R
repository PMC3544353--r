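#' Read a raster image as an intensity matrix or array
#'
#' PNG and TIFF are read natively (8/16-bit integer and floating samples);
#' JPEG is read through the EBImage package when it is installed.  Channel
#' values are returned on the 0-255 scale regardless of bit depth; the
#' exponents are affine-invariant, so the scale convention does not affect
#' the analysis.
#'
#' @param path Image file; format inferred from the extension.
#' @return Numeric matrix (grayscale) or `M x N x C` array.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop_dfa("io", sprintf("cannot read '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path) * 255,
      tif = ,
      tiff = tiff::readTIFF(path) * 255,
      jpg = ,
      jpeg = {
        if (!requireNamespace("EBImage", quietly = TRUE)) {
          stop_dfa("format", "JPEG input needs the EBImage package; convert to PNG/TIFF instead")
        }
        e <- EBImage::imageData(EBImage::readImage(path)) * 255
        # EBImage stores x (columns) first; transpose to rows x cols
        if (length(dim(e)) == 2L) t(e) else aperm(e, c(2L, 1L, 3L))
      },
      stop_dfa("format", sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))),
    error = function(e) {
      if (inherits(e, "dfa2d_error")) rlang::cnd_signal(e)
      stop_dfa("io", sprintf("failed to read '%s': %s", path, conditionMessage(e)))
    })
  img
}

#' Write an intensity matrix or RGB array as PNG
#'
#' @param image Matrix or `M x N x 3` array, intensities 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Analyze one image file
#'
#' Reads the image with [read_raster()] and runs [dfa2d()], recording the
#' file path as the result's identifier.
#'
#' @param path Image file (or a numeric matrix/array, passed through).
#' @param config A [dfa_config()].
#' @return A `dfa2d_fit`.
#' @export
analyze_image <- function(path, config = dfa_config()) {
  if (is.character(path)) {
    dfa2d(read_raster(path), config = config, id = path)
  } else {
    dfa2d(path, config = config)
  }
}

#' Serialize a 2D DFA fit as JSON
#'
#' One self-contained document per image: the fitted exponents with their
#' diagnostics, the full `(s, F(s))` table, and provenance (identifier,
#' dimensions, grayscale convention, scale set).
#'
#' @param fit A `dfa2d_fit`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
result_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dfa2d_fit"))
  doc <- list(
    exponents = fit$exponents,
    curve = as.data.frame(fit$curve),
    provenance = fit$provenance,
    config = unclass(fit$config))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read a batch manifest
#'
#' A manifest is a CSV with columns `path` and `group` (one image per
#' row).  Paths must be unique and group labels non-empty.
#'
#' @param manifest CSV file path, or a data frame with those columns.
#' @return Tibble with columns `path`, `group`.
#' @export
read_manifest <- function(manifest) {
  df <- if (is.character(manifest)) {
    if (!file.exists(manifest)) stop_dfa("io", sprintf("manifest '%s' not found", manifest))
    read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    as.data.frame(manifest)
  }
  if (!all(c("path", "group") %in% names(df))) {
    stop_dfa("input", "manifest needs columns 'path' and 'group'")
  }
  if (nrow(df) == 0L) stop_dfa("input", "manifest is empty")
  if (anyDuplicated(df$path)) stop_dfa("input", "manifest paths must be unique")
  if (any(!nzchar(df$group)) || anyNA(df$group)) stop_dfa("input", "group labels must be non-empty")
  as_tibble(df[c("path", "group")])
}

#' Batch analysis of a grouped image manifest
#'
#' Runs [analyze_image()] on every manifest row, collecting one result row
#' per image (alpha, alpha1, alpha2 and dimensions); a failing image is
#' recorded in its row's `error` column without aborting the rest.  When
#' at least two groups produced a usable alpha1, the groups are compared
#' with [compare_groups()] on alpha1; with a single group the comparison
#' is skipped with a warning.
#'
#' @param manifest CSV path or data frame, see [read_manifest()].
#' @param config A [dfa_config()].
#' @param alpha_level Significance threshold for the comparison.
#' @return A `dfa_batch` list: `results` (tibble with one row per image),
#'   `comparison` (a `dfa_group_comparison` or `NULL`), `n_failed`.
#' @export
run_batch <- function(manifest, config = dfa_config(), alpha_level = 0.05) {
  rows <- read_manifest(manifest)
  results <- purrr::pmap_dfr(rows, function(path, group) {
    out <- tibble(path = path, group = group,
                  alpha = NA_real_, alpha1 = NA_real_, alpha2 = NA_real_,
                  rows = NA_integer_, cols = NA_integer_, error = NA_character_)
    tryCatch({
      g <- glance(analyze_image(path, config = config))
      out$alpha <- g$alpha
      out$alpha1 <- g$alpha1
      out$alpha2 <- g$alpha2
      out$rows <- as.integer(g$rows)
      out$cols <- as.integer(g$cols)
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  ok <- results[!is.na(results$alpha1), ]
  comparison <- NULL
  if (length(unique(ok$group)) >= 2L && nrow(ok) > length(unique(ok$group))) {
    comparison <- compare_groups(ok, alpha1, group, alpha_level = alpha_level)
  } else {
    warn("fewer than 2 groups with usable alpha1: group comparison skipped")
  }
  structure(
    list(results = results, comparison = comparison,
         n_failed = sum(!is.na(results$error))),
    class = "dfa_batch")
}

#' @export
print.dfa_batch <- function(x, ...) {
  cat(sprintf("Batch of %d images (%d failed)\n", nrow(x$results), x$n_failed))
  print(x$results, ...)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
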