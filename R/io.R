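#' Read an image file as a normalised array
#'
#' Reads PNG (always available) or TIFF (if the `tiff` package is
#' installed) into an `H x W x 3` array on the `[0, 1]` scale.  Grayscale
#' images are replicated over channels; an alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric `H x W x 3` array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[[3]] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[[3]] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

#' Write a density map for later use or visualisation
#'
#' The map is stored losslessly as an `.rds` file; optionally a 16-bit PNG
#' visualisation scaled to the map's maximum is written next to it.
#'
#' @param d A [density_map()].
#' @param path Output `.rds` path.
#' @param png_preview Also write `<path>.png`.
#' @export
write_density_map <- function(d, path, png_preview = FALSE) {
  saveRDS(list(values = as_plain_matrix(d),
               resolution_divisor = attr(d, "resolution_divisor")), path)
  if (png_preview) {
    m <- as_plain_matrix(d)
    mx <- max(m, 1e-12)
    png::writePNG(m / mx, paste0(path, ".png"))
  }
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  x <- readRDS(path)
  density_map(x$values, x$resolution_divisor)
}
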