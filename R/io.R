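#' Read a raster image as float planes on the 0--255 scale
#'
#' PNG and TIFF are supported (8- or 16-bit, grayscale or RGB). Grayscale
#' images come back as a numeric matrix; RGB as an `nr x nc x 3` array.
#' 16-bit data are rescaled into \[0, 255\]; an alpha channel, if present, is
#' dropped.
#'
#' @param path image file path.
#' @return numeric matrix or `nr x nc x 3` array on the 0--255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = stop(
      sprintf("JPEG input is not supported ('%s'); convert to PNG or TIFF",
              path), call. = FALSE),
    stop(sprintf("unsupported image format '.%s' for '%s'", ext, path),
         call. = FALSE))
  # readPNG/readTIFF return values in [0, 1] regardless of bit depth
  x <- x * 255
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] >= 3L) x <- x[, , 1:3, drop = FALSE]
    else x <- x[, , 1L]
  }
  x
}

#' Write an image plane (or RGB array) to disk
#'
#' The working-precision values are clipped to \[0, 255\] and rounded to the
#' container's 8-bit depth -- the single lossy step of the pipeline. PNG and
#' TIFF are supported.
#'
#' @param image numeric matrix or `nr x nc x 3` array on the 0--255 scale.
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  x <- clip_to_uint8(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop(sprintf("unsupported output format '.%s' for '%s'", ext, path),
         call. = FALSE))
  invisible(path)
}
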