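#' Grayscale image container
#'
#' A 2D intensity raster normalized to `[0, 1]`, stored as a numeric matrix
#' with rows indexing y (downward) and columns indexing x (rightward),
#' origin at the top-left pixel.
#'
#' @param m Numeric matrix of intensities.
#' @param normalize If `TRUE` (default) and values fall outside `[0, 1]`,
#'   min-max normalize; values already in range are left untouched.
#' @return A `gray_image` matrix.
#' @export
as_gray_image <- function(m, normalize = TRUE) {
  m <- as.matrix(m)
  assert_that(all(is.finite(m)), "image intensities must be finite")
  if (normalize && (min(m) < 0 || max(m) > 1)) m <- norm01(m)
  structure(m, class = c("gray_image", "matrix", "array"))
}

#' Read or write a grayscale image (PNG or TIFF)
#'
#' Single-channel 8-bit PNG or 8/16-bit TIFF; multi-channel files are
#' converted to grayscale by averaging channels. Requires the `png` /
#' `tiff` packages.
#'
#' @param path File path; format chosen by extension.
#' @param img A [as_gray_image()] matrix for writing.
#' @return `read_gray_image()` returns a `gray_image`; `write_gray_image()`
#'   returns `path` invisibly.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = { requireNamespace("png"); png::readPNG(path) },
    tif = , tiff = { requireNamespace("tiff"); tiff::readTIFF(path) },
    stopf("unsupported image extension '%s'", ext))
  if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), mean)
  as_gray_image(m)
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  m <- clamp01(unclass(img))
  switch(ext,
    png = { requireNamespace("png"); png::writePNG(m, path) },
    tif = , tiff = { requireNamespace("tiff")
      tiff::writeTIFF(m, path, bits.per.sample = 16L) },
    stopf("unsupported image extension '%s'", ext))
  invisible(path)
}
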