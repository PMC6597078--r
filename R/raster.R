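#' Read a grayscale microscopy image
#'
#' Reads an 8/16-bit (or float) grayscale TIFF or PNG image into a plain
#' numeric matrix of intensities. Multi-channel images are rejected: the
#' detector operates on single-channel fluorescence data.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A numeric matrix (rows x cols) of non-negative intensities.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) .stop_input("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    .stop_input("unsupported image format '%s' (use TIFF or PNG)", ext)
  )
  if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else {
      .stop_input(
        "multi-channel image (%d channels) not supported; supply a grayscale image",
        dim(img)[3]
      )
    }
  }
  validate_raster(img)
  img
}

#' Write a grayscale image
#'
#' Writes a numeric matrix as a 32-bit float TIFF (any intensity range; used
#' e.g. for voting-map debug output) or as a PNG (values clipped to `[0, 1]`).
#'
#' @param image Numeric matrix.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  validate_raster(image)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(pmin(pmax(image, 0), 1), path)
  } else {
    .stop_input("unsupported image format '%s'", ext)
  }
  invisible(path)
}

#' @keywords internal
validate_raster <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    .stop_input("image must be a numeric matrix")
  }
  if (length(image) == 0L) .stop_input("image is empty")
  if (!all(is.finite(image))) .stop_input("image contains non-finite values")
  invisible(image)
}
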