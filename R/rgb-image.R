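#' Construct an 8-bit RGB image object
#'
#' The raw analytical medium of the package: an integer raster of dimension
#' height x width x 3, channel order fixed as R, G, B, every value in
#' \[0, 255\]. All image-facing functions accept and return this class.
#'
#' @param pixels Numeric or integer array of dimension `c(height, width, 3)`
#'   with values in \[0, 255\]. Values are stored as integers.
#' @return An `rgb_image` object (integer array with class attribute).
#' @examples
#' img <- rgb_image(array(128L, dim = c(4, 4, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be a height x width x 3 array.",
          class = "chromaquant_format_error")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("Channel values must lie in [0, 255] with no missing values.",
          class = "chromaquant_format_error")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("rgb_image", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 channels (R,G,B), 8-bit\n",
              d[1], d[2]))
  invisible(x)
}

#' Load an 8-bit RGB image from disk
#'
#' Reads a PNG, JPEG or TIFF file into an [rgb_image]. An alpha channel, if
#' present, is dropped. Images that are not 8 bits per channel (e.g. 16-bit
#' PNG/TIFF) or that are not colour (grayscale, single channel) are rejected:
#' the downstream calibration maths assumes the camera's native 0-255 scale.
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg` or `.tif`/`.tiff` file.
#' @return An [rgb_image].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("Cannot read image file '%s'.", path),
          class = "chromaquant_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = {
      img <- png::readPNG(path, info = TRUE)
      info <- attr(img, "info")
      if (!is.null(info$bit.depth) && info$bit.depth > 8) {
        abort("16-bit PNG images are not supported; re-export as 8-bit.",
              class = "chromaquant_format_error")
      }
      img
    },
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = {
      img <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(img, "bits.per.sample")
      if (!is.null(bits) && any(bits > 8)) {
        abort("16-bit TIFF images are not supported; re-export as 8-bit.",
              class = "chromaquant_format_error")
      }
      img
    },
    abort(sprintf("Unsupported image format '.%s' (use PNG, JPEG or TIFF).",
                  ext),
          class = "chromaquant_format_error")
  )
  if (length(dim(raw)) == 2L) {
    abort("Grayscale images carry no RGB information; a 3-channel image is required.",
          class = "chromaquant_format_error")
  }
  nch <- dim(raw)[3]
  if (nch == 4L) raw <- raw[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(raw)[3] != 3L) {
    abort(sprintf("Expected 3 colour channels after alpha removal, found %d.",
                  dim(raw)[3]),
          class = "chromaquant_format_error")
  }
  # decoders return [0,1] doubles; map back to the stored 8-bit codes
  rgb_image(array(round(raw * 255), dim = dim(raw)))
}

#' Write an RGB image to a PNG file
#'
#' @param image An [rgb_image].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- unclass(image) / 255
  png::writePNG(arr, target = path)
  invisible(path)
}
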