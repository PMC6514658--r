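#' 8-bit RGB image container
#'
#' Wraps an H x W x 3 integer array (channel order red, green, blue, each value
#' in 0..255) together with a free-text source identifier. This is the raw
#' observation unit consumed by all colour-plane and index computations.
#'
#' @param pixels numeric or integer array of dimension H x W x 3 with values
#'   in `[0, 255]`. Values are rounded to integers.
#' @param source_id character scalar identifying the plot or camera the image
#'   came from.
#' @return An object of class `rgb_image`: the integer pixel array with a
#'   `source_id` attribute.
#' @examples
#' img <- rgb_image(array(c(255, 0, 0), c(1, 1, 3)), "red-pixel")
#' dim(img)
#' @export
rgb_image <- function(pixels, source_id = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array (red, green, blue)", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one pixel", call. = FALSE)
  if (anyNA(pixels)) stop("image contains missing pixel values", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  x <- array(as.integer(round(pixels)), dim = dim(pixels))
  structure(x, source_id = as.character(source_id)[1], class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, source_id = \"%s\"\n",
              d[1], d[2], attr(x, "source_id")))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

assert_rgb_image <- function(img) {
  if (!is_rgb_image(img)) {
    if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)
      return(rgb_image(img))
    stop("expected an `rgb_image` (see rgb_image() / read_rgb_image())",
         call. = FALSE)
  }
  img
}

#' Read an 8-bit RGB image from PNG, JPEG or TIFF
#'
#' Decodes the file with the standard 8-bit decoder for its extension and
#' returns an [rgb_image()]. Images with an alpha channel or a single grey
#' channel are rejected: the index math is defined on plain three-channel RGB.
#'
#' @param path file path ending in .png, .jpg/.jpeg, .tif/.tiff
#'   (case-insensitive).
#' @param source_id identifier stored on the image; defaults to the file name.
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG, JPEG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(raw)) != 3L)
    stop("single-channel (greyscale) images are not supported: ", path,
         call. = FALSE)
  if (dim(raw)[3] == 4L)
    stop("image has an alpha channel; flatten to plain RGB first: ", path,
         call. = FALSE)
  if (dim(raw)[3] != 3L)
    stop("expected 3 channels, found ", dim(raw)[3], ": ", path, call. = FALSE)
  rgb_image(round(raw * 255), source_id = source_id)
}

#' Write an RGB image to PNG
#'
#' @param img an [rgb_image()].
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  img <- assert_rgb_image(img)
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
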