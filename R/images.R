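#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities on the 8-bit scale
#' \[0, 255\]. Rows are image rows (y, increasing downward) and columns are
#' image columns (x, increasing rightward); the pixel at the 0-based
#' coordinate (x = 0, y = 0) is the top-left matrix entry. This matches the
#' orientation of the tube and invasion-spot photographs the package
#' quantifies: the meniscus is at the top of the frame and the settled pellet
#' at the bottom.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @return A `gray_image` object (a classed numeric matrix).
#' @examples
#' img <- gray_image(matrix(0:3 * 80, nrow = 2))
#' image_width(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_validation("a gray_image needs a numeric matrix of pixels")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort_validation("image must have at least one row and one column")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort_validation("image contains non-finite pixel values")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort_validation("pixel values must lie in [0, 255]")
  }
  structure(pixels, class = c("gray_image", class(matrix())))
}

#' @rdname gray_image
#' @param img A `gray_image`.
#' @export
image_width <- function(img) ncol(img)

#' @rdname gray_image
#' @export
image_height <- function(img) nrow(img)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, intensity range [%.1f, %.1f]>\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

#' Convert an image to 8-bit grayscale
#'
#' Collapses an RGB (or RGBA) array to one channel with the Rec. 709 luminance
#' weights 0.2126 R + 0.7152 G + 0.0722 B, the standard colorimetric
#' conversion. Already-grayscale input is passed through unchanged. Values on
#' the unit scale (all pixels within \[0, 1\], as returned by PNG/TIFF
#' readers) are rescaled to \[0, 255\]; out-of-range results are clipped.
#'
#' @param x A numeric matrix (grayscale) or a 3-d array with 2 (gray+alpha),
#'   3 (RGB) or 4 (RGBA) channels in the third dimension. Any alpha channel is
#'   ignored.
#' @return A [gray_image].
#' @examples
#' rgb <- array(c(100, 200, 50) / 255, dim = c(1, 1, 3))
#' as.numeric(to_grayscale(rgb))  # 167.9
#' @export
to_grayscale <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    if (nc %in% c(1L, 2L)) {        # gray (+ alpha)
      g <- x[, , 1L]
    } else if (nc %in% c(3L, 4L)) { # RGB(A)
      g <- 0.2126 * x[, , 1L] + 0.7152 * x[, , 2L] + 0.0722 * x[, , 3L]
    } else {
      abort_validation("unsupported channel count: %d", nc)
    }
    g <- matrix(g, nrow = dim(x)[1L], ncol = dim(x)[2L])
  } else if (is.matrix(x) && is.numeric(x)) {
    g <- x
  } else {
    abort_validation("expected a numeric matrix or a 3-d channel array")
  }
  if (anyNA(g) || any(!is.finite(g))) {
    abort_validation("image contains non-finite values")
  }
  # unit-scale images (from png/tiff readers) go to the 8-bit scale
  if (max(g) <= 1 && min(g) >= 0) g <- g * 255
  gray_image(clip255(g))
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Read an image file as grayscale
#'
#' Reads 8- or 16-bit PNG or TIFF (both decoded to the unit scale by their
#' readers, then rescaled to \[0, 255\]) and converts to grayscale via
#' [to_grayscale()]. JPEG is not supported; no JPEG decoder is available.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) abort_validation("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    abort_validation("unsupported image format '.%s' (PNG or TIFF expected)", ext)
  )
  to_grayscale(raw)
}

#' Write a grayscale image
#'
#' Writes an 8-bit single-channel PNG (or TIFF if the path ends in
#' `.tif`/`.tiff`).
#'
#' @param img A [gray_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  u <- unclass(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(u, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(u, where = path, bits.per.sample = 8L),
    abort_validation("unsupported output format '.%s'", ext)
  )
  invisible(path)
}
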