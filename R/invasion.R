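#' Regions of interest for invasion spots
#'
#' An ROI selects the pixels of the invaded spot. `circle_roi()` takes a
#' center and radius in 0-based pixel coordinates; a pixel belongs to the ROI
#' when the distance from its center to the circle center is at most the
#' radius. `mask_roi()` accepts an arbitrary logical matrix the size of the
#' image.
#'
#' @param cx,cy Circle center (0-based pixel coordinates).
#' @param r Radius in pixels.
#' @return A `spot_roi` object.
#' @export
circle_roi <- function(cx, cy, r) {
  check_scalar(cx, "cx"); check_scalar(cy, "cy")
  check_scalar(r, "r")
  if (r <= 0) abort_validation("ROI radius must be positive")
  structure(list(shape = "circle", cx = cx, cy = cy, r = r),
            class = "spot_roi")
}

#' @rdname circle_roi
#' @param mask Logical matrix, `TRUE` inside the spot.
#' @export
mask_roi <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_validation("mask must be a logical matrix")
  }
  structure(list(shape = "mask", mask = mask), class = "spot_roi")
}

# Realize an ROI as a logical membership matrix for a given image.
roi_mask <- function(roi, img) {
  stopifnot(inherits(roi, "spot_roi"))
  h <- nrow(img); w <- ncol(img)
  if (roi$shape == "mask") {
    if (!all(dim(roi$mask) == c(h, w))) {
      abort_validation("ROI mask dimensions (%d x %d) do not match image (%d x %d)",
                       nrow(roi$mask), ncol(roi$mask), h, w)
    }
    return(roi$mask)
  }
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  (xs - roi$cx)^2 + (ys - roi$cy)^2 <= roi$r^2
}

#' Background-corrected invasion intensity of one spot
#'
#' Computes the invasion statistic for a washed agar-invasion photograph. With
#' \eqn{A_t, I_t} the area and mean gray intensity of the whole image and
#' \eqn{A_s, I_s} those of the invaded spot (the ROI), the background level is
#' \deqn{(A_t I_t - A_s I_s) / (A_t - A_s),}
#' algebraically the mean intensity of the pixels outside the spot. The
#' background-corrected spot intensity is \eqn{I_s} minus this background,
#' clamped at zero: spots fainter than their surroundings score 0 rather than
#' a negative invasion value.
#'
#' @param img A [gray_image] of the washed spot.
#' @param roi A [circle_roi()] or [mask_roi()] strictly inside the image.
#' @return An `invasion_measurement`: list with `area_total`, `mean_total`,
#'   `area_spot`, `mean_spot`, `background`, `raw_corrected` and `corrected`.
#' @examples
#' img <- gray_image(matrix(20, 10, 10))
#' img[3:5, 3:5] <- 120
#' m <- measure_spot(img, mask_roi(unclass(img) == 120))
#' m$corrected  # 100
#' @export
measure_spot <- function(img, roi) {
  stopifnot(inherits(img, "gray_image"))
  inside <- roi_mask(roi, img)
  a_t <- length(img)
  a_s <- sum(inside)
  if (a_s < 1L) abort_validation("ROI selects no pixels")
  if (a_s >= a_t) {
    abort_validation("ROI covers the entire image; no background pixels remain")
  }
  i_t <- mean(img)
  i_s <- mean(img[inside])
  background <- (a_t * i_t - a_s * i_s) / (a_t - a_s)
  raw <- i_s - background
  structure(list(area_total = a_t, mean_total = i_t,
                 area_spot = a_s, mean_spot = i_s,
                 background = background,
                 raw_corrected = raw,
                 corrected = max(0, raw)),
            class = "invasion_measurement")
}

#' @export
print.invasion_measurement <- function(x, ...) {
  cat(sprintf(paste0("<invasion_measurement: spot %d px mean %.2f, ",
                     "background %.2f, corrected %.2f>\n"),
              x$area_spot, x$mean_spot, x$background, x$corrected))
  invisible(x)
}

#' Invasion score across technical replicates
#'
#' The per-strain invasion score is the arithmetic mean of the clamped
#' background-corrected intensities of the replicate spot images (three in
#' the assay protocol).
#'
#' @param measurements A list of `invasion_measurement` objects (or a single
#'   one).
#' @return Mean corrected intensity (gray units).
#' @export
invasion_score <- function(measurements) {
  if (inherits(measurements, "invasion_measurement")) {
    measurements <- list(measurements)
  }
  if (length(measurements) == 0L) {
    abort_validation("at least one invasion measurement required")
  }
  mean(vapply(measurements, function(m) {
    stopifnot(inherits(m, "invasion_measurement"))
    m$corrected
  }, numeric(1)))
}
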