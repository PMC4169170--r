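#' Define a plot-profile line across an image
#'
#' A profile line runs from the meniscus end of the tube (`start`) to the
#' tube-bottom end (`end`), in 0-based real pixel coordinates
#' (x rightward, y downward). Intensities are sampled along it at evenly
#' spaced positions.
#'
#' @param x0,y0 Start point (meniscus end).
#' @param x1,y1 End point (tube bottom end).
#' @param sampling_step_px Spacing between samples in pixels (default 1).
#' @return A `profile_line` object.
#' @export
profile_line <- function(x0, y0, x1, y1, sampling_step_px = 1) {
  for (v in c(x0, y0, x1, y1)) check_scalar(v, "coordinate")
  check_scalar(sampling_step_px, "sampling_step_px")
  if (sampling_step_px <= 0) abort_validation("sampling_step_px must be > 0")
  if (x0 == x1 && y0 == y1) abort_validation("profile line has zero length")
  structure(list(start = c(x = x0, y = y0), end = c(x = x1, y = y1),
                 sampling_step_px = sampling_step_px),
            class = "profile_line")
}

line_length <- function(line) {
  sqrt(sum((line$end - line$start)^2))
}

# Bilinear interpolation of image intensities at real 0-based (x, y).
bilinear_sample <- function(img, x, y) {
  w <- ncol(img); h <- nrow(img)
  # clamp to the valid sampling domain; callers validate endpoints
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); x0[w == 1] <- 0
  y0 <- pmin(floor(y), h - 2); y0[h == 1] <- 0
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  m <- unclass(img)
  idx <- function(yy, xx) m[cbind(yy + 1, xx + 1)]
  (1 - fx) * (1 - fy) * idx(y0, x0) +
    fx     * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy     * idx(y1, x0) +
    fx     * fy       * idx(y1, x1)
}

#' Extract an intensity plot-profile along a line
#'
#' Samples the image with bilinear interpolation at evenly spaced positions
#' from the line's start (meniscus end) to its end (tube bottom), recording
#' the maximum gray intensity along the line. This reproduces the
#' line-profile measurement taken on each tube photograph.
#'
#' @param img A [gray_image].
#' @param line A [profile_line] with both endpoints inside the image.
#' @return An `intensity_profile`: list with `positions` (distances from the
#'   start, starting at 0 and ending at the line length), `values` (sampled
#'   intensities) and `max_gray`.
#' @export
extract_profile <- function(img, line) {
  stopifnot(inherits(img, "gray_image"), inherits(line, "profile_line"))
  w <- ncol(img); h <- nrow(img)
  ends <- rbind(line$start, line$end)
  if (any(ends[, "x"] < 0 | ends[, "x"] > w - 1 |
          ends[, "y"] < 0 | ends[, "y"] > h - 1)) {
    abort_validation("profile line endpoint outside image bounds (%d x %d)", w, h)
  }
  len <- line_length(line)
  n_steps <- max(1L, ceiling(len / line$sampling_step_px))
  pos <- seq(0, len, length.out = n_steps + 1L)
  tt <- pos / len
  xs <- line$start["x"] + tt * (line$end["x"] - line$start["x"])
  ys <- line$start["y"] + tt * (line$end["y"] - line$start["y"])
  vals <- bilinear_sample(img, xs, ys)
  structure(list(positions = pos, values = as.numeric(vals),
                 max_gray = max(vals)),
            class = "intensity_profile")
}

#' Settling ratio from one intensity profile
#'
#' The per-line flocculation statistic: the distance from the meniscus end to
#' the first sampled position whose intensity reaches half of the line's
#' maximum gray, divided by the line length. Dense settled cells image bright,
#' the cleared supernatant dark, so this ratio is the fraction of the tube
#' cleared. For photographs with the opposite contrast set `invert = TRUE`,
#' which reflects intensities about the profile maximum before thresholding.
#'
#' A profile that is zero everywhere carries no signal (no cells visible);
#' the ratio is reported as 0 with a warning.
#'
#' @param profile An `intensity_profile` from [extract_profile()].
#' @param invert Flip contrast polarity before finding the half-max crossing.
#' @return The cleared fraction, a number in \[0, 1\].
#' @examples
#' p <- structure(list(positions = 0:4, values = c(0, 0, 0, 200, 200),
#'                     max_gray = 200), class = "intensity_profile")
#' settling_ratio(p)  # 0.75
#' @export
settling_ratio <- function(profile, invert = FALSE) {
  stopifnot(inherits(profile, "intensity_profile"))
  vals <- profile$values
  if (length(vals) == 0L) abort_validation("empty intensity profile")
  if (invert) vals <- max(vals) - vals
  mx <- max(vals)
  if (mx <= 0) {
    warning("all-zero intensity profile: no cells visible, ratio set to 0",
            call. = FALSE)
    return(0)
  }
  i <- which(vals >= mx / 2)[1L]
  profile$positions[i] / profile$positions[length(profile$positions)]
}

#' Settling score of a tube image
#'
#' Applies [settling_ratio()] to each annotated line (three per image in the
#' assay protocol) and averages the per-line ratios, giving the percentage of
#' the tube cleared at the photographed time point.
#'
#' @param img A [gray_image] of the settled culture tube.
#' @param lines A list of [profile_line] annotations (meniscus to bottom).
#' @param invert Passed to [settling_ratio()].
#' @return A `tube_measurement`: list with `per_line_ratios` and their mean
#'   `ratio`.
#' @export
settling_score <- function(img, lines, invert = FALSE) {
  if (inherits(lines, "profile_line")) lines <- list(lines)
  if (length(lines) == 0L) abort_validation("at least one profile line required")
  ratios <- vapply(lines, function(ln) {
    settling_ratio(extract_profile(img, ln), invert = invert)
  }, numeric(1))
  structure(list(per_line_ratios = ratios, ratio = mean(ratios)),
            class = "tube_measurement")
}

#' @export
print.tube_measurement <- function(x, ...) {
  cat(sprintf("<tube_measurement: ratio %.4f (lines: %s)>\n", x$ratio,
              paste(sprintf("%.4f", x$per_line_ratios), collapse = ", ")))
  invisible(x)
}
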