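#' Specification of a synthetic settling-tube image
#'
#' Describes a tube photograph at a settled time point: a dark cleared
#' supernatant band at the top (the meniscus end) over a bright dense band of
#' settled cells at the bottom, with a known cleared fraction. Used to test
#' the settling quantification by parameter recovery.
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param cleared_fraction Ground-truth fraction of the meniscus-to-bottom
#'   line occupied by cleared supernatant, in \[0, 1\].
#' @param clear_level Intensity of the cleared region (default 30).
#' @param dense_level Intensity of the settled region; must exceed
#'   `clear_level` (default 200).
#' @param boundary_softness_px Width of the linear transition between the two
#'   bands (0 gives a hard step).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed for the noise.
#' @return A `tube_spec` object.
#' @export
tube_spec <- function(width_px = 60, height_px = 400, cleared_fraction,
                      clear_level = 30, dense_level = 200,
                      boundary_softness_px = 0, noise_sd = 0, seed = 1L) {
  check_count(width_px, "width_px"); check_count(height_px, "height_px")
  check_scalar(cleared_fraction, "cleared_fraction", 0, 1)
  check_scalar(clear_level, "clear_level", 0, 255)
  check_scalar(dense_level, "dense_level", 0, 255)
  if (dense_level <= clear_level) {
    abort_validation("dense_level must exceed clear_level")
  }
  check_scalar(boundary_softness_px, "boundary_softness_px", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 cleared_fraction = cleared_fraction,
                 clear_level = clear_level, dense_level = dense_level,
                 boundary_softness_px = boundary_softness_px,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tube_spec")
}

#' Render a synthetic settling-tube image
#'
#' The tube axis is vertical with the dense region at the bottom. The
#' column-averaged vertical profile rises from `clear_level` to `dense_level`,
#' with the half-way point of the transition at the `cleared_fraction` point
#' of the meniscus-to-bottom line (row `cleared_fraction * (height_px - 1)`,
#' since the line spans rows 0 to `height_px - 1`); a settling profile line
#' down the rendered tube therefore recovers `cleared_fraction` exactly, up
#' to one pixel of discretization, for any fraction including 0 and 1.
#' Additive Gaussian noise (clipped to \[0, 255\]) is seeded from the spec,
#' so rendering is reproducible.
#'
#' @param spec A [tube_spec()].
#' @return A [gray_image] of size `height_px` x `width_px`.
#' @export
render_settling_image <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  h <- spec$height_px; w <- spec$width_px
  b <- spec$cleared_fraction * (h - 1)
  s <- spec$boundary_softness_px
  y <- 0:(h - 1)
  frac <- if (s > 0) pmin(pmax((y - (b - s / 2)) / s, 0), 1) else as.numeric(y >= b)
  col_profile <- spec$clear_level + frac * (spec$dense_level - spec$clear_level)
  m <- matrix(col_profile, nrow = h, ncol = w)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    m <- m + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
  }
  gray_image(clip255(m))
}

#' Specification of a synthetic invasion-spot image
#'
#' A disk of known intensity on a uniform background; the noise-free
#' ground-truth corrected intensity is
#' `max(0, spot_level - background_level)`. Disk membership uses the same
#' center-of-pixel rule as [circle_roi()], so an ROI with the same center and
#' radius covers the spot exactly.
#'
#' @param image_width_px,image_height_px Image dimensions.
#' @param background_level Background intensity in \[0, 255\].
#' @param spot_cx,spot_cy Spot center, 0-based pixel coordinates.
#' @param spot_radius_px Spot radius (pixels).
#' @param spot_level Spot intensity in \[0, 255\].
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A `spot_spec` object.
#' @export
spot_spec <- function(image_width_px = 120, image_height_px = 120,
                      background_level = 20, spot_cx = 60, spot_cy = 60,
                      spot_radius_px = 25, spot_level = 120,
                      noise_sd = 0, seed = 1L) {
  check_count(image_width_px, "image_width_px")
  check_count(image_height_px, "image_height_px")
  check_scalar(background_level, "background_level", 0, 255)
  check_scalar(spot_level, "spot_level", 0, 255)
  check_scalar(spot_radius_px, "spot_radius_px")
  if (spot_radius_px <= 0) abort_validation("spot_radius_px must be positive")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (spot_cx - spot_radius_px < 0 || spot_cx + spot_radius_px > image_width_px - 1 ||
      spot_cy - spot_radius_px < 0 || spot_cy + spot_radius_px > image_height_px - 1) {
    abort_validation("spot extends outside the image bounds")
  }
  structure(list(image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 background_level = background_level,
                 spot_cx = spot_cx, spot_cy = spot_cy,
                 spot_radius_px = spot_radius_px, spot_level = spot_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spot_spec")
}

#' Render a synthetic invasion-spot image
#'
#' @param spec A [spot_spec()].
#' @return A list with `image` (a [gray_image]) and `truth`, the noise-free
#'   ground-truth corrected intensity `max(0, spot_level - background_level)`.
#' @export
render_invasion_image <- function(spec) {
  stopifnot(inherits(spec, "spot_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  inside <- (xs - spec$spot_cx)^2 + (ys - spec$spot_cy)^2 <= spec$spot_radius_px^2
  m <- matrix(spec$background_level, h, w)
  m[inside] <- spec$spot_level
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    m <- m + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
  }
  list(image = gray_image(clip255(m)),
       truth = max(0, spec$spot_level - spec$background_level))
}
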