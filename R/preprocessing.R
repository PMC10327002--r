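#' Preprocessing configuration
#'
#' Optional per-channel noise reduction (rolling-ball background subtraction
#' followed by a Gaussian blur) and brightness normalization, applied after
#' RGB conversion and before thresholding. Both stages are off by default:
#' they alter pixel statistics and should be applied with caution.
#'
#' @param noise_reduction apply [subtract_background()] then
#'   [gaussian_blur()]?
#' @param rolling_ball_radius background-estimation radius in pixels. The
#'   default (50 px) is far larger than a typical punctum diameter, so puncta
#'   survive subtraction.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param brightness_norm apply [normalize_brightness()]?
#' @param saturated_fraction target fraction of saturated pixels for
#'   brightness normalization, in `[0, 1)`. The default 0.0035 mirrors the
#'   common enhance-contrast convention.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(noise_reduction = FALSE,
                              rolling_ball_radius = 50,
                              blur_sigma = 1.0,
                              brightness_norm = FALSE,
                              saturated_fraction = 0.0035) {
  if (rolling_ball_radius <= 0) stop("rolling_ball_radius must be > 0",
                                     call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (saturated_fraction < 0 || saturated_fraction >= 1)
    stop("saturated_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(noise_reduction = isTRUE(noise_reduction),
                 rolling_ball_radius = rolling_ball_radius,
                 blur_sigma = blur_sigma,
                 brightness_norm = isTRUE(brightness_norm),
                 saturated_fraction = saturated_fraction),
            class = "preprocess_config")
}

#' Rolling-ball style background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening of
#' the plane with a flat disc of the given radius (the flat-disc analogue of
#' the classic rolling-ball estimate: the largest image not exceeding the
#' input anywhere that contains no feature smaller than the disc), and
#' subtracts it. Objects smaller than the disc — puncta — survive with their
#' local contrast; smooth haze and constant offsets are removed. The output
#' never exceeds the input pixelwise, and a spatially constant plane maps to
#' zero.
#'
#' @param plane 8-bit intensity matrix.
#' @param radius structuring-disc radius in pixels.
#' @return background-subtracted plane (integer matrix, 0--255).
#' @export
subtract_background <- function(plane, radius = 50) {
  stopifnot_plane(plane)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (radius >= min(dim(plane)))
    warning("background radius (", radius, " px) is not smaller than the ",
            "image (", nrow(plane), "x", ncol(plane),
            "); proceeding, but the background estimate is degenerate",
            call. = FALSE)
  size <- 2L * as.integer(radius) + 1L
  size <- min(size, 2L * min(dim(plane)) - 1L)
  if (size %% 2L == 0L) size <- size - 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  bg <- EBImage::opening(plane / 255, brush) * 255
  out <- clip255(round_half_up(plane - bg))
  as_plane_int(out)
}

#' Gaussian blur
#'
#' Standard 2D Gaussian convolution (replicated-edge boundary); `sigma = 0`
#' is the identity. Total intensity is conserved up to rounding for signals
#' supported away from the border.
#'
#' @param plane 8-bit intensity matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred plane (integer matrix, 0--255).
#' @export
gaussian_blur <- function(plane, sigma = 1.0) {
  stopifnot_plane(plane)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(as_plane_int(plane))
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- min(dim(plane))
  if (cap %% 2L == 0L) cap <- cap - 1L
  radius <- min(radius, cap)  # kernel cannot exceed the image
  out <- EBImage::gblur(plane, sigma = sigma, radius = radius,
                        boundary = "replicate")
  as_plane_int(clip255(round_half_up(out)))
}

#' Brightness normalization to a fixed saturated fraction
#'
#' Linearly rescales the plane so the `(1 - saturated_fraction)` intensity
#' quantile maps to 255 and the minimum maps to 0, clipping above. After the
#' operation at least `saturated_fraction` of pixels sit at 255 (intensity
#' ties can push the realized fraction higher). Applying the same fraction
#' across a dataset equalizes the percentage of saturated pixels between
#' images. A constant plane has no dynamic range and is returned unchanged
#' with a warning.
#'
#' @param plane 8-bit intensity matrix.
#' @param saturated_fraction fraction in `[0, 1)`; 0 gives a pure min--max
#'   stretch.
#' @return rescaled plane (integer matrix, 0--255).
#' @export
normalize_brightness <- function(plane, saturated_fraction = 0.0035) {
  stopifnot_plane(plane)
  if (saturated_fraction < 0 || saturated_fraction >= 1)
    stop("saturated_fraction must lie in [0, 1)", call. = FALSE)
  lo <- min(plane)
  if (lo == max(plane)) {
    warning("constant plane has no dynamic range; returned unchanged",
            call. = FALSE)
    return(as_plane_int(plane))
  }
  # type-1 (inverse ECDF) quantile: the smallest intensity with at least
  # (1 - f) of the mass at or below it, so >= f of pixels land at 255
  hi <- quantile(plane, probs = 1 - saturated_fraction, type = 1, names = FALSE)
  if (hi <= lo) hi <- max(plane)
  out <- clip255(round_half_up((plane - lo) / (hi - lo) * 255))
  as_plane_int(out)
}

#' Apply a preprocessing configuration to one plane
#'
#' Fixed stage order: background subtraction, then Gaussian blur, then
#' (optionally) brightness normalization. The applied configuration should be
#' logged with the run so analyses are replayable.
#'
#' @param plane 8-bit intensity matrix.
#' @param config a [preprocess_config()].
#' @return processed plane.
#' @export
preprocess_plane <- function(plane, config = preprocess_config()) {
  if (config$noise_reduction) {
    plane <- subtract_background(plane, config$rolling_ball_radius)
    plane <- gaussian_blur(plane, config$blur_sigma)
  }
  if (config$brightness_norm)
    plane <- normalize_brightness(plane, config$saturated_fraction)
  as_plane_int(plane)
}
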