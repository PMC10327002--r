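#' Channel-to-role mapping for RGB conversion
#'
#' Declares which input channel index supplies each colour role. Red and green
#' must always be assigned (they carry the pre- and post-synaptic markers);
#' blue is optional and used only for triple colocalization.
#'
#' @param red,green input channel indices (1-based) for the red and green
#'   roles.
#' @param blue optional input channel index for the blue role, or `NULL`.
#' @param mode `"two-channel"`, `"three-channel"` or `"pick-channels"`.
#'   Defaults to two- or three-channel depending on whether `blue` is given.
#' @return an object of class `channel_mapping`.
#' @examples
#' channel_mapping(red = 1, green = 2)
#' channel_mapping(red = 3, green = 1, blue = 2, mode = "pick-channels")
#' @export
channel_mapping <- function(red = 1L, green = 2L, blue = NULL, mode = NULL) {
  idx <- c(red = as.integer(red), green = as.integer(green),
           blue = if (is.null(blue)) NA_integer_ else as.integer(blue))
  if (anyNA(idx[c("red", "green")]))
    stop("red and green roles must both be assigned", call. = FALSE)
  assigned <- idx[!is.na(idx)]
  if (anyDuplicated(assigned))
    stop("each input channel may serve at most one role", call. = FALSE)
  if (is.null(mode))
    mode <- if (is.na(idx[["blue"]])) "two-channel" else "three-channel"
  mode <- match.arg(mode, c("two-channel", "three-channel", "pick-channels"))
  structure(list(index = idx, mode = mode), class = "channel_mapping")
}

# Strip the extension from a file name, enforcing the one-dot naming rule.
image_name_from_path <- function(path) {
  base <- basename(path)
  ndots <- lengths(regmatches(base, gregexpr(".", base, fixed = TRUE)))
  if (ndots > 1L)
    stop("invalid image file name '", base, "': image names must contain ",
         "only one '.' character (the one preceding the file extension); ",
         "rename files like 'image1.lif.tif' before analysis", call. = FALSE)
  sub("\\.[^.]*$", "", base)
}

# Normalise one page as read by tiff/png into an h x w x c numeric array of
# raw (unscaled) intensities.
page_to_array <- function(page) {
  if (is.matrix(page)) page <- array(page, c(dim(page), 1L))
  page
}

#' Load a raster image file
#'
#' Reads a single- or multi-page TIFF (8- or 16-bit, any channel count) or an
#' 8-bit PNG. Multi-page files are returned as a z-stack; single-page files as
#' a single multi-channel image. The native bit depth is preserved at this
#' stage; conversion to the canonical 8-bit RGB representation is done by
#' [to_rgb()].
#'
#' The image name is the file name up to the extension dot. File names with
#' more than one `"."` are rejected: the dot separates name from extension,
#' and names such as `image1.lif.tif` (left behind by format converters)
#' break that rule.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return an object of class `zstack` (fields `name`, `n_planes`, `planes`,
#'   `bits`) for multi-page files, or of class `mc_image` (fields `name`,
#'   `data`, `bits`) for single-page files.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop("image file not found: '", path, "'", call. = FALSE)
  name <- image_name_from_path(path)
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (ext %in% c("tif", "tiff")) {
    # read normalized to [0, 1] and rescale by the nominal range: exact for
    # every photometric layout, unlike raw reads which depend on it
    read_quiet <- function(...) withCallingHandlers(
      tiff::readTIFF(...),
      warning = function(w) {
        if (grepl("ExtraSamples|Photometric", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    pages <- tryCatch(read_quiet(path, all = TRUE),
                      error = function(e)
                        stop("unreadable or corrupt image file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
    info <- read_quiet(path, payload = FALSE)
    bits <- as.integer(info$bits.per.sample[[1]])
    pages <- lapply(pages, function(p)
      page_to_array(round_half_up(p * (2^bits - 1))))
  } else if (ext == "png") {
    page <- tryCatch(png::readPNG(path),
                     error = function(e)
                       stop("unreadable or corrupt image file '", path,
                            "': ", conditionMessage(e), call. = FALSE))
    bits <- 8L
    pages <- list(page_to_array(round_half_up(page * 255)))
  } else {
    stop("unsupported image format '.", ext, "' for '", path,
         "'; convert to TIFF or PNG first", call. = FALSE)
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("pages of '", path, "' differ in shape or channel count",
         call. = FALSE)
  if (length(pages) > 1L) {
    structure(list(name = name, n_planes = length(pages), planes = pages,
                   bits = bits, z_step = NULL),
              class = "zstack")
  } else {
    structure(list(name = name, data = pages[[1]], bits = bits,
                   projection_index = NULL),
              class = "mc_image")
  }
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<zstack> '%s': %d planes of %dx%d px, %d channel(s), %d-bit\n",
              x$name, x$n_planes, d[2], d[1], d[3], x$bits))
  invisible(x)
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mc_image> '%s': %dx%d px, %d channel(s), %d-bit\n",
              x$name, d[2], d[1], d[3], x$bits))
  invisible(x)
}

#' Construct the canonical 8-bit RGB analysis image
#'
#' @param name image identifier (no `"."` allowed).
#' @param red,green,blue integer matrices of identical shape with values in
#'   0--255; missing roles may be `NULL` and become all-zero planes.
#' @param pixel_size optional pixel size in micrometres per pixel.
#' @param projection_index optional index recording which projection of a
#'   z-stack this image is.
#' @return an object of class `rgb_image` with fields `name`, `width`,
#'   `height`, `planes` (list `red`/`green`/`blue`), `pixel_size`,
#'   `projection_index`.
#' @export
rgb_image <- function(name, red, green, blue = NULL, pixel_size = NULL,
                      projection_index = NULL) {
  if (grepl(".", name, fixed = TRUE))
    stop("image name must not contain '.': '", name, "'", call. = FALSE)
  if (is.null(red) || is.null(green))
    stop("red and green planes are required", call. = FALSE)
  if (is.null(blue)) blue <- matrix(0L, nrow(red), ncol(red))
  planes <- list(red = red, green = green, blue = blue)
  dims <- vapply(planes, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("all three planes must share the same shape", call. = FALSE)
  for (p in planes) {
    stopifnot_plane(p)
    if (any(p != floor(p)))
      stop("plane intensities must be integers", call. = FALSE)
  }
  planes <- lapply(planes, as_plane_int)
  structure(list(name = name, width = ncol(red), height = nrow(red),
                 planes = planes, pixel_size = pixel_size,
                 projection_index = projection_index),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> '%s': %dx%d px%s\n", x$name, x$width, x$height,
              if (is.null(x$projection_index)) ""
              else sprintf(" (projection %d)", x$projection_index)))
  invisible(x)
}

#' Convert a loaded image to the 8-bit RGB analysis representation
#'
#' Each assigned channel is rescaled from its native bit depth to 8 bits by
#' `round(v / (2^bits - 1) * 255)` with round-half-up — a fixed nominal-range
#' transfer so the conversion is data-independent and reproducible
#' (per-image contrast stretching is available separately through
#' [normalize_brightness()]). Unassigned roles become all-zero planes.
#'
#' @param image an `mc_image` from [load_image()] (or one element of
#'   [grouped_max_projection()] output).
#' @param mapping a [channel_mapping()].
#' @return an [rgb_image()].
#' @examples
#' img <- structure(list(name = "im", data = array(32768, c(4, 4, 2)),
#'                       bits = 16L, projection_index = NULL),
#'                  class = "mc_image")
#' to_rgb(img, channel_mapping(1, 2))$planes$red[1, 1]  # 128
#' @export
to_rgb <- function(image, mapping = channel_mapping()) {
  if (!inherits(image, "mc_image"))
    stop("to_rgb() expects an 'mc_image'; project z-stacks first with ",
         "grouped_max_projection()", call. = FALSE)
  nchan <- dim(image$data)[3]
  scale <- 255 / (2^image$bits - 1)
  take <- function(role) {
    i <- mapping$index[[role]]
    if (is.na(i)) return(NULL)
    if (i < 1L || i > nchan)
      stop("channel mapping assigns ", role, " to input channel ", i,
           " but the image has only ", nchan, " channel(s)", call. = FALSE)
    as_plane_int(clip255(round_half_up(image$data[, , i] * scale)))
  }
  blue <- take("blue")
  rgb_image(image$name, take("red"), take("green"), blue,
            projection_index = image$projection_index)
}

#' Grouped maximum-intensity projection of a z-stack
#'
#' Partitions the optical sections, in acquisition order, into consecutive
#' groups of `group_size` planes and collapses each group to its per-pixel,
#' per-channel maximum. A 15-plane confocal stack with `group_size = 3`
#' therefore yields 5 max-projections. Trailing planes that do not fill a
#' complete group are dropped with a warning, since a partial projection
#' would have a different effective depth. `group_size = 1` returns each
#' plane unchanged.
#'
#' @param stack a `zstack` from [load_image()].
#' @param group_size number of consecutive optical planes per projection.
#' @return list of `mc_image` objects, each carrying its
#'   `projection_index` (1-based).
#' @export
grouped_max_projection <- function(stack, group_size = 3L) {
  if (!inherits(stack, "zstack")) {
    if (inherits(stack, "mc_image")) {
      stack <- structure(list(name = stack$name, n_planes = 1L,
                              planes = list(stack$data), bits = stack$bits,
                              z_step = NULL), class = "zstack")
    } else stop("expected a 'zstack'", call. = FALSE)
  }
  group_size <- as.integer(group_size)
  if (is.na(group_size) || group_size < 1L)
    stop("group_size must be a positive integer", call. = FALSE)
  n_out <- stack$n_planes %/% group_size
  dropped <- stack$n_planes - n_out * group_size
  if (dropped > 0L)
    warning(dropped, " trailing plane(s) of '", stack$name,
            "' do not fill a complete group of ", group_size,
            " and were dropped", call. = FALSE)
  if (n_out == 0L) return(list())
  lapply(seq_len(n_out), function(k) {
    idx <- ((k - 1L) * group_size + 1L):(k * group_size)
    proj <- Reduce(pmax, stack$planes[idx])
    structure(list(name = stack$name, data = proj, bits = stack$bits,
                   projection_index = k),
              class = "mc_image")
  })
}

#' Write an RGB analysis image to a PNG file
#'
#' @param image an [rgb_image()].
#' @param path output file path (`.png`).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  arr <- array(0, c(image$height, image$width, 3L))
  arr[, , 1] <- image$planes$red / 255
  arr[, , 2] <- image$planes$green / 255
  arr[, , 3] <- image$planes$blue / 255
  png::writePNG(arr, path)
  invisible(path)
}
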