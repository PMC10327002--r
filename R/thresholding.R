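#' Threshold audit records
#'
#' Every mask-producing thresholding call attaches a `threshold_record`
#' attribute to the returned mask: the image, channel, method and (for value
#' methods) the intensity cutoff. [run_experiment()] collects these records
#' into a `thresholds.csv` audit table whose value rows can be fed back
#' through [thresholds_from_file()] to reproduce an analysis exactly.
#'
#' @param image_name image identifier.
#' @param channel channel role (`"red"`, `"green"`, `"blue"`).
#' @param method one of `"fixed"`, `"from_file"`, `"synquant"`,
#'   `"external_mask"`.
#' @param value intensity threshold in 0--255, or `NA` for methods that do
#'   not use a single cutoff.
#' @return a one-row data frame with columns `image`, `channel`, `method`,
#'   `value`.
#' @export
threshold_record <- function(image_name, channel, method, value = NA_real_) {
  method <- match.arg(method,
                      c("fixed", "from_file", "synquant", "external_mask"))
  has_value <- method %in% c("fixed", "from_file")
  if (has_value && is.na(value))
    stop("method '", method, "' requires a threshold value", call. = FALSE)
  if (!has_value) value <- NA_real_
  data.frame(image = image_name, channel = channel, method = method,
             value = value, stringsAsFactors = FALSE)
}

mask_with_record <- function(mask, record) {
  attr(mask, "threshold_record") <- record
  mask
}

#' Fixed-value intensity threshold
#'
#' Foreground is every pixel with intensity greater than or equal to the
#' cutoff (inclusive lower bound, the ImageJ-style pass-above convention).
#' Raising the value never adds foreground pixels.
#'
#' @param plane 8-bit intensity matrix.
#' @param value cutoff in 0--255.
#' @param image_name,channel identifiers recorded in the threshold audit
#'   record attached to the mask.
#' @return logical foreground mask with a `threshold_record` attribute.
#' @export
fixed_threshold <- function(plane, value, image_name = "image",
                            channel = "red") {
  stopifnot_plane(plane)
  if (value < 0 || value > 255) stop("threshold value must lie in [0, 255]",
                                     call. = FALSE)
  mask <- plane >= value
  mask_with_record(mask,
                   threshold_record(image_name, channel, "fixed", value))
}

#' Read a per-image threshold table
#'
#' Reads the CSV schema `image,channel,value` (the `method` column emitted by
#' the audit log is accepted and ignored). Used by the from-file thresholding
#' method: supplying the `thresholds.csv` written by a previous run
#' reproduces that run's masks, and hence its counts, exactly.
#'
#' @param csv_path path to the CSV file.
#' @return data frame with columns `image`, `channel`, `value`.
#' @export
thresholds_from_file <- function(csv_path) {
  tbl <- read.csv(csv_path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("image", "channel", "value")
  if (!all(need %in% names(tbl)))
    stop("threshold file '", csv_path, "' must have columns image, channel, ",
         "value", call. = FALSE)
  tbl <- tbl[, intersect(c(need, "method"), names(tbl))]
  key <- paste(tbl$image, tbl$channel, sep = "\r")
  if (anyDuplicated(key))
    stop("threshold file '", csv_path, "' has duplicate (image, channel) ",
         "pairs: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  tbl
}

#' Check a threshold table covers an image/channel set
#'
#' @param table data frame from [thresholds_from_file()].
#' @param images character vector of image names to be analyzed.
#' @param channels character vector of channel roles in use.
#' @return the table, invisibly; errors listing every missing pair otherwise.
#' @export
validate_threshold_table <- function(table, images, channels) {
  want <- expand.grid(image = images, channel = channels,
                      stringsAsFactors = FALSE)
  have <- paste(table$image, table$channel, sep = "\r")
  missing <- !(paste(want$image, want$channel, sep = "\r") %in% have)
  if (any(missing))
    stop("threshold table is missing ",
         sum(missing), " (image, channel) pair(s): ",
         paste(paste0(want$image[missing], "/", want$channel[missing]),
               collapse = ", "), call. = FALSE)
  invisible(table)
}

#' Look up and apply a from-file threshold
#'
#' @param plane 8-bit intensity matrix.
#' @param table data frame from [thresholds_from_file()].
#' @param image_name,channel the pair to look up.
#' @return logical mask with a `threshold_record` (method `"from_file"`).
#' @export
apply_threshold_file <- function(plane, table, image_name, channel) {
  hit <- table$image == image_name & table$channel == channel
  if (sum(hit) != 1L)
    stop("threshold table has no entry for (", image_name, ", ", channel,
         ")", call. = FALSE)
  value <- table$value[hit]
  mask <- plane >= value
  mask_with_record(mask, threshold_record(image_name, channel, "from_file",
                                          value))
}

#' Threshold by an externally produced mask or probability map
#'
#' Accepts a foreground mask computed outside this package (for example by a
#' trained pixel classifier). Probability maps are binarized at 0.5; binary
#' masks pass through unchanged.
#'
#' @param plane 8-bit intensity matrix (used only for the shape check).
#' @param mask_path path to a TIFF/PNG mask or probability map, or a numeric
#'   matrix (values in `[0, 1]`, or 0/255).
#' @param image_name,channel identifiers for the audit record.
#' @return logical mask with a `threshold_record` (method
#'   `"external_mask"`, no value).
#' @export
external_mask <- function(plane, mask_path, image_name = "image",
                          channel = "red") {
  stopifnot_plane(plane)
  if (is.matrix(mask_path)) {
    m <- mask_path
  } else {
    img <- load_image(mask_path)
    if (!inherits(img, "mc_image"))
      stop("external mask '", mask_path, "' must be single-page",
           call. = FALSE)
    m <- img$data[, , 1]
  }
  if (!all(dim(m) == dim(plane)))
    stop("external mask shape (", nrow(m), "x", ncol(m),
         ") does not match the plane (", nrow(plane), "x", ncol(plane), ")",
         call. = FALSE)
  if (max(m) > 1) m <- m / 255  # 8-bit probability map or 0/255 binary
  mask <- m >= 0.5
  mask_with_record(mask, threshold_record(image_name, channel,
                                          "external_mask"))
}
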