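#' Parameters for the statistical spot-detection threshold
#'
#' Controls [synquant_threshold()], a statistical object detector in the
#' spirit of the SynQuant family of tools: candidate objects are judged
#' against their local neighbourhood by a z-score on the contrast between the
#' object and a surrounding ring, rather than by a single global intensity
#' cutoff. Defaults are the values used for simulated two-channel synapse
#' data.
#'
#' @param z_threshold minimum z-score (number of noise standard deviations of
#'   object/ring contrast) for acceptance.
#' @param min_size,max_size accepted object area range in pixels.
#' @param min_fill minimum fill factor, object area divided by bounding-box
#'   area, in `(0, 1]`.
#' @param max_wh_ratio maximum bounding-box aspect ratio `max(w,h)/min(w,h)`.
#' @param noise_sd estimated intensity noise standard deviation (8-bit
#'   units).
#' @param z_axis_multiplier accepted for configuration parity with 3D
#'   pipelines; it has no effect on 2D planes and a value other than 1 draws
#'   a warning from [synquant_threshold()].
#' @return an object of class `synquant_params`.
#' @export
synquant_params <- function(z_threshold = 10, min_size = 10, max_size = 100,
                            min_fill = 0.5, max_wh_ratio = 4, noise_sd = 12,
                            z_axis_multiplier = 1) {
  if (min_size > max_size) stop("min_size must be <= max_size", call. = FALSE)
  if (min_fill <= 0 || min_fill > 1) stop("min_fill must lie in (0, 1]",
                                          call. = FALSE)
  if (max_wh_ratio < 1) stop("max_wh_ratio must be >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(z_threshold = z_threshold, min_size = min_size,
                 max_size = max_size, min_fill = min_fill,
                 max_wh_ratio = max_wh_ratio, noise_sd = noise_sd,
                 z_axis_multiplier = z_axis_multiplier),
            class = "synquant_params")
}

# Contrast z-score of one candidate against a 2-px-wide surrounding ring.
# Computed on a padded local window so the ring never walks off the plane.
candidate_zscore <- function(plane, idx, noise_sd) {
  nr <- nrow(plane)
  r <- (idx - 1L) %% nr + 1L
  c_ <- (idx - 1L) %/% nr + 1L
  r0 <- max(1L, min(r) - 2L); r1 <- min(nr, max(r) + 2L)
  c0 <- max(1L, min(c_) - 2L); c1 <- min(ncol(plane), max(c_) + 2L)
  win <- plane[r0:r1, c0:c1, drop = FALSE]
  comp <- matrix(FALSE, nrow(win), ncol(win))
  comp[cbind(r - r0 + 1L, c_ - c0 + 1L)] <- TRUE
  ring <- EBImage::dilate(comp, synquant_ring_brush()) & !comp
  n_in <- length(idx); n_ring <- sum(ring)
  if (n_ring == 0L) return(-Inf)
  z <- (mean(win[comp]) - mean(win[ring])) /
    (noise_sd * sqrt(1 / n_in + 1 / n_ring))
  z
}

synquant_ring_brush <- local({
  brush <- NULL
  function() {
    if (is.null(brush)) brush <<- EBImage::makeBrush(5, shape = "box")
    brush
  }
})

#' Statistical spot-detection threshold
#'
#' A simplified statistical object detector: candidate objects are the
#' connected components obtained by sweeping an intensity threshold from the
#' highest level present down to 1. Each candidate within the allowed size
#' range is scored by the contrast between its pixels and a 2-px-wide
#' surrounding ring,
#' \deqn{z = \frac{\bar I_{in} - \bar I_{ring}}
#'            {\sigma \sqrt{1/n_{in} + 1/n_{ring}}},}
#' where \eqn{\sigma} is the configured noise standard deviation. A candidate
#' is accepted iff `z >= z_threshold`, its area lies in
#' `[min_size, max_size]`, its fill factor (area / bounding-box area) is at
#' least `min_fill`, and its bounding-box aspect ratio is at most
#' `max_wh_ratio`. Because candidates from different sweep levels can
#' overlap, the final mask keeps a non-overlapping set chosen greedily by
#' descending z-score; each pixel belongs to at most one accepted object.
#'
#' The z statistic depends only on intensity differences, so the result is
#' invariant to adding a constant to the whole plane (so long as no pixel
#' clips at 255). A constant plane yields an empty mask.
#'
#' @param plane 8-bit intensity matrix.
#' @param params a [synquant_params()].
#' @param image_name,channel identifiers for the audit record.
#' @return logical mask with a `threshold_record` (method `"synquant"`, no
#'   single value).
#' @export
synquant_threshold <- function(plane, params = synquant_params(),
                               image_name = "image", channel = "red") {
  stopifnot_plane(plane)
  if (!inherits(params, "synquant_params"))
    stop("params must be created with synquant_params()", call. = FALSE)
  if (params$z_axis_multiplier != 1)
    warning("z_axis_multiplier has no effect on 2D planes; ignored",
            call. = FALSE)
  rec <- threshold_record(image_name, channel, "synquant")
  out <- matrix(FALSE, nrow(plane), ncol(plane))
  levels <- sort(unique(plane[plane > 0]), decreasing = TRUE)
  if (length(levels) == 0L)
    return(mask_with_record(out, rec))

  cands <- vector("list", 256L)
  n_cand <- 0L
  seen <- character(0)
  for (lv in levels) {
    L <- label_components(plane >= lv)
    areas <- tabulate(L)
    keep <- which(areas >= params$min_size & areas <= params$max_size)
    if (length(keep) == 0L) next
    px <- component_pixels(L)
    for (k in keep) {
      idx <- px[[as.character(k)]]
      # the same pixel set recurs at consecutive levels; evaluate it once
      key <- paste(idx[1], length(idx), sum(idx), sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      nr <- nrow(plane)
      rr <- range((idx - 1L) %% nr + 1L)
      cc <- range((idx - 1L) %/% nr + 1L)
      w <- diff(cc) + 1L; h <- diff(rr) + 1L
      fill <- length(idx) / (w * h)
      whr <- max(w, h) / min(w, h)
      if (fill < params$min_fill || whr > params$max_wh_ratio) next
      z <- candidate_zscore(plane, idx, params$noise_sd)
      if (z < params$z_threshold) next
      n_cand <- n_cand + 1L
      cands[[n_cand]] <- list(idx = idx, z = z)
    }
  }
  if (n_cand == 0L) return(mask_with_record(out, rec))
  cands <- cands[seq_len(n_cand)]
  ord <- order(vapply(cands, `[[`, numeric(1), "z"), decreasing = TRUE)
  claimed <- matrix(FALSE, nrow(plane), ncol(plane))
  for (i in ord) {
    idx <- cands[[i]]$idx
    if (any(claimed[idx])) next
    claimed[idx] <- TRUE
    out[idx] <- TRUE
  }
  mask_with_record(out, rec)
}
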