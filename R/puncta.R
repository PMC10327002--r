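#' Region-of-interest specification
#'
#' Restricts puncta counting to a sub-region of the image, typically a circle
#' around the soma of a cultured neuron. A punctum (or overlap component)
#' belongs to the ROI iff its centroid lies inside it — a centroid rule
#' counts each object exactly once and is unambiguous at the ROI edge. The
#' circle is not required to lie fully within the image; its nominal area
#' \eqn{\pi r^2} is reported regardless of clipping.
#'
#' @param cx,cy circle centre in 0-based pixel coordinates.
#' @param radius circle radius in pixels.
#' @return an object of class `roi_spec`.
#' @export
roi_circle <- function(cx, cy, radius) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  structure(list(kind = "circle", cx = cx, cy = cy, radius = radius),
            class = "roi_spec")
}

#' @rdname roi_circle
#' @export
roi_whole_image <- function() {
  structure(list(kind = "whole_image"), class = "roi_spec")
}

#' @param roi an `roi_spec`.
#' @param width,height image dimensions in pixels.
#' @return `roi_area()`: the ROI area in square pixels.
#' @rdname roi_circle
#' @export
roi_area <- function(roi, width, height) {
  switch(roi$kind,
         whole_image = width * height,
         circle = pi * roi$radius^2)
}

#' @param x,y vectors of 0-based coordinates to test.
#' @return `roi_contains()`: logical vector, `TRUE` where (x, y) lies inside
#'   the ROI.
#' @rdname roi_circle
#' @export
roi_contains <- function(roi, x, y) {
  switch(roi$kind,
         whole_image = rep(TRUE, length(x)),
         circle = (x - roi$cx)^2 + (y - roi$cy)^2 <= roi$radius^2)
}

# Corner-corrected crack-length perimeter of one component.
#
# Crack length counts exposed pixel edges: E = 4*area - 2*(number of
# 4-adjacent foreground pairs). Pure crack length overestimates smooth
# boundaries (a diagonal step costs 2 instead of sqrt(2)), so each boundary
# corner is discounted:
#
#   P = E - (2 - sqrt(2)) * C,   C = C1 + C3 + 2*Cd
#
# where, over all 2x2 windows of the (padded) component, C1 / C3 count
# windows with exactly one / three foreground pixels (convex / concave 90-
# degree corners) and Cd counts windows whose two foreground pixels are
# diagonal (a double corner). Each corner replaces two unit cracks by one
# sqrt(2) diagonal, recovering length sqrt(2) per staircase step.
component_perimeter <- function(idx, nrow_) {
  r <- (idx - 1L) %% nrow_ + 1L
  c_ <- (idx - 1L) %/% nrow_ + 1L
  r0 <- min(r); c0 <- min(c_)
  h <- max(r) - r0 + 1L; w <- max(c_) - c0 + 1L
  m <- matrix(0L, h + 2L, w + 2L)  # 1-px pad so border windows are seen
  m[cbind(r - r0 + 2L, c_ - c0 + 2L)] <- 1L
  area <- length(idx)
  adj <- sum(m[-nrow(m), ] * m[-1, ]) + sum(m[, -ncol(m)] * m[, -1])
  E <- 4L * area - 2L * adj
  a <- m[-nrow(m), -ncol(m)]; b <- m[-nrow(m), -1]
  d <- m[-1, -ncol(m)]; e <- m[-1, -1]
  s <- a + b + d + e
  C1 <- sum(s == 1L)
  C3 <- sum(s == 3L)
  Cd <- sum(s == 2L & ((a == 1L & e == 1L) | (b == 1L & d == 1L)))
  E - (2 - sqrt(2)) * (C1 + C3 + 2L * Cd)
}

#' Circularity of a connected component
#'
#' Shape compactness `4 * pi * area / perimeter^2`, with the perimeter
#' estimated by a corner-corrected crack length (see the source for the
#' exact formula). A perfect circle scores 1; elongated shapes score lower.
#' Discretization can push small compact shapes above 1, so values are
#' clamped to 1; a single pixel is defined as perfectly compact (1.0).
#'
#' @param idx 1-based linear pixel indices of the component.
#' @param nrow_ number of rows of the mask the indices refer to.
#' @return circularity in `(0, 1]`.
#' @export
measure_circularity <- function(idx, nrow_) {
  if (length(idx) == 0L) stop("component is empty", call. = FALSE)
  if (length(idx) == 1L) return(1.0)
  p <- component_perimeter(idx, nrow_)
  min(1, 4 * pi * length(idx) / p^2)
}

#' Detect puncta as measured connected components
#'
#' Extracts 8-connected components from a binary foreground mask, measures
#' each (centroid, area, equivalent radius `sqrt(area/pi)`, circularity),
#' discards components outside the `[min_size, max_size]` area range or whose
#' centroid falls outside the ROI, and returns them sorted by
#' `(centroid_y, centroid_x)` with ids 1..n assigned after sorting, so output
#' order is deterministic.
#'
#' @param mask logical foreground mask (e.g. from [fixed_threshold()]).
#' @param channel channel role recorded with each punctum.
#' @param min_size,max_size area limits in pixels (inclusive).
#' @param roi an [roi_circle()]/[roi_whole_image()] specification.
#' @return data frame with columns `channel`, `id`, `x`, `y` (0-based
#'   centroid), `area`, `equiv_radius`, `circularity`, and a list-column
#'   `pixels` of 1-based linear indices into the mask.
#' @export
detect_puncta <- function(mask, channel = "red", min_size = 4,
                          max_size = Inf, roi = roi_whole_image()) {
  if (min_size < 1) stop("min_size must be >= 1", call. = FALSE)
  if (max_size < min_size) stop("max_size must be >= min_size", call. = FALSE)
  empty <- data.frame(channel = character(0), id = integer(0),
                      x = numeric(0), y = numeric(0), area = numeric(0),
                      equiv_radius = numeric(0), circularity = numeric(0))
  empty$pixels <- list()
  L <- label_components(mask)
  if (max(L) == 0L) return(empty)
  px <- component_pixels(L)
  areas <- lengths(px)
  keep <- areas >= min_size & areas <= max_size
  px <- px[keep]
  if (length(px) == 0L) return(empty)
  nr <- nrow(mask)
  cent <- t(vapply(px, pixel_centroid, numeric(2), nrow_ = nr))
  inside <- roi_contains(roi, cent[, "x"], cent[, "y"])
  px <- px[inside]
  if (length(px) == 0L) return(empty)
  cent <- cent[inside, , drop = FALSE]
  area <- lengths(px)
  circ <- vapply(px, measure_circularity, numeric(1), nrow_ = nr)
  out <- data.frame(channel = channel, id = NA_integer_,
                    x = cent[, "x"], y = cent[, "y"], area = as.numeric(area),
                    equiv_radius = sqrt(area / pi), circularity = circ,
                    stringsAsFactors = FALSE)
  out$pixels <- unname(px)
  ord <- order(out$y, out$x)
  out <- out[ord, ]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
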