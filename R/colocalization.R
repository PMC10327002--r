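#' Do two circular puncta colocalize?
#'
#' Two puncta, each approximated by the circle of its equivalent radius
#' centred on its centroid, colocalize iff the distance between their
#' centres is strictly less than the sum of their radii. Tangency
#' (`d == r1 + r2`) is not colocalization: the overlap area there is zero.
#'
#' @param p1,p2 one-row punctum records (lists or data-frame rows with
#'   fields `x`, `y`, `equiv_radius`).
#' @return logical.
#' @export
circles_colocalize <- function(p1, p2) {
  d <- sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2)
  d < p1$equiv_radius + p2$equiv_radius
}

#' Area of intersection of two circles
#'
#' Computes the lens-shaped overlap by the sector construction: for each
#' circle, take the circular sector spanned by the two intersection points
#' and subtract the triangle between the chord and the centre; the two
#' remainders sum to the overlap. With `d1 = (d^2 + r1^2 - r2^2)/(2d)` the
#' signed distance from centre 1 to the chord and `h` the half-chord length,
#' \deqn{A = r_1^2\cos^{-1}(d_1/r_1) - d_1 h
#'         + r_2^2\cos^{-1}(d_2/r_2) - d_2 h, \quad d_2 = d - d_1.}
#' Limits: separated or tangent circles (`d >= r1 + r2`) give 0; full
#' containment (`d <= |r1 - r2|`) gives the smaller circle's area. The
#' result is symmetric in `(r1, r2)`. All arguments are vectorized.
#'
#' @param r1,r2 circle radii in pixels (`> 0`).
#' @param d centre-to-centre distance in pixels (`>= 0`).
#' @return overlap area in square pixels.
#' @examples
#' circle_overlap_area(5, 5, 0)   # contained: 25*pi
#' circle_overlap_area(2, 3, 5)   # tangent: 0
#' circle_overlap_area(1, 1, 1)   # ~1.2284
#' @export
circle_overlap_area <- function(r1, r2, d) {
  if (any(r1 <= 0) || any(r2 <= 0) || any(d < 0))
    stop("radii must be positive and the distance non-negative",
         call. = FALSE)
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); d <- rep_len(d, n)
  out <- numeric(n)
  contained <- d <= abs(r1 - r2)
  out[contained] <- pi * pmin(r1, r2)[contained]^2
  lens <- !contained & d < r1 + r2
  if (any(lens)) {
    rl1 <- r1[lens]; rl2 <- r2[lens]; dl <- d[lens]
    d1 <- (dl^2 + rl1^2 - rl2^2) / (2 * dl)  # centre 1 -> chord
    d2 <- dl - d1                            # centre 2 -> chord (signed)
    h <- sqrt(pmax(rl1^2 - d1^2, 0))         # half chord
    sector1 <- rl1^2 * acos(pmin(pmax(d1 / rl1, -1), 1))
    sector2 <- rl2^2 * acos(pmin(pmax(d2 / rl2, -1), 1))
    out[lens] <- (sector1 - d1 * h) + (sector2 - d2 * h)
  }
  out
}

#' Circular-approximation colocalization of one image
#'
#' Every red punctum is compared to every green punctum; each qualifying
#' pair ([circles_colocalize()]) yields one record, so a punctum engaged by
#' several partners appears in several records (the per-pair convention; see
#' the summary output for the deduplicated count). The record centre is the
#' midpoint of the intersection chord,
#' `c1 + (d^2 + r1^2 - r2^2) / (2 d^2) * (c2 - c1)` (the midpoint of the two
#' centres for concentric circles), and the overlap area comes from
#' [circle_overlap_area()].
#'
#' @param red,green punctum tables from [detect_puncta()].
#' @param image_name identifier written into the records.
#' @return data frame with columns `image`, `method` (`"circular"`),
#'   `center_x`, `center_y`, `overlap_area`, `red_id`, `green_id`.
#' @export
circular_colocalize_image <- function(red, green, image_name = "image") {
  empty <- data.frame(image = character(0), method = character(0),
                      center_x = numeric(0), center_y = numeric(0),
                      overlap_area = numeric(0), red_id = integer(0),
                      green_id = integer(0), stringsAsFactors = FALSE)
  if (nrow(red) == 0L || nrow(green) == 0L) return(empty)
  dx <- outer(red$x, green$x, "-")
  dy <- outer(red$y, green$y, "-")
  d <- sqrt(dx^2 + dy^2)
  rsum <- outer(red$equiv_radius, green$equiv_radius, "+")
  hit <- which(d < rsum, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  r1 <- red$equiv_radius[i]; r2 <- green$equiv_radius[j]
  dij <- d[hit]
  t <- ifelse(dij > 0, (dij^2 + r1^2 - r2^2) / (2 * dij^2), 0.5)
  out <- data.frame(image = image_name, method = "circular",
                    center_x = red$x[i] + t * (green$x[j] - red$x[i]),
                    center_y = red$y[i] + t * (green$y[j] - red$y[i]),
                    overlap_area = circle_overlap_area(r1, r2, dij),
                    red_id = red$id[i], green_id = green$id[j],
                    stringsAsFactors = FALSE)
  out <- out[order(out$red_id, out$green_id), ]
  rownames(out) <- NULL
  out
}

#' Pixel-overlap colocalization of one image
#'
#' Intersects the red and green foreground masks pixel by pixel (and the
#' blue mask too for triple colocalization); the 8-connected components of
#' the resulting overlap mask, filtered by minimum area and by ROI
#' membership of their centroid, are the colocalization records. Unlike the
#' circular approximation this makes no shape assumption, so it also handles
#' non-circular objects.
#'
#' @param red_mask,green_mask logical masks of identical shape.
#' @param blue_mask optional third mask for triple colocalization.
#' @param min_size minimum overlap-component area in pixels.
#' @param roi ROI applied to overlap-component centroids.
#' @param image_name identifier written into the records.
#' @return data frame with columns `image`, `method` (`"pixel2"` or
#'   `"pixel3"`), `center_x`, `center_y`, `overlap_area`, `red_id`,
#'   `green_id` (ids are `NA`: pixel records are not tied to single input
#'   puncta).
#' @export
pixel_colocalize_image <- function(red_mask, green_mask, blue_mask = NULL,
                                   min_size = 1, roi = roi_whole_image(),
                                   image_name = "image") {
  if (!all(dim(red_mask) == dim(green_mask)))
    stop("red and green masks differ in shape", call. = FALSE)
  overlap <- red_mask & green_mask
  method <- "pixel2"
  if (!is.null(blue_mask)) {
    if (!all(dim(blue_mask) == dim(red_mask)))
      stop("blue mask differs in shape", call. = FALSE)
    overlap <- overlap & blue_mask
    method <- "pixel3"
  }
  comps <- detect_puncta(overlap, channel = "overlap", min_size = min_size,
                         max_size = Inf, roi = roi)
  data.frame(image = rep(image_name, nrow(comps)),
             method = rep(method, nrow(comps)),
             center_x = comps$x, center_y = comps$y,
             overlap_area = comps$area,
             red_id = rep(NA_integer_, nrow(comps)),
             green_id = rep(NA_integer_, nrow(comps)),
             stringsAsFactors = FALSE)
}

# Deduplicated colocalized-puncta count: records collapsed so each punctum
# pair partner is counted once. For circular records this is the number of
# distinct red puncta engaged in at least one colocalization; pixel records
# are already disjoint components, so the count is the record count.
dedup_coloc_count <- function(records) {
  if (nrow(records) == 0L) return(0L)
  if (all(records$method == "circular"))
    length(unique(records$red_id))
  else
    nrow(records)
}
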