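# Internal helpers shared across modules.

# Round half away from zero (all intensities here are non-negative, so this is
# round-half-up). base::round() rounds half to even, which would make 8-bit
# conversion of mid-grey values platform-lore rather than arithmetic.
round_half_up <- function(x) floor(x + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

as_plane_int <- function(x) {
  storage.mode(x) <- "integer"
  x
}

stopifnot_plane <- function(plane) {
  if (!is.matrix(plane) || !is.numeric(plane))
    stop("expected a 2D numeric intensity plane", call. = FALSE)
  if (any(plane < 0 | plane > 255))
    stop("plane intensities must lie in [0, 255]", call. = FALSE)
  invisible(plane)
}

#' Label connected components with 8-connectivity
#'
#' Connected-component labelling of a binary mask where pixels touching
#' edge-to-edge or corner-to-corner belong to the same object, matching the
#' default behaviour of ImageJ's Analyze Particles. Built on
#' [EBImage::bwlabel()] (4-connected) followed by a union-find merge of
#' labels that touch diagonally.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer matrix of the same shape; background is 0, components are
#'   numbered 1..n in first-encounter raster order.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  m <- mask != 0
  L <- EBImage::bwlabel(m)
  L <- matrix(as.integer(EBImage::imageData(L)), nrow(m), ncol(m))
  nlab <- max(L)
  if (nlab <= 1L) return(L)

  nr <- nrow(L); nc <- ncol(L)
  # diagonally adjacent label pairs (both diagonal directions)
  a <- L[-nr, -nc]; b <- L[-1, -1]   # NW–SE
  c_ <- L[-nr, -1]; d <- L[-1, -nc]  # NE–SW
  sel1 <- a > 0L & b > 0L & a != b
  sel2 <- c_ > 0L & d > 0L & c_ != d
  pairs <- rbind(cbind(a[sel1], b[sel1]), cbind(c_[sel2], d[sel2]))
  if (nrow(pairs) == 0L) return(L)
  pairs <- unique(pairs)

  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  # renumber roots consecutively in raster order of first appearance
  fg <- L > 0L
  L[fg] <- root[L[fg]]
  ids <- unique(L[fg])
  remap <- integer(nlab)
  remap[ids] <- seq_along(ids)
  L[fg] <- remap[L[fg]]
  L
}

# Per-component pixel index lists from a label matrix (1-based linear indices).
component_pixels <- function(labels) {
  fg <- which(labels > 0L)
  if (length(fg) == 0L) return(list())
  split(fg, labels[fg])
}

# Centroids (0-based x = col-1, y = row-1) of pixel index sets.
pixel_centroid <- function(idx, nrow_) {
  r <- (idx - 1L) %% nrow_ + 1L
  c_ <- (idx - 1L) %/% nrow_ + 1L
  c(x = mean(c_) - 1, y = mean(r) - 1)
}
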