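# Independent oracles and fixture builders used across the suite.

# Brute-force 8-connected component labelling by BFS flood fill.
# Returns a list of sorted 1-based linear pixel index vectors, ordered by
# their smallest index.
flood_fill_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (start in which(mask)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      members <- c(members, cur)
      r <- (cur - 1L) %% nr + 1L
      c_ <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c_ + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        idx <- (cc - 1L) * nr + rr
        if (mask[idx] && !seen[idx]) {
          seen[idx] <- TRUE
          queue <- c(queue, idx)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# Centroid (0-based x, y) of a pixel index set, independent arithmetic.
pixel_centroid_oracle <- function(idx, nr) {
  r <- (idx - 1) %% nr + 1
  c_ <- (idx - 1) %/% nr + 1
  c(mean(c_) - 1, mean(r) - 1)
}

# Standard closed-form circle-circle lens area (independent of the package's
# sector construction).
lens_closed_form <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
}

# Monte-Carlo rejection-sampling estimate of the lens area for a partial
# overlap (circle 1 at the origin, circle 2 at (d, 0)).
lens_mc <- function(r1, r2, d, n = 4e6, seed = 42) {
  set.seed(seed)
  x0 <- d - r2; x1 <- r1
  x1c <- (d^2 + r1^2 - r2^2) / (2 * d)
  ymax <- sqrt(max(r1^2 - x1c^2, 0))  # half-chord: widest point of the lens
  x <- runif(n, x0, x1)
  y <- runif(n, -ymax, ymax)
  inside <- (x^2 + y^2 <= r1^2) & ((x - d)^2 + y^2 <= r2^2)
  mean(inside) * (x1 - x0) * 2 * ymax
}

# Rasterized disc mask: pixels whose centre lies within radius r of (cx, cy)
# (0-based coordinates).
raster_disc <- function(nr, nc, cx, cy, r) {
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# Write a (possibly multi-page) 8-bit single-channel TIFF from a list of
# integer matrices.
write_stack_tiff <- function(planes, path) {
  tiff::writeTIFF(lapply(planes, function(p) p / 255), path,
                  bits.per.sample = 8L)
  path
}

# Maximum one-to-one matching size between detections and truths with
# pairwise distance <= tol, by exhaustive recursion (tiny instances only).
max_matching_size <- function(dmat, tol) {
  nd <- nrow(dmat)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nd - i + 1L) <= best) return()
    if (i > nd) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used, count)  # leave detection i unmatched
    for (j in seq_len(ncol(dmat))) {
      if (!used[j] && dmat[i, j] <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(ncol(dmat)), 0L)
  best
}

# Small simulation config for fast tests.
tiny_sim_config <- function(...) {
  simulation_config(width = 256L, height = 256L, n_red_only = 20L,
                    n_green_only = 20L, n_both = 20L, seed = 99L, ...)
}
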