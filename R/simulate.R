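#' Configuration of the simulated-synapse image generator
#'
#' The generator reproduces the standard validation design for synapse
#' counting: two-channel images in which circular puncta are pasted at known
#' positions onto a Gaussian-noise background. Of `n_positions = 1000`
#' positions per image, 334 receive a red punctum only, 333 a green punctum
#' only, and 333 receive a red and a green punctum at the same location — a
#' simulated synapse — giving 667 red puncta, 666 green puncta and 333
#' overlaps per image in total. Backgrounds are i.i.d. Gaussian with mean
#' and standard deviation equal to a reference histogram's values scaled by
#' a noise multiplier (0 = no background, 1 = excessive background); the
#' benchmark set holds 20 images at each of the 5 multipliers, 100 images in
#' all.
#'
#' Puncta are synthesized as radially decaying (Gaussian-profile) discs
#' rather than crops from real micrographs, keeping the generator
#' self-contained; the radius and peak ranges emulate sub-micrometre
#' synaptic puncta at a confocal pixel scale of roughly 0.1 um/px.
#'
#' @param width,height image size in pixels.
#' @param n_red_only,n_green_only,n_both position class counts; their sum is
#'   the total number of pasted positions.
#' @param n_templates_per_channel number of distinct punctum stamps drawn
#'   per channel.
#' @param template_radius_range integer radius range (px) of the stamps.
#' @param template_peak_range integer peak-intensity range of the stamps.
#' @param base_mean,base_sd reference background histogram mean and standard
#'   deviation (8-bit intensity units), scaled by the noise multiplier.
#' @param noise_multipliers background scaling levels of the benchmark set.
#' @param n_images_per_level benchmark images per noise level.
#' @param seed integer seed; fixes the template set and, through
#'   [generate_benchmark_set()], every per-image seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(width = 1024L, height = 1024L,
                              n_red_only = 334L, n_green_only = 333L,
                              n_both = 333L,
                              n_templates_per_channel = 10L,
                              template_radius_range = c(2L, 6L),
                              template_peak_range = c(120L, 230L),
                              base_mean = 20, base_sd = 12,
                              noise_multipliers = c(0, 0.25, 0.5, 0.75, 1),
                              n_images_per_level = 20L,
                              seed = 1L) {
  counts <- c(n_red_only, n_green_only, n_both)
  if (any(counts <= 0)) stop("all position class counts must be > 0",
                             call. = FALSE)
  if (any(noise_multipliers < 0)) stop("noise multipliers must be >= 0",
                                       call. = FALSE)
  if (diff(template_radius_range) < 0 || diff(template_peak_range) < 0)
    stop("template ranges must be non-decreasing", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_positions = sum(counts),
                 n_red_only = as.integer(n_red_only),
                 n_green_only = as.integer(n_green_only),
                 n_both = as.integer(n_both),
                 n_templates_per_channel = as.integer(n_templates_per_channel),
                 template_radius_range = as.integer(template_radius_range),
                 template_peak_range = as.integer(template_peak_range),
                 base_mean = base_mean, base_sd = base_sd,
                 noise_multipliers = noise_multipliers,
                 n_images_per_level = as.integer(n_images_per_level),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Synthesize punctum template stamps
#'
#' Draws `n_templates_per_channel` stamps per channel: square matrices of
#' side `2r + 1` holding a radially decaying disc,
#' `I(rho) = round(peak * exp(-rho^2 / (2 (r/2)^2)))` for `rho <= r` and 0
#' outside, with radius `r` and `peak` sampled uniformly (as integers) from
#' the configured ranges. The stamp maximum equals the sampled peak.
#' Deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with elements `red` and `green`, each a list of integer
#'   stamp matrices carrying attributes `radius` and `peak`.
#' @export
make_templates <- function(config = simulation_config(), seed = config$seed) {
  rr <- config$template_radius_range
  pr <- config$template_peak_range
  if (2L * rr[2] + 1L > min(config$width, config$height))
    stop("largest template would not fit in the image", call. = FALSE)
  set.seed(seed)
  one <- function() {
    r <- rr[1] + sample.int(rr[2] - rr[1] + 1L, 1L) - 1L
    peak <- pr[1] + sample.int(pr[2] - pr[1] + 1L, 1L) - 1L
    s <- 2L * r + 1L
    xy <- seq_len(s) - (r + 1L)
    rho2 <- outer(xy^2, xy^2, "+")
    stamp <- round_half_up(peak * exp(-rho2 / (2 * (r / 2)^2)))
    stamp[rho2 > r^2] <- 0
    structure(as_plane_int(stamp), radius = r, peak = peak)
  }
  list(red = replicate(config$n_templates_per_channel, one(),
                       simplify = FALSE),
       green = replicate(config$n_templates_per_channel, one(),
                         simplify = FALSE))
}

#' Gaussian-noise background plane
#'
#' I.i.d. normal draws with mean `base_mean * multiplier` and standard
#' deviation `base_sd * multiplier`, rounded and clipped to 0--255. A
#' multiplier of 0 gives an all-zero plane.
#'
#' @param width,height plane size in pixels.
#' @param base_mean,base_sd reference histogram statistics.
#' @param multiplier noise scaling (`>= 0`).
#' @param seed optional integer seed.
#' @return integer matrix `height x width`.
#' @export
gaussian_background <- function(width, height, base_mean = 20, base_sd = 12,
                                multiplier = 1, seed = NULL) {
  if (multiplier < 0) stop("multiplier must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (multiplier == 0) return(matrix(0L, height, width))
  v <- rnorm(width * height, mean = base_mean * multiplier,
             sd = base_sd * multiplier)
  as_plane_int(matrix(clip255(round_half_up(v)), height, width))
}

# Sample an anchor (top-left corner, 0-based) for a box of the given sides
# such that the box is free in every required channel occupancy grid.
sample_anchor <- function(grids, need, side_by_channel, width, height,
                          max_attempts = 10000L) {
  for (att in seq_len(max_attempts)) {
    ok <- TRUE
    ax <- NULL
    for (ch in need) {
      s <- side_by_channel[[ch]]
      if (is.null(ax)) {
        smax <- max(unlist(side_by_channel[need]))
        ax <- sample.int(width - smax + 1L, 1L) - 1L
        ay <- sample.int(height - smax + 1L, 1L) - 1L
      }
      if (any(grids[[ch]][(ay + 1L):(ay + s), (ax + 1L):(ax + s)])) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(c(ax, ay))
  }
  stop("could not place all puncta without same-channel overlap after ",
       max_attempts, " attempts; use a larger image or fewer positions",
       call. = FALSE)
}

#' Generate one simulated synapse image with ground truth
#'
#' Samples anchors (top-left corners of the stamp bounding boxes) so that no
#' two bounding boxes pasted into the same channel overlap — the pipeline
#' assumes non-overlapping same-channel objects — assigns them to the three
#' position classes, and pastes one randomly chosen template per required
#' channel at each position by pixelwise maximum with the background (so
#' noise never darkens a punctum). At a `both` position the red and the
#' green stamp share the same anchor; because their radii generally differ,
#' their centres are offset diagonally by `sqrt(2) * |r_red - r_green|` px,
#' giving varying degrees of overlap as in real data. Cross-channel chance
#' adjacency beyond the designed synapses is allowed.
#'
#' @param config a [simulation_config()].
#' @param noise_multiplier background scaling for this image.
#' @param seed integer seed for this image (positions + background).
#' @param templates template set from [make_templates()]; by default drawn
#'   from `config$seed`, so one template set serves a whole benchmark.
#' @param name image name.
#' @return list with elements `image` (an [rgb_image()]) and `truth`, a data
#'   frame with one row per position: `class` (`red_only`, `green_only`,
#'   `both`), `anchor_x`, `anchor_y`, `template_red`, `template_green`,
#'   centre coordinates of each pasted stamp, and for `both` rows the
#'   synapse reference centre `cx`, `cy` (midpoint of the two stamp
#'   centres).
#' @export
generate_simulated_image <- function(config = simulation_config(),
                                     noise_multiplier = 0,
                                     seed = config$seed,
                                     templates = NULL,
                                     name = "simulated") {
  if (is.null(templates)) templates <- make_templates(config)
  set.seed(seed)
  w <- config$width; h <- config$height
  red <- gaussian_background(w, h, config$base_mean, config$base_sd,
                             noise_multiplier)
  green <- gaussian_background(w, h, config$base_mean, config$base_sd,
                               noise_multiplier)

  classes <- sample(rep(c("red_only", "green_only", "both"),
                        c(config$n_red_only, config$n_green_only,
                          config$n_both)))
  n <- length(classes)
  grids <- list(red = matrix(FALSE, h, w), green = matrix(FALSE, h, w))
  truth <- data.frame(class = classes,
                      anchor_x = NA_integer_, anchor_y = NA_integer_,
                      template_red = NA_integer_, template_green = NA_integer_,
                      red_cx = NA_real_, red_cy = NA_real_,
                      green_cx = NA_real_, green_cy = NA_real_,
                      cx = NA_real_, cy = NA_real_,
                      stringsAsFactors = FALSE)
  nt <- config$n_templates_per_channel
  for (i in seq_len(n)) {
    need <- switch(classes[i], red_only = "red", green_only = "green",
                   both = c("red", "green"))
    tid <- setNames(sample.int(nt, length(need), replace = TRUE), need)
    side <- lapply(need, function(ch)
      nrow(templates[[ch]][[tid[[ch]]]]))
    names(side) <- need
    a <- sample_anchor(grids, need, side, w, h)
    ax <- a[1]; ay <- a[2]
    truth$anchor_x[i] <- ax; truth$anchor_y[i] <- ay
    for (ch in need) {
      stamp <- templates[[ch]][[tid[[ch]]]]
      s <- nrow(stamp)
      rows <- (ay + 1L):(ay + s); cols <- (ax + 1L):(ax + s)
      if (ch == "red") {
        red[rows, cols] <- pmax(red[rows, cols], stamp)
        truth$template_red[i] <- tid[[ch]]
        truth$red_cx[i] <- ax + (s - 1L) / 2
        truth$red_cy[i] <- ay + (s - 1L) / 2
      } else {
        green[rows, cols] <- pmax(green[rows, cols], stamp)
        truth$template_green[i] <- tid[[ch]]
        truth$green_cx[i] <- ax + (s - 1L) / 2
        truth$green_cy[i] <- ay + (s - 1L) / 2
      }
      grids[[ch]][rows, cols] <- TRUE
    }
    if (classes[i] == "both") {
      truth$cx[i] <- (truth$red_cx[i] + truth$green_cx[i]) / 2
      truth$cy[i] <- (truth$red_cy[i] + truth$green_cy[i]) / 2
    }
  }
  img <- rgb_image(name, as_plane_int(red), as_plane_int(green))
  list(image = img, truth = truth)
}

#' Generate a full benchmark set of simulated images
#'
#' For each noise multiplier, generates `n_images_per_level` images with
#' per-image seeds derived deterministically from `config$seed`, all sharing
#' one template set. Images can be written to disk (lossless TIFF plus a
#' per-image ground-truth CSV) and/or handed to a callback for immediate
#' analysis, which avoids holding the whole set in memory.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory; when given, each image is saved
#'   as `<name>.tif` with its truth table as `<name>_truth.csv`, plus a
#'   `manifest.csv` (`file,multiplier,seed`).
#' @param image_fun optional `function(image, truth, multiplier)` applied to
#'   each generated image; its results are returned in the `results` list.
#' @return list with `manifest` (data frame `file`, `multiplier`, `seed`),
#'   `class_counts` (matrix of per-image truth class counts) and `results`
#'   (list of `image_fun` outputs, or `NULL`).
#' @export
generate_benchmark_set <- function(config = simulation_config(),
                                   out_dir = NULL, image_fun = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  templates <- make_templates(config)
  n_total <- length(config$noise_multipliers) * config$n_images_per_level
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, n_total)
  manifest <- data.frame(file = character(n_total),
                         multiplier = numeric(n_total),
                         seed = integer(n_total), stringsAsFactors = FALSE)
  class_counts <- matrix(0L, n_total, 3,
                         dimnames = list(NULL,
                                         c("red_only", "green_only", "both")))
  results <- if (is.null(image_fun)) NULL else vector("list", n_total)
  k <- 0L
  for (m in config$noise_multipliers) {
    for (i in seq_len(config$n_images_per_level)) {
      k <- k + 1L
      name <- sprintf("sim_m%03d_i%02d", round(100 * m), i)
      sim <- generate_simulated_image(config, m, seed = seeds[k],
                                      templates = templates, name = name)
      tab <- table(factor(sim$truth$class,
                          levels = c("red_only", "green_only", "both")))
      class_counts[k, ] <- as.integer(tab)
      file <- ""
      if (!is.null(out_dir)) {
        file <- file.path(out_dir, paste0(name, ".tif"))
        arr <- array(0, c(config$height, config$width, 3L))
        arr[, , 1] <- sim$image$planes$red / 255
        arr[, , 2] <- sim$image$planes$green / 255
        tiff::writeTIFF(arr, file, bits.per.sample = 8L)
        truth_out <- sim$truth
        write.csv(truth_out, file.path(out_dir, paste0(name, "_truth.csv")),
                  row.names = FALSE)
      }
      manifest$file[k] <- if (nzchar(file)) basename(file) else name
      manifest$multiplier[k] <- m
      manifest$seed[k] <- seeds[k]
      if (!is.null(image_fun))
        results[[k]] <- image_fun(sim$image, sim$truth, m)
    }
  }
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  list(manifest = manifest, class_counts = class_counts, results = results)
}

#' Score detections against simulated ground truth
#'
#' Greedy one-to-one matching of detected colocalization centres to the true
#' synapse (`both`) positions: candidate detection--truth pairs within the
#' distance tolerance are matched in order of increasing distance, each
#' detection and each truth at most once. Matched detections are true
#' positives; unmatched detections false positives; unmatched truths false
#' negatives. By convention recall is 1 when there are no truths and
#' precision is 1 when there are no detections.
#'
#' @param detections data frame with `center_x`, `center_y` columns (e.g.
#'   from [pixel_colocalize_image()] or [circular_colocalize_image()]).
#' @param truth ground-truth table from [generate_simulated_image()] (only
#'   its `both` rows, with reference centres `cx`, `cy`, are used), or any
#'   data frame with `cx`, `cy` columns.
#' @param tolerance matching radius in pixels.
#' @return list with `tp`, `fp`, `fn`, `recall`, `precision`.
#' @export
match_and_score <- function(detections, truth, tolerance = 5) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if ("class" %in% names(truth)) truth <- truth[truth$class == "both", ]
  n_det <- nrow(detections); n_tru <- nrow(truth)
  tp <- 0L
  if (n_det > 0L && n_tru > 0L) {
    dx <- outer(detections$center_x, truth$cx, "-")
    dy <- outer(detections$center_y, truth$cy, "-")
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= tolerance, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_det <- logical(n_det); used_tru <- logical(n_tru)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_det[i] && !used_tru[j]) {
          used_det[i] <- TRUE; used_tru[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- n_det - tp
  fn <- n_tru - tp
  list(tp = tp, fp = fp, fn = fn,
       recall = if (tp + fn == 0L) 1 else tp / (tp + fn),
       precision = if (tp + fp == 0L) 1 else tp / (tp + fp))
}
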