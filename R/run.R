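#' Batch run configuration
#'
#' Collects every setting of a batch analysis. The experiment directory must
#' contain at least one subfolder; each subfolder holds only the image files
#' to analyze (groups are often split between subfolders, which does not
#' affect the analysis). Thresholding applies one method to all active
#' channels: `"fixed"` (per-channel values), `"from_file"` (a threshold
#' table CSV, see [thresholds_from_file()]), `"synquant"`
#' ([synquant_threshold()]) or `"external_mask"` (per-image mask files named
#' `<name>_<channel>_mask.tif`/`.png` in `threshold$mask_dir`).
#'
#' @param experiment_dir directory whose subfolders contain the images.
#' @param output_dir where all outputs are written (created if needed).
#' @param mapping a [channel_mapping()].
#' @param preprocess a [preprocess_config()].
#' @param threshold list with `method` and, depending on it, `value` (named
#'   numeric, per channel), `file`, `synquant` ([synquant_params()]) or
#'   `mask_dir`.
#' @param roi an [roi_circle()] / [roi_whole_image()].
#' @param analysis_mode `"pixel"` or `"circular"`.
#' @param group_size z-stack projection group size (see
#'   [grouped_max_projection()]).
#' @param min_size,max_size punctum area limits in pixels (applied to every
#'   channel).
#' @param coloc_min_size minimum overlap-component area for the pixel
#'   method.
#' @param overlay_radius radius (px) of the white discs drawn on the
#'   feedback overlay.
#' @param seed integer recorded in the run log (the analysis itself is
#'   deterministic).
#' @return an object of class `run_config`.
#' @export
run_config <- function(experiment_dir, output_dir,
                       mapping = channel_mapping(),
                       preprocess = preprocess_config(),
                       threshold = list(method = "fixed",
                                        value = c(red = 50, green = 50,
                                                  blue = 50)),
                       roi = roi_whole_image(),
                       analysis_mode = c("pixel", "circular"),
                       group_size = 3L,
                       min_size = 4, max_size = Inf,
                       coloc_min_size = 1,
                       overlay_radius = 3L,
                       seed = 1L) {
  analysis_mode <- match.arg(analysis_mode)
  threshold$method <- match.arg(threshold$method,
                                c("fixed", "from_file", "synquant",
                                  "external_mask"))
  structure(list(experiment_dir = experiment_dir, output_dir = output_dir,
                 mapping = mapping, preprocess = preprocess,
                 threshold = threshold, roi = roi,
                 analysis_mode = analysis_mode,
                 group_size = as.integer(group_size),
                 min_size = min_size, max_size = max_size,
                 coloc_min_size = coloc_min_size,
                 overlay_radius = as.integer(overlay_radius),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the [run_config()] arguments; nested sections
#' `channels` (`red`/`green`/`blue` input indices), `preprocess`
#' (`noise_reduction`, `rolling_ball_radius`, `blur_sigma`,
#' `brightness_norm`, `saturated_fraction`), `threshold` (`method` plus
#' method-specific keys, `synquant.*` matching [synquant_params()]
#' arguments) and `roi` (`kind`, `cx`, `cy`, `radius`). Missing keys take
#' the package defaults.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  mp <- y$channels
  mapping <- channel_mapping(red = mp$red %||% 1L, green = mp$green %||% 2L,
                             blue = mp$blue)
  pp <- do.call(preprocess_config, y$preprocess %||% list())
  th <- y$threshold %||% list(method = "fixed")
  if (!is.null(th$synquant)) th$synquant <- do.call(synquant_params,
                                                   th$synquant)
  if (!is.null(th$value)) th$value <- unlist(th$value)
  roi <- if (is.null(y$roi) || identical(y$roi$kind, "whole_image"))
    roi_whole_image()
  else roi_circle(y$roi$cx, y$roi$cy, y$roi$radius)
  run_config(experiment_dir = y$experiment_dir, output_dir = y$output_dir,
             mapping = mapping, preprocess = pp, threshold = th, roi = roi,
             analysis_mode = y$analysis_mode %||% "pixel",
             group_size = y$group_size %||% 3L,
             min_size = y$min_size %||% 4, max_size = y$max_size %||% Inf,
             coloc_min_size = y$coloc_min_size %||% 1,
             overlay_radius = y$overlay_radius %||% 3L,
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coord_comment <- "# pixel coordinates are 0-based, x = column, y = row, origin at the top-left"

write_csv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(coord_comment, con)
  suppressWarnings(write.csv(df, con, row.names = FALSE))
  invisible(path)
}

active_channels <- function(mapping) {
  names(mapping$index)[!is.na(mapping$index)]
}

threshold_channel <- function(plane, config, image_name, channel,
                              threshold_table = NULL) {
  th <- config$threshold
  switch(th$method,
         fixed = {
           if (!channel %in% names(th$value))
             stop("no fixed threshold value configured for channel '",
                  channel, "'", call. = FALSE)
           fixed_threshold(plane, th$value[[channel]], image_name, channel)
         },
         from_file = apply_threshold_file(plane, threshold_table,
                                          image_name, channel),
         synquant = synquant_threshold(plane,
                                       th$synquant %||% synquant_params(),
                                       image_name, channel),
         external_mask = {
           cand <- file.path(th$mask_dir,
                             paste0(image_name, "_", channel, "_mask",
                                    c(".tif", ".tiff", ".png")))
           hit <- cand[file.exists(cand)]
           if (length(hit) == 0L)
             stop("no external mask found for (", image_name, ", ", channel,
                  ") under '", th$mask_dir, "'", call. = FALSE)
           external_mask(plane, hit[[1]], image_name, channel)
         })
}

#' Draw the colocalization feedback overlay
#'
#' Copies the input image and paints a small white disc at the centre of
#' each recorded colocalization, then saves it as `<name>_colocs.png` so the
#' counted synapses can be checked against the raw image by eye.
#'
#' @param image an [rgb_image()].
#' @param records colocalization record table for this image.
#' @param dir output directory.
#' @param radius overlay disc radius in pixels.
#' @return the written file path, invisibly.
#' @export
render_overlay <- function(image, records, dir, radius = 3L) {
  planes <- image$planes
  if (nrow(records) > 0L) {
    off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
    off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
    for (k in seq_len(nrow(records))) {
      px <- round(records$center_x[k]) + off$dx + 1L
      py <- round(records$center_y[k]) + off$dy + 1L
      ok <- px >= 1L & px <= image$width & py >= 1L & py <= image$height
      idx <- cbind(py[ok], px[ok])
      for (ch in names(planes)) planes[[ch]][idx] <- 255L
    }
  }
  out <- image
  out$planes <- planes
  path <- file.path(dir, paste0(image$name, "_colocs.png"))
  write_rgb_image(out, path)
  invisible(path)
}

#' Save thresholded channel masks
#'
#' Writes each channel's binary foreground mask as a lossless 0/255 PNG
#' named `<name>_<channel>_thresholded.png`; reading the file back
#' reproduces the mask exactly.
#'
#' @param masks named list of logical masks (names are channel roles).
#' @param image_name image identifier used in the file names.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_thresholded_channels <- function(masks, image_name, dir) {
  paths <- character(0)
  for (ch in names(masks)) {
    path <- file.path(dir, paste0(image_name, "_", ch, "_thresholded.png"))
    png::writePNG(ifelse(masks[[ch]], 1, 0), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# One analysis unit = one single image or one projection of a stack.
units_from_file <- function(path, config) {
  loaded <- load_image(path)
  if (inherits(loaded, "zstack")) {
    projs <- grouped_max_projection(loaded, config$group_size)
    lapply(projs, function(p) {
      img <- to_rgb(p, config$mapping)
      img$name <- sprintf("%s_proj%d", img$name, p$projection_index)
      img
    })
  } else {
    list(to_rgb(loaded, config$mapping))
  }
}

analyze_unit <- function(img, config, threshold_table = NULL) {
  chans <- active_channels(config$mapping)
  masks <- list()
  records_th <- list()
  puncta <- list()
  for (ch in chans) {
    plane <- preprocess_plane(img$planes[[ch]], config$preprocess)
    mask <- threshold_channel(plane, config, img$name, ch, threshold_table)
    masks[[ch]] <- mask
    records_th[[ch]] <- attr(mask, "threshold_record")
    puncta[[ch]] <- detect_puncta(mask, channel = ch,
                                  min_size = config$min_size,
                                  max_size = config$max_size,
                                  roi = config$roi)
  }
  coloc <- if (config$analysis_mode == "circular") {
    circular_colocalize_image(puncta$red, puncta$green, img$name)
  } else {
    pixel_colocalize_image(masks$red, masks$green, masks$blue,
                           min_size = config$coloc_min_size,
                           roi = config$roi, image_name = img$name)
  }
  th_rec <- do.call(rbind, unname(records_th))
  thr_of <- function(ch) {
    if (!ch %in% chans) return(NA_character_)
    r <- records_th[[ch]]
    if (is.na(r$value)) r$method else as.character(r$value)
  }
  summary_row <- data.frame(
    image = img$name,
    n_red = nrow(puncta$red), n_green = nrow(puncta$green),
    n_blue = if ("blue" %in% chans) nrow(puncta$blue) else NA_integer_,
    n_coloc_records = nrow(coloc),
    n_coloc_dedup = dedup_coloc_count(coloc),
    red_threshold = thr_of("red"), green_threshold = thr_of("green"),
    blue_threshold = thr_of("blue"),
    min_size = config$min_size, max_size = config$max_size,
    roi_area = roi_area(config$roi, img$width, img$height),
    stringsAsFactors = FALSE)
  list(image = img, masks = masks, puncta = puncta, coloc = coloc,
       thresholds = th_rec, summary = summary_row)
}

#' Run a batch synapse-quantification experiment
#'
#' Walks every subfolder of the experiment directory (non-recursively;
#' extensions `.tif`, `.tiff`, `.png`), analyzes each image — or each
#' grouped max-projection of each z-stack — with the configured
#' preprocessing, thresholding, particle detection and colocalization, and
#' writes all output artifacts to `output_dir`:
#'
#' * `Summary.csv` — one row per analyzed image/projection with puncta and
#'   colocalization counts (per-pair records and the deduplicated count
#'   side by side), the thresholds used, size settings and ROI area;
#' * `thresholds.csv` — the threshold audit table; feeding it back with
#'   `threshold$method = "from_file"` reproduces the run exactly;
#' * `red_puncta.csv` / `green_puncta.csv` (/ `blue_puncta.csv`) — every
#'   individual punctum with coordinates, area and circularity;
#' * `coloc_puncta.csv` — every colocalization record;
#' * per image, a `<name>_colocs.png` feedback overlay and
#'   `<name>_<channel>_thresholded.png` masks;
#' * `run_log.yaml` — configuration echo, package version, seed and
#'   per-image status.
#'
#' Images that fail (for example names with more than one `"."`) are
#' skipped; processing continues and the failures are listed in the run log
#' and in the returned object.
#'
#' @param config a [run_config()] or path to a YAML configuration.
#' @return invisibly, a list with `summary`, `thresholds`, `failures` and
#'   `output_dir`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  subdirs <- list.dirs(config$experiment_dir, recursive = FALSE)
  if (length(subdirs) == 0L)
    stop("the experiment directory must include at least one subfolder of ",
         "images: '", config$experiment_dir, "' has none", call. = FALSE)
  files <- unlist(lapply(subdirs, function(d)
    list.files(d, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
               full.names = TRUE)))
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)

  threshold_table <- NULL
  if (config$threshold$method == "from_file")
    threshold_table <- thresholds_from_file(config$threshold$file)

  chans <- active_channels(config$mapping)
  summaries <- list(); th_all <- list(); coloc_all <- list()
  puncta_all <- setNames(vector("list", length(chans)), chans)
  failures <- character(0); status <- list()
  for (f in files) {
    res <- tryCatch({
      units <- units_from_file(f, config)
      for (u in units) {
        a <- analyze_unit(u, config, threshold_table)
        summaries[[length(summaries) + 1L]] <- a$summary
        th_all[[length(th_all) + 1L]] <- a$thresholds
        coloc_all[[length(coloc_all) + 1L]] <- a$coloc
        for (ch in chans) {
          p <- a$puncta[[ch]]
          p$pixels <- NULL
          p <- data.frame(image = rep(u$name, nrow(p)), p,
                          stringsAsFactors = FALSE)
          puncta_all[[ch]][[length(puncta_all[[ch]]) + 1L]] <- p
        }
        render_overlay(u, a$coloc, config$output_dir,
                       config$overlay_radius)
        write_thresholded_channels(a$masks, u$name, config$output_dir)
      }
      "ok"
    }, error = function(e) conditionMessage(e))
    status[[basename(f)]] <- res
    if (!identical(res, "ok")) failures <- c(failures, basename(f))
  }

  summary_df <- do.call(rbind, summaries)
  th_df <- do.call(rbind, th_all)
  coloc_df <- do.call(rbind, coloc_all)
  write_csv_commented(summary_df, file.path(config$output_dir,
                                            "Summary.csv"))
  write_csv_commented(th_df, file.path(config$output_dir, "thresholds.csv"))
  write_csv_commented(coloc_df, file.path(config$output_dir,
                                          "coloc_puncta.csv"))
  for (ch in chans) {
    df <- do.call(rbind, puncta_all[[ch]])
    if (is.null(df))
      df <- data.frame(image = character(0), channel = character(0),
                       id = integer(0), x = numeric(0), y = numeric(0),
                       area = numeric(0), equiv_radius = numeric(0),
                       circularity = numeric(0))
    write_csv_commented(df, file.path(config$output_dir,
                                      paste0(ch, "_puncta.csv")))
  }
  log <- list(package = "punctacoloc",
              version = as.character(packageVersion("punctacoloc")),
              seed = config$seed,
              analysis_mode = config$analysis_mode,
              threshold_method = config$threshold$method,
              group_size = config$group_size,
              min_size = config$min_size,
              n_images_analyzed = if (is.null(summary_df)) 0L
                                  else nrow(summary_df),
              failures = as.list(failures),
              status = status)
  yaml::write_yaml(log, file.path(config$output_dir, "run_log.yaml"))
  if (length(failures) > 0L)
    warning("analysis failed for: ", paste(failures, collapse = ", "),
            call. = FALSE)
  invisible(list(summary = summary_df, thresholds = th_df,
                 coloc = coloc_df, failures = failures,
                 output_dir = config$output_dir))
}
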