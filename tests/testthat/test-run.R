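# Build a small experiment directory: two subfolders of single-plane
# two-channel TIFFs containing a few discs with known overlaps.
make_experiment <- function(root, n_per_folder = 3) {
  k <- 0
  for (sub in c("groupA", "groupB")) {
    dir.create(file.path(root, sub), recursive = TRUE)
    for (i in seq_len(n_per_folder)) {
      k <- k + 1
      red <- matrix(0L, 64, 64); green <- matrix(0L, 64, 64)
      red[raster_disc(64, 64, 15 + k, 15, 4)] <- 180L
      green[raster_disc(64, 64, 17 + k, 15, 4)] <- 160L  # overlaps red
      red[raster_disc(64, 64, 45, 45, 3)] <- 140L        # red-only punctum
      arr <- array(0, c(64, 64, 3))
      arr[, , 1] <- red / 255; arr[, , 2] <- green / 255
      tiff::writeTIFF(arr, file.path(root, sub,
                                     sprintf("%s_im%d.tif", sub, k)),
                      bits.per.sample = 8L)
    }
  }
}

base_config <- function(exp_dir, out_dir, ...) {
  run_config(experiment_dir = exp_dir, output_dir = out_dir,
             mapping = channel_mapping(1, 2),
             threshold = list(method = "fixed",
                              value = c(red = 50, green = 50)),
             analysis_mode = "pixel", ...)
}

test_that("a batch run produces one summary row per image and all artifacts", {
  root <- withr::local_tempdir()
  exp_dir <- file.path(root, "exp"); out_dir <- file.path(root, "out")
  make_experiment(exp_dir)
  res <- run_experiment(base_config(exp_dir, out_dir))
  expect_equal(nrow(res$summary), 6L)
  expect_true(all(res$summary$n_red == 2))
  expect_true(all(res$summary$n_green == 1))
  expect_true(all(res$summary$n_coloc_records == 1))
  expect_true(all(res$summary$n_coloc_dedup <= res$summary$n_coloc_records))
  expect_equal(nrow(res$thresholds), 12L)  # 6 images x 2 channels
  for (f in c("Summary.csv", "thresholds.csv", "coloc_puncta.csv",
              "red_puncta.csv", "green_puncta.csv", "run_log.yaml"))
    expect_true(file.exists(file.path(out_dir, f)))
  for (nm in res$summary$image) {
    expect_true(file.exists(file.path(out_dir, paste0(nm, "_colocs.png"))))
    expect_true(file.exists(file.path(out_dir,
                                      paste0(nm, "_red_thresholded.png"))))
  }
  # puncta CSV row counts agree with the summary counts
  red_tbl <- read.csv(file.path(out_dir, "red_puncta.csv"),
                      comment.char = "#")
  expect_equal(nrow(red_tbl), sum(res$summary$n_red))
})

test_that("z-stacks expand into one summary row per projection", {
  root <- withr::local_tempdir()
  exp_dir <- file.path(root, "exp"); out_dir <- file.path(root, "out")
  dir.create(file.path(exp_dir, "stacks"), recursive = TRUE)
  planes <- lapply(1:15, function(z) {
    red <- matrix(0L, 32, 32)
    red[raster_disc(32, 32, 16, 16, 3)] <- as.integer(50 + 10 * z)
    array(c(red, red) / 255, c(32, 32, 2))
  })
  tiff::writeTIFF(planes, file.path(exp_dir, "stacks", "vivo1.tif"),
                  bits.per.sample = 8L)
  res <- run_experiment(base_config(exp_dir, out_dir, group_size = 3))
  expect_equal(nrow(res$summary), 5L)
  expect_equal(res$summary$image,
               paste0("vivo1_proj", 1:5))
})

test_that("rerunning from the emitted threshold file reproduces Summary.csv byte-identically", {
  root <- withr::local_tempdir()
  exp_dir <- file.path(root, "exp")
  make_experiment(exp_dir)
  out1 <- file.path(root, "out1"); out2 <- file.path(root, "out2")
  run_experiment(base_config(exp_dir, out1))
  cfg2 <- base_config(exp_dir, out2)
  cfg2$threshold <- list(method = "from_file",
                         file = file.path(out1, "thresholds.csv"))
  run_experiment(cfg2)
  s1 <- readBin(file.path(out1, "Summary.csv"), "raw",
                file.size(file.path(out1, "Summary.csv")))
  s2 <- readBin(file.path(out2, "Summary.csv"), "raw",
                file.size(file.path(out2, "Summary.csv")))
  expect_identical(s1, s2)
})

test_that("directory contract violations are reported", {
  root <- withr::local_tempdir()
  empty <- file.path(root, "empty"); dir.create(empty)
  expect_error(run_experiment(base_config(empty, file.path(root, "o"))),
               "at least one subfolder")
  # a file with two dots is skipped and listed, the rest still run
  exp_dir <- file.path(root, "exp")
  make_experiment(exp_dir, n_per_folder = 1)
  bad <- file.path(exp_dir, "groupA", "conv.lif.tif")
  tiff::writeTIFF(matrix(0, 8, 8), bad)
  res <- suppressWarnings(
    run_experiment(base_config(exp_dir, file.path(root, "out"))))
  expect_equal(res$failures, "conv.lif.tif")
  expect_equal(nrow(res$summary), 2L)
})

test_that("overlay rendering marks each record with one white disc", {
  img <- rgb_image("ov", matrix(30L, 64, 64), matrix(30L, 64, 64))
  d <- withr::local_tempdir()
  # zero records: output pixel-identical to input
  render_overlay(img, data.frame(center_x = numeric(0),
                                 center_y = numeric(0)), d)
  back <- png::readPNG(file.path(d, "ov_colocs.png"))
  expect_true(all(abs(back[, , 1] * 255 - 30) < 0.5))
  # records appear as white discs countable on the difference image
  rec <- data.frame(center_x = c(10, 40, 22), center_y = c(12, 45, 30))
  render_overlay(img, rec, d, radius = 3)
  over <- png::readPNG(file.path(d, "ov_colocs.png"))
  diffmask <- over[, , 1] * 255 > 200
  expect_equal(length(flood_fill_components(diffmask)), nrow(rec))
  expect_true(diffmask[13, 11])  # disc centred at (x=10, y=12), 1-based
})

test_that("thresholded masks round-trip losslessly through PNG", {
  set.seed(6)
  mask <- matrix(runif(32 * 32) < 0.4, 32, 32)
  d <- withr::local_tempdir()
  write_thresholded_channels(list(red = mask), "img", d)
  path <- file.path(d, "img_red_thresholded.png")
  expect_true(file.exists(path))
  back <- png::readPNG(path) == 1
  expect_identical(back, mask)
})

test_that("YAML configs round-trip into run_config", {
  root <- withr::local_tempdir()
  cfgfile <- file.path(root, "config.yaml")
  yaml::write_yaml(list(experiment_dir = "exp", output_dir = "out",
                        channels = list(red = 1, green = 2),
                        threshold = list(method = "fixed",
                                         value = list(red = 60, green = 70)),
                        roi = list(kind = "circle", cx = 100, cy = 120,
                                   radius = 301),
                        analysis_mode = "circular", group_size = 3,
                        min_size = 4, seed = 7),
                   cfgfile)
  cfg <- read_run_config(cfgfile)
  expect_equal(cfg$threshold$value[["green"]], 70)
  expect_equal(cfg$roi$radius, 301)
  expect_equal(cfg$analysis_mode, "circular")
  expect_equal(cfg$seed, 7L)
})
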