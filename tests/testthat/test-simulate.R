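test_that("template synthesis is deterministic with the stated profile", {
  cfg <- tiny_sim_config()
  t1 <- make_templates(cfg, seed = 4)
  t2 <- make_templates(cfg, seed = 4)
  expect_identical(t1, t2)
  expect_length(t1$red, cfg$n_templates_per_channel)
  for (s in c(t1$red, t1$green)) {
    expect_equal(max(s), attr(s, "peak"))  # stamp max is the sampled peak
    expect_gt(sum(s), 0)
    expect_equal(nrow(s), 2L * attr(s, "radius") + 1L)
  }
  # degenerate ranges give identical stamps
  cfg2 <- tiny_sim_config(template_radius_range = c(3L, 3L),
                          template_peak_range = c(200L, 200L))
  t3 <- make_templates(cfg2, seed = 1)
  expect_true(all(vapply(t3$red, identical, logical(1), t3$red[[1]])))
  expect_equal(max(t3$red[[1]]), 200)
})

test_that("gaussian background respects multiplier, statistics and seed", {
  z <- gaussian_background(64, 64, 20, 12, 0)
  expect_true(all(z == 0L))
  # CLT at a mean far from the clipping boundary
  g <- gaussian_background(512, 512, 100, 12, 1, seed = 8)
  expect_lt(abs(mean(g) - 100), 3 * 12 / sqrt(512^2))
  # at the default (20, 12) clipping at zero biases the mean slightly up
  g2 <- gaussian_background(512, 512, 20, 12, 1, seed = 8)
  expect_gt(mean(g2), 19.9)
  expect_lt(mean(g2), 21)
  expect_identical(gaussian_background(32, 32, 20, 12, 0.5, seed = 3),
                   gaussian_background(32, 32, 20, 12, 0.5, seed = 3))
})

test_that("generated images carry exact ground truth and reproduce by seed", {
  cfg <- tiny_sim_config()
  sim <- generate_simulated_image(cfg, 0.25, seed = 5)
  counts <- table(sim$truth$class)
  expect_equal(unname(counts[c("red_only", "green_only", "both")]),
               c(20L, 20L, 20L), ignore_attr = TRUE)
  sim2 <- generate_simulated_image(cfg, 0.25, seed = 5)
  expect_identical(sim$image$planes, sim2$image$planes)
  expect_identical(sim$truth, sim2$truth)
  # anchors keep every stamp fully inside the image
  tmpl <- make_templates(cfg)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    if (!is.na(tr$template_red)) {
      s <- nrow(tmpl$red[[tr$template_red]])
      expect_true(tr$anchor_x + s <= cfg$width)
      expect_true(tr$anchor_y + s <= cfg$height)
    }
  }
  # minimal allocation
  cfg3 <- simulation_config(width = 64, height = 64, n_red_only = 1,
                            n_green_only = 1, n_both = 1, seed = 2)
  sim3 <- generate_simulated_image(cfg3, 0, seed = 2)
  expect_equal(sort(sim3$truth$class),
               c("both", "green_only", "red_only"))
})

test_that("same-channel bounding boxes never overlap", {
  cfg <- tiny_sim_config()
  tmpl <- make_templates(cfg)
  sim <- generate_simulated_image(cfg, 0, seed = 13)
  for (ch in c("red", "green")) {
    tcol <- paste0("template_", ch)
    rows <- sim$truth[!is.na(sim$truth[[tcol]]), ]
    cover <- matrix(0L, cfg$height, cfg$width)
    for (i in seq_len(nrow(rows))) {
      s <- nrow(tmpl[[ch]][[rows[[tcol]][i]]])
      ys <- (rows$anchor_y[i] + 1):(rows$anchor_y[i] + s)
      xs <- (rows$anchor_x[i] + 1):(rows$anchor_x[i] + s)
      cover[ys, xs] <- cover[ys, xs] + 1L
    }
    expect_true(all(cover <= 1L))
  }
})

test_that("an image too crowded to place every box errors out", {
  cfg <- simulation_config(width = 40, height = 40, n_red_only = 100,
                           n_green_only = 100, n_both = 100, seed = 1)
  expect_error(generate_simulated_image(cfg, 0, seed = 1), "larger image")
})

test_that("benchmark sets have the configured layout and write a manifest", {
  cfg <- tiny_sim_config(noise_multipliers = 0, n_images_per_level = 1L)
  d <- withr::local_tempdir()
  out <- generate_benchmark_set(cfg, out_dir = d)
  expect_equal(nrow(out$manifest), 1L)
  expect_true(file.exists(file.path(d, out$manifest$file[1])))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_equal(unname(out$class_counts[1, ]), c(20L, 20L, 20L))
  # round-trip: the written TIFF reloads to the generated planes
  img <- load_image(file.path(d, out$manifest$file[1]))
  sim <- generate_simulated_image(cfg, 0, seed = out$manifest$seed[1],
                                  templates = make_templates(cfg),
                                  name = "x")
  expect_equal(img$data[, , 1], unclass(sim$image$planes$red),
               ignore_attr = TRUE)
})

test_that("scoring obeys the bookkeeping identities and matches brute force", {
  truth <- data.frame(class = "both", cx = c(10, 30), cy = c(10, 30))
  # perfect detections
  det <- data.frame(center_x = c(10, 30), center_y = c(10, 30))
  s <- match_and_score(det, truth, tolerance = 5)
  expect_equal(s[c("tp", "fp", "fn")], list(tp = 2L, fp = 0L, fn = 0L))
  expect_equal(s$recall, 1); expect_equal(s$precision, 1)
  # no detections
  s0 <- match_and_score(det[0, ], truth, tolerance = 5)
  expect_equal(s0$recall, 0); expect_equal(s0$fn, 2L)
  expect_equal(s0$precision, 1)  # convention when tp + fp = 0
  # 2 truths, 3 detections, 2 within tolerance: greedy equals the optimum
  det3 <- data.frame(center_x = c(11, 29, 100), center_y = c(9, 31, 100))
  s3 <- match_and_score(det3, truth, tolerance = 5)
  dmat <- sqrt(outer(det3$center_x, truth$cx, "-")^2 +
               outer(det3$center_y, truth$cy, "-")^2)
  expect_equal(s3$tp, max_matching_size(dmat, 5))
  expect_equal(s3$tp, 2L); expect_equal(s3$fp, 1L)
  expect_equal(s3$recall, 1); expect_equal(s3$precision, 2 / 3)
  # identities: tp + fn = truths, tp + fp = detections
  set.seed(44)
  for (rep in 1:10) {
    tr <- data.frame(class = "both", cx = runif(5, 0, 50),
                     cy = runif(5, 0, 50))
    de <- data.frame(center_x = runif(7, 0, 50), center_y = runif(7, 0, 50))
    sc <- match_and_score(de, tr, tolerance = 8)
    expect_equal(sc$tp + sc$fn, 5L)
    expect_equal(sc$tp + sc$fp, 7L)
    dm <- sqrt(outer(de$center_x, tr$cx, "-")^2 +
               outer(de$center_y, tr$cy, "-")^2)
    expect_lte(sc$tp, max_matching_size(dm, 8))
    if (!any(dm <= 8)) expect_equal(sc$tp, 0L)
  }
})
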