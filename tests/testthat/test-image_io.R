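test_that("single-page and multi-page TIFFs load as image and z-stack", {
  d <- withr::local_tempdir()
  # 2-channel single page
  p1 <- matrix(10L, 8, 8); p2 <- matrix(200L, 8, 8)
  arr <- array(c(p1, p2) / 255, c(8, 8, 2))
  tiff::writeTIFF(arr, file.path(d, "im1.tif"), bits.per.sample = 8L)
  img <- load_image(file.path(d, "im1.tif"))
  expect_s3_class(img, "mc_image")
  expect_equal(dim(img$data), c(8, 8, 2))
  expect_equal(img$name, "im1")

  # 15-page stack, as acquired for a 5 um z-range
  planes <- lapply(1:15, function(k) matrix(k, 8, 8))
  write_stack_tiff(planes, file.path(d, "stack.tif"))
  st <- load_image(file.path(d, "stack.tif"))
  expect_s3_class(st, "zstack")
  expect_equal(st$n_planes, 15L)
})

test_that("file names with more than one dot are rejected", {
  d <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0, 4, 4), file.path(d, "image1.lif.tif"))
  expect_error(load_image(file.path(d, "image1.lif.tif")),
               "only one '\\.' character")
  expect_error(load_image(file.path(d, "missing.tif")), "not found")
})

test_that("to_rgb rescales by the nominal bit-depth range with half-up rounding", {
  mk <- function(vals, bits) {
    structure(list(name = "im", data = array(vals, c(4, 4, 2)),
                   bits = bits, projection_index = NULL),
              class = "mc_image")
  }
  # 8-bit input is passed through unchanged (idempotence)
  img8 <- to_rgb(mk(c(rep(7, 16), rep(250, 16)), 8L), channel_mapping(1, 2))
  expect_true(all(img8$planes$red == 7))
  expect_true(all(img8$planes$green == 250))
  # 16-bit full scale -> 255; mid scale 32768 -> round(32768*255/65535) = 128
  img16 <- to_rgb(mk(c(rep(65535, 16), rep(32768, 16)), 16L),
                  channel_mapping(1, 2))
  expect_true(all(img16$planes$red == 255))
  expect_true(all(img16$planes$green == 128))
  # unassigned blue role becomes an all-zero plane
  expect_true(all(img16$planes$blue == 0))
  # mapping to a nonexistent channel errors
  expect_error(to_rgb(mk(rep(0, 32), 8L), channel_mapping(1, 3)),
               "only 2 channel")
})

test_that("channel mapping validates roles", {
  expect_error(channel_mapping(red = 1, green = 1), "at most one role")
  m <- channel_mapping(red = 2, green = 1, blue = 3)
  expect_equal(m$mode, "three-channel")
})

test_that("grouped max projection partitions planes and takes the maximum", {
  mkstack <- function(planes) {
    structure(list(name = "s", n_planes = length(planes),
                   planes = lapply(planes, function(p)
                     array(p, c(dim(p), 1L))),
                   bits = 8L, z_step = NULL), class = "zstack")
  }
  # 15 planes, groups of 3 -> 5 projections
  st <- mkstack(lapply(1:15, function(k) matrix(k, 4, 4)))
  projs <- grouped_max_projection(st, 3L)
  expect_length(projs, 5L)
  expect_equal(vapply(projs, function(p) p$data[1, 1, 1], numeric(1)),
               c(3, 6, 9, 12, 15))
  # group_size 1 is the identity
  st4 <- mkstack(lapply(c(4, 9, 2, 7), function(k) matrix(k, 3, 3)))
  projs1 <- grouped_max_projection(st4, 1L)
  expect_length(projs1, 4L)
  expect_equal(projs1[[2]]$data[1, 1, 1], 9)
  # max of constants
  st2 <- mkstack(list(matrix(10, 3, 3), matrix(200, 3, 3)))
  expect_true(all(grouped_max_projection(st2, 2L)[[1]]$data == 200))
  # remainder planes dropped with a warning
  expect_warning(p7 <- grouped_max_projection(mkstack(
    lapply(1:7, function(k) matrix(k, 2, 2))), 3L), "dropped")
  expect_length(p7, 2L)
  expect_error(grouped_max_projection(st2, 0L), "positive")
})

test_that("projection equals the per-pixel group maximum and count formula holds", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(2:10, 1)
    g <- sample(1:4, 1)
    planes <- lapply(seq_len(n), function(k)
      array(matrix(sample(0:255, 36, TRUE), 6, 6), c(6, 6, 1)))
    st <- structure(list(name = "s", n_planes = n, planes = planes,
                         bits = 8L, z_step = NULL), class = "zstack")
    projs <- suppressWarnings(grouped_max_projection(st, g))
    expect_length(projs, n %/% g)
    for (k in seq_along(projs)) {
      idx <- ((k - 1) * g + 1):(k * g)
      expected <- Reduce(pmax, planes[idx])
      expect_equal(projs[[k]]$data, expected)
    }
  }
  # exhaustive projection-count formula
  for (n in 1:20) for (g in 1:6) {
    planes <- rep(list(array(0, c(2, 2, 1))), n)
    st <- structure(list(name = "s", n_planes = n, planes = planes,
                         bits = 8L, z_step = NULL), class = "zstack")
    expect_length(suppressWarnings(grouped_max_projection(st, g)), n %/% g)
  }
})

test_that("rgb_image enforces its invariants", {
  m <- matrix(1L, 4, 4)
  expect_error(rgb_image("a.b", m, m), "must not contain")
  expect_error(rgb_image("a", m, matrix(1L, 5, 5)), "same shape")
  expect_error(rgb_image("a", m, matrix(300L, 4, 4)), "\\[0, 255\\]")
  img <- rgb_image("a", m, m)
  expect_equal(img$width, 4L)
  expect_true(all(img$planes$blue == 0L))
})
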