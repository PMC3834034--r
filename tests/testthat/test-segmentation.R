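test_that("green-channel extraction is exact channel indexing", {
  img <- array(0L, dim = c(2, 2, 3))
  img[1, 1, ] <- c(0L, 255L, 0L)     # pure green
  img[1, 2, ] <- c(200L, 60L, 60L)   # droplet colour
  img[2, 1, ] <- c(235L, 225L, 230L) # background colour
  g <- extract_green_channel(img)
  expect_identical(g[1, 1], 255L)
  expect_identical(g[1, 2], 60L)
  expect_identical(g[2, 1], 225L)
  expect_lt(g[1, 2], g[2, 1])        # stain darker than background in green

  spec <- make_spec(seed = 2, n_droplets = 10, noise_sd = 5)
  sec <- generate_section_image(spec)
  expect_identical(g <- extract_green_channel(sec$image),
                   {
                     oracle <- sec$image[, , 2]
                     storage.mode(oracle) <- "integer"
                     oracle
                   })
  expect_error(extract_green_channel(matrix(0, 2, 2)), "3-channel")
})

test_that("contrast enhancement is a monotone full-range percentile rescale", {
  # constant image: documented no-op
  const <- matrix(100L, 10, 10)
  expect_identical(enhance_contrast(const), const)

  # two-valued image maps onto the 8-bit extremes (closed-form rescale)
  two <- matrix(rep(c(50L, 200L), each = 200), 20)
  out <- enhance_contrast(two, segmentation_config(1, 99))
  expect_setequal(unique(as.vector(out)), c(0L, 255L))
  expect_true(all(out[two == 50L] == 0L) && all(out[two == 200L] == 255L))

  # non-constant input spans the full range; ordering preserved
  set.seed(1)
  g <- matrix(sample(40:210, 400, replace = TRUE), 20)
  out <- enhance_contrast(g, segmentation_config(1, 99))
  expect_equal(range(out), c(0, 255))
  u <- sort(unique(as.vector(g)))
  mapped <- vapply(u, function(v) out[which(g == v)[1]], integer(1))
  expect_true(all(diff(mapped) >= 0))
})

test_that("automatic threshold equals the exhaustive between-class-variance oracle", {
  # two delta peaks: threshold strictly between them
  bi <- matrix(c(rep(60L, 150), rep(225L, 250)), 20)
  k <- otsu_threshold(bi)
  thr <- attr(threshold_objects(bi), "threshold")
  expect_gt(thr, 60)
  expect_lt(thr, 225)
  expect_identical(k, otsu_oracle(bi))

  # random and rendered images
  set.seed(7)
  for (i in 1:5) {
    g <- matrix(sample(0:255, 300, replace = TRUE), 15)
    expect_identical(otsu_threshold(g), otsu_oracle(g))
  }
  sec <- generate_section_image(make_spec(seed = i, n_droplets = 15,
                                          noise_sd = 6))
  g <- enhance_contrast(extract_green_channel(sec$image))
  expect_identical(otsu_threshold(g), otsu_oracle(g))

  expect_error(otsu_threshold(matrix(7L, 3, 3)), "fixed")
})

test_that("thresholding picks the dark (stained) class", {
  # constant image with a fixed threshold below it: empty mask
  const <- matrix(100L, 8, 8)
  m <- threshold_objects(const, segmentation_config(threshold_mode = 50))
  expect_false(any(m))

  # single rendered disk: foreground area within a 1-px perimeter ring
  spec <- synthetic_image_spec(field_width_px = 64L, field_height_px = 64L,
                               n_droplets = 1, radius_median_um = 5,
                               radius_sigma_log = 0, seed = 4)
  sec <- generate_section_image(spec)           # r = 10 px exactly
  g <- extract_green_channel(sec$image)
  m <- threshold_objects(g, segmentation_config(threshold_mode = 128))
  expect_lt(abs(sum(m) - pi * 100), 2 * pi * 10)
})

test_that("component labeling is 8-connected with consecutive labels", {
  mask <- matrix(FALSE, 6, 6)
  mask[2, 2] <- TRUE; mask[3, 3] <- TRUE    # diagonal touch: one object
  mask[5, 5] <- TRUE; mask[5, 6] <- TRUE    # separate object
  lab <- label_components(mask)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
  expect_setequal(unique(as.vector(lab)), 0:2)
  expect_equal(max(label_components(matrix(FALSE, 4, 4))), 0)
})

test_that("artifact filtering removes specks, streaks and border objects", {
  cfg <- segmentation_config(min_area_px = 4)
  # empty mask
  expect_equal(filter_artifacts(matrix(FALSE, 32, 32), cfg)$n_objects, 0)

  # disk + 2-px speck: only the disk survives the area bound
  m <- disk_mask(64, 30, 30, 10)
  m[2, 2] <- TRUE; m[2, 3] <- TRUE
  lm <- filter_artifacts(m, cfg)
  expect_equal(lm$n_candidates, 2)
  expect_equal(lm$n_objects, 1)

  # disk + 40x4 streak at min_circularity 0.6: streak removed
  m2 <- disk_mask(96, 30, 30, 10)
  m2[70:73, 20:59] <- TRUE
  lab <- label_components(m2)
  stats_df <- liverLD:::component_stats(lab)
  circ <- 4 * pi * stats_df$area_px / (stats_df$edges * pi / 4)^2
  expect_true(any(circ < 0.6) && any(circ > 0.6))  # streak below, disk above
  lm2 <- filter_artifacts(m2, segmentation_config(min_circularity = 0.6))
  expect_equal(lm2$n_objects, 1)

  # border policy: disk touching the edge is excluded, then included
  m3 <- disk_mask(64, 0, 30, 8)
  expect_equal(filter_artifacts(m3, cfg)$n_objects, 0)
  expect_equal(
    filter_artifacts(m3, segmentation_config(border_policy = "include"))$n_objects,
    1)

  # idempotence: filtering an already-filtered mask changes nothing
  once <- filter_artifacts(m2, cfg)
  twice <- filter_artifacts(once$labels > 0, cfg)
  expect_identical(once$labels, twice$labels)
})

test_that("the full sequence recovers ground truth and ignores distractors", {
  spec <- make_spec(seed = 31, n_droplets = 50, field = 512L)
  sec <- generate_section_image(spec)
  lm <- segment(sec)
  expect_equal(lm$n_objects, 50)

  # pure background
  bg <- generate_section_image(make_spec(seed = 1, n_droplets = 0))
  expect_equal(segment(bg)$n_objects, 0)

  # same field with 5 streak + speck artifacts: still 50 objects
  spec_art <- make_spec(seed = 31, n_droplets = 50, field = 512L,
                        n_artifacts = 5)
  lm_art <- segment(generate_section_image(spec_art))
  expect_equal(lm_art$n_objects, 50)
})

test_that("images and masks round-trip through TIFF/PNG on disk", {
  sec <- generate_section_image(make_spec(seed = 55, n_droplets = 8,
                                          field = 96L))
  for (ext in c(".tif", ".png")) {
    path <- withr::local_tempfile(fileext = ext)
    write_section_image(sec, path)
    expect_identical(read_section_image(path), sec$image)
  }
  lm <- segment(sec)
  tif <- withr::local_tempfile(fileext = ".tif")
  log <- withr::local_tempfile(fileext = ".csv")
  write_labeled_mask(lm, tif, log)
  back <- round(tiff::readTIFF(tif) * 65535)
  expect_equal(back, unclass(lm$labels), ignore_attr = TRUE)
  run_log <- read.csv(log)
  expect_equal(run_log$n_objects, lm$n_objects)
})

test_that("recovery holds across seeds and survives noise", {
  for (seed in 1:25) {
    sec <- generate_section_image(make_spec(seed = seed, n_droplets = 15))
    expect_equal(segment(sec)$n_objects, 15)
  }
  tp <- 0; nd <- 0; nt <- 0
  for (seed in 1:10) {
    sec <- generate_section_image(make_spec(seed = seed, n_droplets = 15,
                                            noise_sd = 10))
    res <- analyze_section(sec)
    m <- match_to_ground_truth(res$features, sec$truth)
    tp <- tp + m$n_matched; nd <- nd + m$n_detected; nt <- nt + m$n_truth
  }
  expect_gte(tp / nt, 0.95)   # recall
  expect_gte(tp / nd, 0.95)   # precision
})
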