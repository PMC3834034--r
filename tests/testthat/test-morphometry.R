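test_that("per-object features have closed-form values on simple shapes", {
  # single pixel at 1 um/px
  lab <- matrix(0L, 8, 8); lab[4, 4] <- 1L
  f <- measure_droplets(make_labeled_mask(lab))
  expect_equal(f$area_um2, 1)
  expect_equal(f$eq_diameter_um, 2 / sqrt(pi))
  expect_equal(f$convex_area_um2, 1)
  expect_equal(c(f$cx_um, f$cy_um), c(3, 3))  # 0-based pixel centre

  # 10x10 filled square: convex shape, convex area equals area
  lab2 <- matrix(0L, 20, 20); lab2[5:14, 5:14] <- 1L
  f2 <- measure_droplets(make_labeled_mask(lab2))
  expect_equal(f2$area_um2, 100)
  expect_equal(f2$convex_area_um2, f2$area_um2)

  # rasterized disk r = 10 px at 0.5 um/px: area within 5% of pi * 5^2
  m <- disk_mask(64, 30, 30, 10)
  lm <- filter_artifacts(m, segmentation_config(), pixel_size_um = 0.5)
  f3 <- measure_droplets(lm)
  expect_lt(abs(f3$area_um2 - pi * 25) / (pi * 25), 0.05)
  expect_gte(f3$convex_area_um2, f3$area_um2)
  # corrected crack perimeter is close to the true circumference 2*pi*5
  expect_lt(abs(f3$perimeter_um - 2 * pi * 5) / (2 * pi * 5), 0.1)

  expect_error(measure_droplets(make_labeled_mask(lab, pixel_size_um = NA)),
               "calibration")
})

test_that("equivalent-diameter identity holds to machine precision", {
  sec <- generate_section_image(make_spec(seed = 13, n_droplets = 25))
  f <- analyze_section(sec)$features
  expect_equal(f$eq_diameter_um^2 * pi / 4, f$area_um2, tolerance = 1e-12)
  expect_true(all(f$area_um2 <= f$convex_area_um2 + 1e-9))
  expect_true(all(f$area_um2 > 0 & f$perimeter_um > 0))
})

test_that("nearest-neighbour distances match geometry and the exhaustive oracle", {
  # two points 3 um apart
  expect_equal(nearest_neighbor_distances(cbind(c(0, 3), c(0, 0))),
               c(3, 3))
  # unit-square corners: nearest is the side, not the diagonal
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(nearest_neighbor_distances(sq), rep(1, 4))
  # 50 random points vs O(n^2) double loop
  set.seed(99)
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  nn <- nearest_neighbor_distances(pts)
  oracle <- vapply(1:50, function(i) {
    best <- Inf
    for (j in 1:50) {
      if (i == j) next
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d < best) best <- d
    }
    best
  }, numeric(1))
  expect_equal(nn, oracle)
  expect_error(nearest_neighbor_distances(cbind(1, 1)), "at least 2")
})

test_that("field summaries define area percent and flag empty fields", {
  empty <- measure_droplets(make_labeled_mask(matrix(0L, 4, 4)))
  s0 <- summarize_field(empty, 1000)
  expect_equal(s0$count, 0)
  expect_equal(s0$area_percent, 0)
  expect_true(is.na(s0$mean_size_um2))

  one <- data.frame(label = 1L, area_um2 = 50, eq_diameter_um = 2,
                    perimeter_um = 8, convex_area_um2 = 50,
                    cx_um = 1, cy_um = 1)
  expect_equal(summarize_field(one, 1000)$area_percent, 5)

  sec <- generate_section_image(make_spec(seed = 17, n_droplets = 12))
  res <- analyze_section(sec)
  expect_equal(res$summary$total_area_um2, sum(res$features$area_um2))
})

test_that("spherical volume and its fold relations are exact", {
  expect_equal(spherical_volume(0), 0)
  expect_equal(spherical_volume(1), pi / 6)
  expect_error(spherical_volume(-1), "non-negative")

  # sphere chain: volume fold is the cube of the diameter fold
  dfold <- 1.121
  expect_equal(dfold^3, spherical_volume(1.121) / spherical_volume(1),
               tolerance = 1e-12)
  expect_equal(sphere_diameter_fold(dfold^3), dfold, tolerance = 1e-12)
  # the diameter fold implied by the reported per-droplet volumes matches
  # the reported 12.1% diameter increase at 1-decimal rounding
  expect_equal(round(100 * (sphere_diameter_fold(0.248 / 0.176) - 1), 1),
               12.1)

  # volume per total LD area: product definition and the reported fold
  expect_equal(volume_per_total_area(0, 1.5), 0)
  set.seed(3)
  cnt <- runif(5, 1, 100); vol <- runif(5, 0.1, 2)
  expect_equal(volume_per_total_area(cnt, vol), cnt * vol)
  expect_equal(round(volume_per_total_area(3.7, 0.248) /
                       volume_per_total_area(1, 0.176), 1), 5.2)
})

test_that("group summaries aggregate object -> field -> animal -> group", {
  # 3 animals x 4 fields with constructed field summaries
  fs <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(field_id = i, count = 10 + (i %% 3), total_area_um2 = 100 + i,
               area_percent = 1, mean_size_um2 = 10, mean_diameter_um = 3,
               mean_perimeter_um = 9, mean_convex_area_um2 = 11,
               mean_nn_distance_um = 5)
  }))
  animals <- rep(c("a1", "a2", "a3"), each = 4)
  gs <- group_summary(fs, animals, group = "UK_T1")
  expect_equal(gs$n_animals, 3)
  # SEM across animals, not across the 12 fields
  per_animal_counts <- tapply(fs$count, animals, mean)
  expect_equal(unname(gs$sem[["count"]]),
               stats::sd(per_animal_counts) / sqrt(3))
  expect_equal(unname(gs$mean[["mean_diameter_um"]]), 3)
  expect_equal(gs$mean_volume_um3, spherical_volume(3))
  expect_equal(gs$volume_per_total_area_um3,
               gs$mean[["count"]] * spherical_volume(3))
})

test_that("group fold changes obey the reported decompositions", {
  fs <- function(count, size) {
    data.frame(field_id = 1, count = count, total_area_um2 = count * size,
               area_percent = 1, mean_size_um2 = size,
               mean_diameter_um = 2 * sqrt(size / pi), mean_perimeter_um = 1,
               mean_convex_area_um2 = size, mean_nn_distance_um = 1)
  }
  mk <- function(count, size, g) {
    group_summary(do.call(rbind, replicate(3, fs(count, size),
                                           simplify = FALSE)),
                  paste0("a", 1:3), group = g)
  }
  u <- mk(37, 12.49, "U"); n <- mk(10, 10, "N")
  fc <- group_fold_changes(u, n)
  get <- function(metric) fc$fold[fc$metric == metric]
  # total-area fold = count fold x mean-size fold (equal field areas)
  expect_equal(get("total_area_um2"), get("count") * get("mean_size_um2"),
               tolerance = 1e-12)
  # count fold 3.7 with per-droplet size fold 1.249 gives total-area 4.6
  expect_equal(round(get("total_area_um2"), 1), 4.6)
  expect_equal(round(get("count"), 1), 3.7)
  # sphere chain on the group summaries: volume fold = diameter fold^3
  expect_equal(get("mean_volume_um3"), get("mean_diameter_um")^3,
               tolerance = 1e-12)
  # identical groups
  id <- group_fold_changes(u, u)
  expect_true(all(abs(id$fold - 1) < 1e-12))
  expect_true(all(abs(id$percent) < 1e-9))
})

test_that("two-group image sets recover the generating count and size ratios", {
  cfg <- segmentation_config()
  measure_set <- function(n_droplets, radius_median, seeds) {
    do.call(rbind, lapply(seeds, function(s) {
      sec <- generate_section_image(make_spec(
        seed = s, n_droplets = n_droplets, field = 384L,
        radius_median_um = radius_median, radius_sigma_log = 0.1))
      analyze_section(sec, cfg, field_id = s)$summary
    }))
  }
  # U-like: 3.7x the count, 1.121x the diameter of N-like fields
  fs_u <- measure_set(37, 2.5 * 1.121, seeds = 1:6)
  fs_n <- measure_set(10, 2.5, seeds = 7:12)
  gs_u <- group_summary(fs_u, rep(1:3, each = 2), "U")
  gs_n <- group_summary(fs_n, rep(1:3, each = 2), "N")
  fc <- group_fold_changes(gs_u, gs_n)
  count_fold <- fc$fold[fc$metric == "count"]
  diam_fold <- fc$fold[fc$metric == "mean_diameter_um"]
  expect_lt(abs(count_fold - 3.7) / 3.7, 0.10)
  expect_lt(abs(diam_fold - 1.121) / 1.121, 0.10)
})
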