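#' Per-droplet morphometric features
#'
#' Measures every labeled object in physical units: area (pixel count times
#' the squared pixel size), equivalent diameter `2*sqrt(area/pi)`, perimeter
#' ("circumference"; corrected crack-length estimator, see
#' [filter_artifacts()] for the definition), convex-hull area (hull of the
#' pixel squares, so `convex_area >= area` always holds and a convex pixel
#' shape has `convex_area == area`), and the object centroid (mean of pixel
#' centres; x rightward, y downward, physical coordinates at pixel centres).
#'
#' @param lmask A `labeled_mask` with a positive `pixel_size_um`.
#' @return Data frame with one row per label: `label`, `area_um2`,
#'   `eq_diameter_um`, `perimeter_um`, `convex_area_um2`, `cx_um`, `cy_um`.
#' @export
measure_droplets <- function(lmask) {
  stopifnot(inherits(lmask, "labeled_mask"))
  ps <- lmask$pixel_size_um
  if (is.null(ps) || !is.finite(ps) || ps <= 0) {
    stop("labeled mask is missing a valid pixel calibration", call. = FALSE)
  }
  labels <- lmask$labels
  k <- max(labels)
  if (k == 0L) {
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      eq_diameter_um = numeric(0), perimeter_um = numeric(0),
                      convex_area_um2 = numeric(0),
                      cx_um = numeric(0), cy_um = numeric(0)))
  }
  st <- component_stats(labels)
  h <- nrow(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  px_r <- ((idx - 1L) %% h) + 1L
  px_c <- ((idx - 1L) %/% h) + 1L
  # 0-based pixel-centre coordinates
  x <- px_c - 1; y <- px_r - 1
  cx <- tapply(x, lab, mean)
  cy <- tapply(y, lab, mean)

  convex_area_px <- vapply(seq_len(k), function(l) {
    sel <- lab == l
    xs <- x[sel]; ys <- y[sel]
    # hull over the four corners of each pixel square
    px <- c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5)
    py <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
    hull <- grDevices::chull(px, py)
    hx <- px[hull]; hy <- py[hull]
    j <- c(seq_along(hull)[-1], 1)
    abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  }, numeric(1))

  area_um2 <- st$area_px * ps^2
  data.frame(
    label = st$label,
    area_um2 = area_um2,
    eq_diameter_um = 2 * sqrt(area_um2 / pi),
    perimeter_um = crack_perimeter(st$edges) * ps,
    convex_area_um2 = convex_area_px * ps^2,
    cx_um = as.numeric(cx) * ps,
    cy_um = as.numeric(cy) * ps
  )
}

#' Nearest-neighbour distances between object centroids
#'
#' Euclidean centroid-to-centroid distance from each object to its nearest
#' other object; the field-level spatial dispersion statistic reported for
#' lipid droplets.
#'
#' @param centroids Two-column matrix or data frame of `(x, y)` coordinates
#'   (um), or a `measure_droplets()` result (columns `cx_um`, `cy_um`).
#' @return Numeric vector of nearest-neighbour distances, one per object.
#' @export
nearest_neighbor_distances <- function(centroids) {
  if (is.data.frame(centroids) && all(c("cx_um", "cy_um") %in% names(centroids))) {
    centroids <- as.matrix(centroids[, c("cx_um", "cy_um")])
  }
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) {
    stop("nearest-neighbour distances need at least 2 objects; ",
         "field flagged as undefined", call. = FALSE)
  }
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' Summarize all droplets of one microscope field
#'
#' @param features A [measure_droplets()] data frame.
#' @param field_area_um2 Field area (um^2), > 0.
#' @param field_id Optional field identifier.
#' @return One-row data frame with `field_id`, `count`, `total_area_um2`,
#'   `area_percent`, `mean_size_um2`, `mean_diameter_um`,
#'   `mean_perimeter_um`, `mean_convex_area_um2`, `mean_nn_distance_um`.
#'   An empty field has count 0 and area 0 with means flagged `NA`;
#'   `mean_nn_distance_um` is `NA` with fewer than 2 objects.
#' @export
summarize_field <- function(features, field_area_um2, field_id = 1L) {
  stopifnot(field_area_um2 > 0)
  n <- nrow(features)
  total <- sum(features$area_um2)
  nn <- if (n >= 2) mean(nearest_neighbor_distances(features)) else NA_real_
  data.frame(
    field_id = field_id,
    count = n,
    total_area_um2 = total,
    area_percent = 100 * total / field_area_um2,
    mean_size_um2 = if (n) mean(features$area_um2) else NA_real_,
    mean_diameter_um = if (n) mean(features$eq_diameter_um) else NA_real_,
    mean_perimeter_um = if (n) mean(features$perimeter_um) else NA_real_,
    mean_convex_area_um2 = if (n) mean(features$convex_area_um2) else NA_real_,
    mean_nn_distance_um = nn
  )
}

#' Aggregate field summaries to animal means and a group summary
#'
#' The aggregation hierarchy is fixed: object -> field -> animal (mean over
#' that animal's fields, 16 in the study design) -> group (mean +/- SEM over
#' animals, 3 in the study design). SEM is computed across animals, never
#' across the pooled fields.
#'
#' @param field_summaries Data frame of [summarize_field()] rows.
#' @param animal_ids Vector assigning each field row to an animal.
#' @param group Group label (e.g. `"UK_T1"`).
#' @param mean_volume_mode How the mean spherical droplet volume is derived:
#'   `"from_mean_diameter"` (default; the volume of the sphere with the
#'   group-mean equivalent diameter, matching single-value reporting) or
#'   `"mean_of_volumes"` (mean of per-animal volumes computed from each
#'   animal's mean diameter).
#' @return A list of class `group_summary`: `group`, `n_animals`,
#'   `per_animal` (data frame of animal means), `mean` and `sem` (named
#'   vectors over the field metrics), `mean_volume_um3`, and
#'   `volume_per_total_area_um3` (mean count per field times mean volume).
#' @export
group_summary <- function(field_summaries, animal_ids, group = "group",
                          mean_volume_mode = c("from_mean_diameter",
                                               "mean_of_volumes")) {
  mean_volume_mode <- match.arg(mean_volume_mode)
  stopifnot(nrow(field_summaries) == length(animal_ids))
  metrics <- c("count", "total_area_um2", "area_percent", "mean_size_um2",
               "mean_diameter_um", "mean_perimeter_um",
               "mean_convex_area_um2", "mean_nn_distance_um")
  per_animal <- do.call(rbind, lapply(split(field_summaries, animal_ids),
    function(d) as.data.frame(lapply(d[metrics], mean, na.rm = TRUE))))
  per_animal <- cbind(animal = rownames(per_animal), per_animal)
  rownames(per_animal) <- NULL
  m <- vapply(per_animal[metrics], mean, numeric(1))
  s <- vapply(per_animal[metrics],
              function(v) stats::sd(v) / sqrt(length(v)), numeric(1))
  mean_vol <- if (mean_volume_mode == "from_mean_diameter") {
    spherical_volume(m[["mean_diameter_um"]])
  } else {
    mean(spherical_volume(per_animal$mean_diameter_um))
  }
  structure(
    list(group = group, n_animals = nrow(per_animal),
         per_animal = per_animal, mean = m, sem = s,
         mean_volume_um3 = mean_vol,
         volume_per_total_area_um3 = volume_per_total_area(m[["count"]], mean_vol)),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: %d animals\n", x$group, x$n_animals))
  df <- data.frame(mean = x$mean, sem = x$sem)
  print(round(df, 3))
  cat(sprintf("mean spherical volume: %.3f um^3; volume per total LD area: %.1f um^3\n",
              x$mean_volume_um3, x$volume_per_total_area_um3))
  invisible(x)
}

#' Spherical droplet volume from a 2-D equivalent diameter
#'
#' Assuming droplets are spheres, `V = pi * d^3 / 6`.
#'
#' @param diameter_um Equivalent diameter (um), >= 0. Vectorized.
#' @return Volume in um^3.
#' @export
spherical_volume <- function(diameter_um) {
  if (any(diameter_um < 0, na.rm = TRUE)) {
    stop("diameter must be non-negative", call. = FALSE)
  }
  pi * diameter_um^3 / 6
}

#' Diameter fold implied by a spherical volume fold
#'
#' For spheres the volume fold between two groups is the cube of the
#' diameter fold, so the diameter fold is the cube root of the volume fold.
#'
#' @param volume_fold Ratio of mean spherical volumes (> 0).
#' @return The implied diameter fold.
#' @export
sphere_diameter_fold <- function(volume_fold) {
  stopifnot(all(volume_fold > 0))
  volume_fold^(1 / 3)
}

#' Droplet volume per standardized field area
#'
#' The product of droplet count (per equal-sized reference field) and mean
#' spherical droplet volume; between two groups its fold equals the count
#' fold times the volume fold.
#'
#' @param count_per_field Droplet count per reference field (>= 0).
#' @param mean_volume_um3 Mean spherical droplet volume (um^3, >= 0).
#' @return Volume per reference field, um^3.
#' @export
volume_per_total_area <- function(count_per_field, mean_volume_um3) {
  stopifnot(all(count_per_field >= 0, na.rm = TRUE),
            all(mean_volume_um3 >= 0, na.rm = TRUE))
  count_per_field * mean_volume_um3
}

#' Fold changes and percent differences between two group summaries
#'
#' For every shared metric, `fold = mean_A / mean_B` and
#' `percent = 100 * (fold - 1)`; positive percents are increases of A over
#' B, negative percents reductions. Metrics undefined (`NA`) in either group
#' propagate as `NA`. Report-parity rounding (1 decimal for folds and
#' percents) is left to the caller.
#'
#' @param group_a,group_b `group_summary` objects (A is compared against B).
#' @return Data frame with `metric`, `mean_a`, `mean_b`, `fold`, `percent`;
#'   rows for the mean spherical volume and volume-per-total-area are
#'   appended.
#' @export
group_fold_changes <- function(group_a, group_b) {
  stopifnot(inherits(group_a, "group_summary"),
            inherits(group_b, "group_summary"))
  metrics <- names(group_a$mean)
  ma <- c(group_a$mean,
          mean_volume_um3 = group_a$mean_volume_um3,
          volume_per_total_area_um3 = group_a$volume_per_total_area_um3)
  mb <- c(group_b$mean,
          mean_volume_um3 = group_b$mean_volume_um3,
          volume_per_total_area_um3 = group_b$volume_per_total_area_um3)
  if (any(!is.na(mb) & mb == 0)) {
    stop("zero group-B mean: fold change undefined", call. = FALSE)
  }
  fold <- ma / mb
  data.frame(metric = names(ma), mean_a = as.numeric(ma),
             mean_b = as.numeric(mb), fold = as.numeric(fold),
             percent = 100 * (as.numeric(fold) - 1),
             row.names = NULL)
}
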