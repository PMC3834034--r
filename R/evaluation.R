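#' Segment and measure one section in a single call
#'
#' Convenience composition used throughout the workflow: [segment()],
#' [measure_droplets()] and [summarize_field()].
#'
#' @param section An `ld_section` (or RGB array, in which case
#'   `pixel_size_um` and `field_area_um2` must be supplied).
#' @param config A [segmentation_config()].
#' @param field_id Field identifier for the summary row.
#' @param pixel_size_um,field_area_um2 Calibration when a bare array is
#'   given.
#' @return List with `mask` (`labeled_mask`), `features`
#'   ([measure_droplets()] table) and `summary` ([summarize_field()] row).
#' @export
analyze_section <- function(section, config = segmentation_config(),
                            field_id = 1L, pixel_size_um = NULL,
                            field_area_um2 = NULL) {
  if (inherits(section, "ld_section")) {
    pixel_size_um <- section$spec$pixel_size_um
    field_area_um2 <- section$field_area_um2
  } else if (is.null(pixel_size_um) || is.null(field_area_um2)) {
    stop("pixel_size_um and field_area_um2 are required for a bare array",
         call. = FALSE)
  }
  mask <- segment(section, config,
                  pixel_size_um = pixel_size_um)
  features <- measure_droplets(mask)
  list(mask = mask, features = features,
       summary = summarize_field(features, field_area_um2, field_id))
}

#' Match detected droplets to ground truth
#'
#' Greedy one-to-one matching by increasing centroid distance: a detection
#' matches a ground-truth droplet when their centroid distance is within
#' one true radius. Reports recall (matched truth / all truth) and
#' precision (matched detections / all detections).
#'
#' @param features A [measure_droplets()] table (columns `cx_um`, `cy_um`).
#' @param truth Ground-truth data frame (`cx_um`, `cy_um`, `r_um`), e.g.
#'   from an `ld_section`.
#' @return List with `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `precision`. Empty truth gives recall 1; empty detection gives
#'   precision 1.
#' @export
match_to_ground_truth <- function(features, truth) {
  nt <- nrow(truth); nd <- nrow(features)
  if (nt == 0 || nd == 0) {
    return(list(n_truth = nt, n_detected = nd, n_matched = 0L,
                recall = if (nt == 0) 1 else 0,
                precision = if (nd == 0) 1 else 0))
  }
  d <- sqrt(outer(features$cx_um, truth$cx_um, `-`)^2 +
            outer(features$cy_um, truth$cy_um, `-`)^2)
  ok <- sweep(d, 2, truth$r_um, `<=`)
  d[!ok] <- Inf
  matched <- 0L
  while (any(is.finite(d))) {
    hit <- arrayInd(which.min(d), dim(d))
    matched <- matched + 1L
    d[hit[1], ] <- Inf
    d[, hit[2]] <- Inf
  }
  list(n_truth = nt, n_detected = nd, n_matched = matched,
       recall = matched / nt, precision = matched / nd)
}
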