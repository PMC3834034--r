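#' Segmentation configuration
#'
#' Parameters of the automated droplet-detection sequence: percentile-based
#' contrast rescaling, thresholding (automatic between-class-variance search
#' or a fixed 8-bit level), and rule-based artifact filtering by area bounds,
#' circularity and border policy. The interactive threshold and artifact
#' deletion of the original microscope macro are replaced by these
#' deterministic rules so that runs are reproducible.
#'
#' @param contrast_low,contrast_high Percentiles (0..100) of the rescale;
#'   must be ordered. `contrast_low` should stay below the expected stain
#'   area fraction (in percent): if it lands inside the background
#'   distribution, sparse droplets are clipped to black while background
#'   noise is stretched across the full range, and the automatic threshold
#'   then splits the background instead of separating the droplets. The
#'   defaults (0.1, 99.9) are safe for stain fractions above 0.1%.
#' @param threshold_mode `"auto"` for the exhaustive between-class-variance
#'   (Otsu) search over all 256 candidate levels, or a fixed numeric
#'   threshold in \[0, 255\] (foreground = strictly below it).
#' @param min_area_px,max_area_px Retained component area bounds in pixels.
#'   `max_area_px = NULL` means 10% of the field at segmentation time.
#' @param min_circularity Minimum circularity `4*pi*A/P^2` in (0, 1]. With
#'   the corrected crack-length perimeter used here a rasterized disk scores
#'   close to 1 and elongated streaks score well below it.
#' @param border_policy `"exclude"` (default) drops objects touching the
#'   field edge; `"include"` keeps them.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(contrast_low = 0.1, contrast_high = 99.9,
                                threshold_mode = "auto",
                                min_area_px = 4L, max_area_px = NULL,
                                min_circularity = 0.3,
                                border_policy = c("exclude", "include")) {
  border_policy <- match.arg(border_policy)
  stopifnot(contrast_low >= 0, contrast_high <= 100,
            min_area_px >= 1, min_circularity > 0, min_circularity <= 1)
  if (contrast_low >= contrast_high) {
    stop("contrast percentiles must be ordered (low < high)", call. = FALSE)
  }
  if (!identical(threshold_mode, "auto")) {
    stopifnot(is.numeric(threshold_mode), length(threshold_mode) == 1,
              threshold_mode >= 0, threshold_mode <= 255)
  }
  if (!is.null(max_area_px) && max_area_px <= min_area_px) {
    stop("min_area_px must be smaller than max_area_px", call. = FALSE)
  }
  structure(
    list(contrast_low = contrast_low, contrast_high = contrast_high,
         threshold_mode = threshold_mode,
         min_area_px = as.integer(min_area_px),
         max_area_px = if (is.null(max_area_px)) NULL else as.integer(max_area_px),
         min_circularity = min_circularity,
         border_policy = border_policy),
    class = "segmentation_config"
  )
}

#' Extract the green channel from an RGB image
#'
#' Oil Red O stains neutral lipids red, so droplets absorb green light and
#' appear dark in the green channel; all downstream detection operates there.
#'
#' @param rgb_image Height x width x 3 array (R, G, B order), 8-bit values.
#' @return Single-channel integer matrix.
#' @export
extract_green_channel <- function(rgb_image) {
  d <- dim(rgb_image)
  if (length(d) != 3 || d[3] != 3) {
    stop("expected a 3-channel RGB image", call. = FALSE)
  }
  g <- rgb_image[, , 2]
  storage.mode(g) <- "integer"
  g
}

#' Percentile-based contrast enhancement
#'
#' Linearly rescales the intensity range between the `contrast_low` and
#' `contrast_high` percentiles onto the full 8-bit range, saturating outside
#' it. The mapping is monotone, so pixel ordering is preserved up to
#' saturation. A constant image is returned unchanged (documented no-op:
#' there is no contrast to stretch).
#'
#' @param gray_image Single-channel numeric matrix.
#' @param config A [segmentation_config()].
#' @return Integer matrix with values in 0..255.
#' @export
enhance_contrast <- function(gray_image, config = segmentation_config()) {
  if (!is.matrix(gray_image)) stop("expected a single-channel matrix", call. = FALSE)
  q <- stats::quantile(gray_image,
                       c(config$contrast_low, config$contrast_high) / 100,
                       names = FALSE)
  if (q[2] <= q[1]) {
    out <- gray_image
    storage.mode(out) <- "integer"
    return(out)
  }
  out <- round((gray_image - q[1]) / (q[2] - q[1]) * 255)
  out <- pmin(pmax(out, 0), 255)
  storage.mode(out) <- "integer"
  out
}

#' Automatic threshold maximizing between-class variance
#'
#' Exhaustive search over all 256 candidate split levels `k`: pixels with
#' value `<= k` form one class, `> k` the other; the chosen `k` maximizes the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2`. Ties are broken toward
#' the lowest level.
#'
#' @param gray_image Single-channel matrix with 8-bit values.
#' @return The split level `k` (integer in 0..254).
#' @export
otsu_threshold <- function(gray_image) {
  v <- as.integer(gray_image)
  if (length(unique(v)) < 2) {
    stop("automatic thresholding needs at least 2 distinct values; ",
         "use a fixed threshold instead", call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  k <- 1:255                       # split after level k-1
  w0k <- w0[k]; w1k <- 1 - w0k
  valid <- w0k > 0 & w1k > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0k[valid] - mu[k][valid])^2 /
    (w0k[valid] * w1k[valid])
  which.max(sigma_b) - 1L          # class boundary level
}

#' Threshold a grayscale image into a droplet foreground mask
#'
#' Droplets are the low-intensity class in the green channel, so the
#' foreground is everything strictly below the effective threshold. In
#' automatic mode the between-class-variance split level `k` from
#' [otsu_threshold()] gives the effective threshold `k + 1` (foreground
#' `<= k`); a fixed threshold is used as given.
#'
#' @param gray_image Single-channel matrix with 8-bit values.
#' @param config A [segmentation_config()].
#' @return Logical matrix (foreground = `TRUE`), with attribute
#'   `threshold` (the effective threshold used).
#' @export
threshold_objects <- function(gray_image, config = segmentation_config()) {
  if (!is.matrix(gray_image)) stop("expected a single-channel matrix", call. = FALSE)
  thr <- if (identical(config$threshold_mode, "auto")) {
    otsu_threshold(gray_image) + 1L
  } else {
    config$threshold_mode
  }
  mask <- gray_image < thr
  attr(mask, "threshold") <- thr
  mask
}

#' Label connected components of a binary mask (8-connectivity)
#'
#' Union-find over foreground pixels; 8-connectivity avoids splitting the
#' anti-aliased rims of round objects. Labels are consecutive from 1 in
#' first-pixel (column-major) order.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, h, w)
  n <- length(idx)
  if (n == 0L) return(out)
  pos <- integer(h * w)
  pos[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  # Half the 8-neighbourhood suffices (the rest is covered symmetrically).
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + off[1]; cn <- cc + off[2]
    ok <- rr >= 1L & rr <= h & cn >= 1L & cn <= w
    j <- (cn - 1L) * h + rr
    ok[ok] <- mask[j[ok]]
    a <- pos[idx[ok]]; b <- pos[j[ok]]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out[idx] <- match(roots, unique(roots))
  out
}

# Per-label pixel statistics on a label matrix: area, crack-edge count
# (pixel edges facing a different label or the image border), bounding box
# border contact. Returns a data frame ordered by label.
component_stats <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  k <- max(labels)
  if (k == 0L) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      edges = integer(0), touches_border = logical(0)))
  }
  area <- tabulate(labels[labels > 0L], nbins = k)
  edges <- integer(k)
  for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- matrix(0L, h, w)
    sr <- max(1L, 1L + off[1]):min(h, h + off[1])
    sc <- max(1L, 1L + off[2]):min(w, w + off[2])
    nb[sr, sc] <- labels[sr - off[1], sc - off[2]]
    diff <- labels > 0L & nb != labels
    edges <- edges + tabulate(labels[diff], nbins = k)
  }
  border <- unique(c(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
  data.frame(label = seq_len(k), area_px = area, edges = edges,
             touches_border = seq_len(k) %in% border[border > 0L])
}

# Crack-length perimeter with the pi/4 average-orientation correction:
# exact (in expectation over orientations) for convex shapes, and equal to
# 2*pi*r for a rasterized disk. This estimator is the package's frozen
# definition of an object's "circumference".
crack_perimeter <- function(edges) edges * pi / 4

#' Remove artifact components and build a labeled droplet mask
#'
#' Labels the binary mask with 8-connectivity, then removes components that
#' fail the area bounds, whose circularity `4*pi*A/P^2` (with the corrected
#' crack-length perimeter) falls below `min_circularity`, or that touch the
#' field border under the `"exclude"` policy. Survivors are relabeled
#' consecutively. Applying the filter twice equals applying it once.
#'
#' @param mask Logical foreground mask (may carry a `threshold` attribute,
#'   which is propagated).
#' @param config A [segmentation_config()].
#' @param pixel_size_um Physical pixel size for the resulting mask.
#' @return An object of class `labeled_mask`: list with `labels` (integer
#'   matrix), `pixel_size_um`, `n_candidates` (components before filtering),
#'   `n_objects`, `threshold`, and `config`.
#' @export
filter_artifacts <- function(mask, config = segmentation_config(),
                             pixel_size_um = 0.5) {
  stopifnot(pixel_size_um > 0)
  labels <- label_components(mask)
  st <- component_stats(labels)
  max_area <- if (is.null(config$max_area_px)) {
    as.integer(0.10 * length(mask))
  } else config$max_area_px
  circ <- 4 * pi * st$area_px / crack_perimeter(st$edges)^2
  keep <- st$area_px >= config$min_area_px &
    st$area_px <= max_area &
    circ >= config$min_circularity
  if (config$border_policy == "exclude") keep <- keep & !st$touches_border
  remap <- integer(max(labels, 1L))
  remap[st$label[keep]] <- seq_len(sum(keep))
  relabeled <- matrix(0L, nrow(labels), ncol(labels))
  fg <- labels > 0L
  relabeled[fg] <- remap[labels[fg]]
  structure(
    list(labels = relabeled, pixel_size_um = pixel_size_um,
         n_candidates = nrow(st), n_objects = sum(keep),
         threshold = attr(mask, "threshold"), config = config),
    class = "labeled_mask"
  )
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d objects (of %d candidates) @ %.3g um/px",
              x$n_objects, x$n_candidates, x$pixel_size_um))
  if (!is.null(x$threshold)) cat(sprintf(", threshold %s", format(x$threshold)))
  cat("\n")
  invisible(x)
}

#' Segment droplets in an RGB section image
#'
#' The full detection sequence: green-channel extraction, percentile
#' contrast enhancement, thresholding (automatic between-class-variance
#' search by default) and rule-based artifact filtering. Deterministic.
#'
#' @param rgb_image Height x width x 3 8-bit array, or an `ld_section`.
#' @param config A [segmentation_config()].
#' @param pixel_size_um Physical pixel size; taken from the section spec
#'   when an `ld_section` is supplied.
#' @return A `labeled_mask` (see [filter_artifacts()]).
#' @export
segment <- function(rgb_image, config = segmentation_config(),
                    pixel_size_um = 0.5) {
  if (inherits(rgb_image, "ld_section")) {
    pixel_size_um <- rgb_image$spec$pixel_size_um
    rgb_image <- rgb_image$image
  }
  g <- extract_green_channel(rgb_image)
  g <- enhance_contrast(g, config)
  # a constant field (no stained objects at all) has nothing to threshold
  mask <- if (identical(config$threshold_mode, "auto") &&
              diff(range(g)) == 0) {
    structure(matrix(FALSE, nrow(g), ncol(g)), threshold = NA_real_)
  } else {
    threshold_objects(g, config)
  }
  filter_artifacts(mask, config, pixel_size_um)
}

#' Write a labeled mask as a 16-bit TIFF plus a run log CSV
#'
#' @param lmask A `labeled_mask`.
#' @param tiff_path Output TIFF path (labels stored as 16-bit gray).
#' @param log_path Optional CSV run-log path (threshold, candidate and
#'   retained object counts).
#' @return `tiff_path`, invisibly.
#' @export
write_labeled_mask <- function(lmask, tiff_path, log_path = NULL) {
  stopifnot(inherits(lmask, "labeled_mask"))
  tiff::writeTIFF(lmask$labels / 65535, tiff_path, bits.per.sample = 16)
  if (!is.null(log_path)) {
    utils::write.csv(
      data.frame(threshold = if (is.null(lmask$threshold)) NA else lmask$threshold,
                 n_candidates = lmask$n_candidates,
                 n_objects = lmask$n_objects,
                 pixel_size_um = lmask$pixel_size_um),
      log_path, row.names = FALSE)
  }
  invisible(tiff_path)
}
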