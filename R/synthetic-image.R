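#' Specification for a synthetic Oil-Red-O section image
#'
#' Describes a rendered liver-section field: red lipid droplets (dark in the
#' green channel, because the red stain absorbs green) on a pale tissue
#' background, optional additive Gaussian noise, and optional artifacts
#' (elongated streaks and sub-resolution specks) for the artifact filter to
#' remove. Droplet radii are drawn from a lognormal distribution specified by
#' its median (in micrometres) and log-scale standard deviation.
#'
#' @param field_width_px,field_height_px Field size in pixels.
#' @param pixel_size_um Physical pixel size (micrometres per pixel). The
#'   default 0.5 um/px makes a sub-micrometre droplet span more than one
#'   pixel.
#' @param n_droplets Number of droplets to place.
#' @param radius_median_um Median droplet radius (um) of the lognormal.
#' @param radius_sigma_log Log-scale standard deviation of the lognormal.
#' @param droplet_color_rgb,background_color_rgb Integer RGB triplets in
#'   0..255. The droplet green value must be below the background green value.
#' @param noise_sd Standard deviation of additive Gaussian noise per channel,
#'   in 8-bit intensity units.
#' @param hardcore If `TRUE` (default) droplets may not overlap: pairwise
#'   centre distances must exceed the sum of the radii plus a small guard
#'   margin (`separation_px`) that keeps anti-aliased rims from fusing.
#' @param separation_px Extra centre-to-centre clearance, in pixels, added on
#'   top of the radius sum under hardcore placement.
#' @param n_artifacts Number of artifacts; alternates between streaks
#'   (axis ratio >= 4) and specks (area < 4 px).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `ld_image_spec` (a validated list).
#' @seealso [generate_section_image()]
#' @export
synthetic_image_spec <- function(field_width_px = 512L,
                                 field_height_px = 512L,
                                 pixel_size_um = 0.5,
                                 n_droplets = 50L,
                                 radius_median_um = 3,
                                 radius_sigma_log = 0.2,
                                 droplet_color_rgb = c(200L, 60L, 60L),
                                 background_color_rgb = c(235L, 225L, 230L),
                                 noise_sd = 0,
                                 hardcore = TRUE,
                                 separation_px = 2,
                                 n_artifacts = 0L,
                                 seed = 1L) {
  stopifnot(
    field_width_px >= 1, field_height_px >= 1,
    n_droplets >= 0, radius_median_um > 0, radius_sigma_log >= 0,
    length(droplet_color_rgb) == 3, length(background_color_rgb) == 3,
    all(droplet_color_rgb >= 0 & droplet_color_rgb <= 255),
    all(background_color_rgb >= 0 & background_color_rgb <= 255),
    noise_sd >= 0, separation_px >= 0, n_artifacts >= 0
  )
  if (pixel_size_um <= 0) {
    stop("pixel_size_um must be positive", call. = FALSE)
  }
  if (droplet_color_rgb[2] >= background_color_rgb[2]) {
    stop("droplet green value must be below background green value ",
         "(the red stain absorbs green)", call. = FALSE)
  }
  structure(
    list(
      field_width_px = as.integer(field_width_px),
      field_height_px = as.integer(field_height_px),
      pixel_size_um = pixel_size_um,
      n_droplets = as.integer(n_droplets),
      radius_median_um = radius_median_um,
      radius_sigma_log = radius_sigma_log,
      droplet_color_rgb = as.integer(droplet_color_rgb),
      background_color_rgb = as.integer(background_color_rgb),
      noise_sd = noise_sd,
      hardcore = isTRUE(hardcore),
      separation_px = separation_px,
      n_artifacts = as.integer(n_artifacts),
      seed = as.integer(seed)
    ),
    class = "ld_image_spec"
  )
}

#' Load a synthetic image spec from a YAML config file
#'
#' The file holds top-level keys matching the [synthetic_image_spec()]
#' arguments, e.g.
#' ```yaml
#' field_width_px: 512
#' n_droplets: 50
#' radius_median_um: 3
#' droplet_color_rgb: [200, 60, 60]
#' seed: 1
#' ```
#' Unspecified fields take the defaults; unknown keys are an error.
#'
#' @param path Path to the YAML file.
#' @return An `ld_image_spec`.
#' @export
read_image_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(synthetic_image_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown spec field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(synthetic_image_spec, cfg)
}

#' @export
print.ld_image_spec <- function(x, ...) {
  cat(sprintf(
    "<ld_image_spec> %d x %d px @ %.3g um/px, %d droplets (lognormal median %.3g um, sigma_log %.3g)\n",
    x$field_width_px, x$field_height_px, x$pixel_size_um,
    x$n_droplets, x$radius_median_um, x$radius_sigma_log
  ))
  cat(sprintf("  noise_sd %.3g, hardcore %s, artifacts %d, seed %d\n",
              x$noise_sd, x$hardcore, x$n_artifacts, x$seed))
  invisible(x)
}

# Anti-aliased disk coverage block. Coverage of a pixel is approximated from
# the distance of its centre to the disk edge: clamp(r - d + 0.5, 0, 1) -- a
# half-pixel linear ramp. Returned as a bounding-box patch so the caller can
# update its accumulator in place (no full-image copies per droplet).
disk_block <- function(cx, cy, r, h, w) {
  c0 <- max(1L, floor(cx - r - 1) + 1L); c1 <- min(w, ceiling(cx + r + 1) + 1L)
  r0 <- max(1L, floor(cy - r - 1) + 1L); r1 <- min(h, ceiling(cy + r + 1) + 1L)
  if (c0 > c1 || r0 > r1) return(NULL)
  xs <- (c0:c1) - 1; ys <- (r0:r1) - 1   # pixel-centre coordinates, 0-based
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  list(r0 = r0, r1 = r1, c0 = c0, c1 = c1,
       a = pmin(pmax(r - d + 0.5, 0), 1))
}

# Rotated-rectangle (streak) coverage; binary inside test is adequate for
# artifacts, which only need to be crisply non-circular.
paint_streak <- function(cov, cx, cy, len, width, theta) {
  h <- nrow(cov); w <- ncol(cov)
  half <- len / 2 + 1
  c0 <- max(1L, floor(cx - half) + 1L); c1 <- min(w, ceiling(cx + half) + 1L)
  r0 <- max(1L, floor(cy - half) + 1L); r1 <- min(h, ceiling(cy + half) + 1L)
  if (c0 > c1 || r0 > r1) return(cov)
  xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
  u <- outer(ys - cy, xs - cx, function(dy, dx)  dx * cos(theta) + dy * sin(theta))
  v <- outer(ys - cy, xs - cx, function(dy, dx) -dx * sin(theta) + dy * cos(theta))
  a <- (abs(u) <= len / 2) & (abs(v) <= width / 2)
  block <- cov[r0:r1, c0:c1]
  cov[r0:r1, c0:c1] <- pmax(block, a * 1)
  cov
}

#' Render a synthetic stained-section image with ground truth
#'
#' Places droplets (uniformly, fully inside the field; under hardcore
#' placement by rejection sampling with a bounded attempt budget), renders
#' them as anti-aliased disks in the droplet colour over the background
#' colour, optionally adds artifacts and per-channel Gaussian noise, and
#' returns the 8-bit RGB image together with the exact ground truth.
#'
#' Coordinates are 0-based with x rightward and y downward; physical
#' coordinates are pixel index times `pixel_size_um`, at pixel centres.
#' Ground-truth droplet areas are the analytic `pi * r^2`; rasterized areas
#' agree with them up to a one-pixel boundary ring.
#'
#' @param spec An [synthetic_image_spec()] object.
#' @param max_attempts_per_droplet Rejection-sampling budget under hardcore
#'   placement; exceeding it is an error naming the budget.
#' @return A list of class `ld_section` with elements `image` (height x
#'   width x 3 integer array, 0..255), `truth` (data frame with columns
#'   `id`, `cx_um`, `cy_um`, `r_um`), `field_area_um2`, and `spec`.
#' @export
generate_section_image <- function(spec, max_attempts_per_droplet = 1000L) {
  stopifnot(inherits(spec, "ld_image_spec"))
  set.seed(spec$seed)
  h <- spec$field_height_px; w <- spec$field_width_px
  ps <- spec$pixel_size_um

  r_px <- numeric(0); cx <- numeric(0); cy <- numeric(0)
  n <- spec$n_droplets
  if (n > 0) {
    r_px <- stats::rlnorm(n, meanlog = log(spec$radius_median_um),
                          sdlog = spec$radius_sigma_log) / ps
    budget <- as.integer(max_attempts_per_droplet) * n
    cx <- numeric(n); cy <- numeric(n)
    attempts <- 0L
    for (i in seq_len(n)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > budget) {
          stop(sprintf(
            "hardcore placement failed: could not place droplet %d of %d within %d attempts",
            i, n, budget), call. = FALSE)
        }
        r <- r_px[i]
        if (2 * r + 2 >= min(h, w)) {
          stop("droplet radius exceeds field size", call. = FALSE)
        }
        x <- stats::runif(1, r + 1, w - r - 2)
        y <- stats::runif(1, r + 1, h - r - 2)
        if (!spec$hardcore || i == 1L) break
        prev <- seq_len(i - 1L)
        dmin <- sqrt((cx[prev] - x)^2 + (cy[prev] - y)^2)
        if (all(dmin > r_px[prev] + r + spec$separation_px)) break
      }
      cx[i] <- x; cy[i] <- y
    }
  }

  cov <- matrix(0, h, w)
  for (i in seq_len(n)) {
    b <- disk_block(cx[i], cy[i], r_px[i], h, w)
    if (!is.null(b)) {
      cov[b$r0:b$r1, b$c0:b$c1] <- pmax(cov[b$r0:b$r1, b$c0:b$c1], b$a)
    }
  }

  # Artifacts: alternate streaks (axis ratio >= 4) and specks (< 4 px),
  # kept clear of droplets so they never merge with a true object.
  if (spec$n_artifacts > 0) {
    art <- matrix(0, h, w)
    for (k in seq_len(spec$n_artifacts)) {
      streak <- (k %% 2L) == 1L
      for (try in seq_len(1000L)) {
        if (streak) {
          len <- stats::runif(1, 24, 48)
          wid <- stats::runif(1, 2, min(4, len / 4))
          theta <- stats::runif(1, 0, pi)
          guard <- len / 2
        } else {
          len <- wid <- 1.2   # single-pixel speck footprint
          theta <- 0
          guard <- 1.5
        }
        x <- stats::runif(1, guard + 1, w - guard - 2)
        y <- stats::runif(1, guard + 1, h - guard - 2)
        clear <- n == 0 ||
          all(sqrt((cx - x)^2 + (cy - y)^2) > r_px + guard + spec$separation_px)
        if (clear) break
      }
      art <- if (streak) paint_streak(art, x, y, len, wid, theta) else {
        px <- round(x) + 1L; py <- round(y) + 1L
        art[py, px] <- 1
        art
      }
    }
    cov <- pmax(cov, art)
  }

  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    bg <- spec$background_color_rgb[ch]
    fg <- spec$droplet_color_rgb[ch]
    plane <- bg + (fg - bg) * cov
    if (spec$noise_sd > 0) {
      plane <- plane + stats::rnorm(h * w, sd = spec$noise_sd)
    }
    img[, , ch] <- pmin(pmax(round(plane), 0), 255)
  }
  storage.mode(img) <- "integer"

  truth <- data.frame(
    id = seq_len(n),
    cx_um = cx * ps,
    cy_um = cy * ps,
    r_um = r_px * ps
  )
  structure(
    list(image = img, truth = truth,
         field_area_um2 = h * w * ps^2, spec = spec),
    class = "ld_section"
  )
}

#' @export
print.ld_section <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<ld_section> %d x %d px RGB, %d ground-truth droplets, field %.1f um^2\n",
              d[2], d[1], nrow(x$truth), x$field_area_um2))
  invisible(x)
}

#' Write a section image to TIFF or PNG
#'
#' @param section An `ld_section` object or a height x width x 3 integer
#'   array with values in 0..255.
#' @param path Output path; the extension (`.tif`/`.tiff` or `.png`)
#'   selects the format.
#' @return `path`, invisibly.
#' @export
write_section_image <- function(section, path) {
  img <- if (inherits(section, "ld_section")) section$image else section
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  arr <- img / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8)
  } else if (ext == "png") {
    png::writePNG(arr, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read an RGB section image from TIFF or PNG
#'
#' @param path Image path (`.tif`/`.tiff` or `.png`).
#' @return Height x width x 3 integer array with values in 0..255.
#' @export
read_section_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3) {
    stop("expected a 3-channel RGB image", call. = FALSE)
  }
  img <- round(arr[, , 1:3] * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write droplet ground truth as CSV
#'
#' Columns: `id`, `cx_um`, `cy_um`, `r_um`.
#'
#' @param section An `ld_section` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(section, path) {
  stopifnot(inherits(section, "ld_section"))
  utils::write.csv(section$truth, path, row.names = FALSE)
  invisible(path)
}
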