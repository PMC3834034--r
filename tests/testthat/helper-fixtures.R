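# Shared fixture builders; everything is generated in code at test time.

# Compact image spec used across segmentation tests: 5-px median radius at
# 0.5 um/px so droplets are well above the 3-px recovery limit.
make_spec <- function(seed, n_droplets = 20L, field = 256L, noise_sd = 0,
                      n_artifacts = 0L, radius_median_um = 2.5,
                      radius_sigma_log = 0.15, ...) {
  synthetic_image_spec(
    field_width_px = field, field_height_px = field,
    n_droplets = n_droplets, radius_median_um = radius_median_um,
    radius_sigma_log = radius_sigma_log, noise_sd = noise_sd,
    n_artifacts = n_artifacts, seed = seed, ...
  )
}

# Hand-built labeled mask on a unit-calibrated grid.
make_labeled_mask <- function(labels, pixel_size_um = 1) {
  structure(
    list(labels = labels, pixel_size_um = pixel_size_um,
         n_candidates = max(labels), n_objects = max(labels),
         threshold = NULL, config = segmentation_config()),
    class = "labeled_mask"
  )
}

# Draw a filled disk into a logical matrix (pixel-centre inside test).
disk_mask <- function(size, cx, cy, r) {
  xs <- matrix(rep(0:(size - 1), each = size), size)
  ys <- matrix(rep(0:(size - 1), times = size), size)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# Independent exhaustive between-class-variance search (the oracle for the
# automatic threshold): direct two-class means over the raw pixel values.
otsu_oracle <- function(v) {
  v <- as.numeric(v)
  best <- -Inf
  best_k <- NA_integer_
  for (k in 0:254) {
    lo <- v[v <= k]
    hi <- v[v > k]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-9) {
      best <- sb
      best_k <- k
    }
  }
  best_k
}

# Brute-force exhaustive two-sided permutation p for one site (oracle).
perm_oracle_p <- function(values, n_exp) {
  n <- length(values)
  combos <- combn(n, n_exp)
  obs <- mean(values[seq_len(n_exp)]) - mean(values[-seq_len(n_exp)])
  ds <- apply(combos, 2, function(ix) mean(values[ix]) - mean(values[-ix]))
  sum(abs(ds) >= abs(obs) - 1e-12) / ncol(combos)
}

# Direct sums-of-squares oracle for a balanced 2x2 ANOVA.
anova_ss_oracle <- function(y, A, B) {
  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  nA <- table(A); nB <- table(B); nAB <- table(interaction(A, B))
  ss_A <- sum(nA * (mA - gm)^2)
  ss_B <- sum(nB * (mB - gm)^2)
  ss_cells <- sum(nAB * (mAB - gm)^2)
  ss_AB <- ss_cells - ss_A - ss_B
  ss_res <- ss_total - ss_cells
  df_res <- length(y) - 4
  list(
    ss = c(A = ss_A, B = ss_B, AB = ss_AB, res = ss_res, total = ss_total),
    F = c(A = (ss_A / 1) / (ss_res / df_res),
          B = (ss_B / 1) / (ss_res / df_res),
          AB = (ss_AB / 1) / (ss_res / df_res))
  )
}

# Balanced 2x2 observation table from per-cell mean + residual generator.
make_obs_table <- function(cell_means, n_per_cell = 3, sd = 1, seed = 1,
                           quantity = "q") {
  set.seed(seed)
  grid <- expand.grid(birth_weight = c("U", "N"), diet = c("K", "R"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(4), function(i) {
    key <- paste0(grid$birth_weight[i], grid$diet[i])
    data.frame(
      animal = paste0(key, "_", seq_len(n_per_cell)),
      birth_weight = grid$birth_weight[i],
      diet = grid$diet[i],
      timepoint = "T2",
      quantity = quantity,
      value = cell_means[[key]] + rnorm(n_per_cell, sd = sd)
    )
  }))
  observation_table(rows)
}
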