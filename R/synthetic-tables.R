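#' Construct a methylation-ratio matrix
#'
#' Container for per-CpG-site methylation ratios (fraction methylated, in
#' \[0, 1\], missing allowed) across samples split into an experimental and a
#' control group.
#'
#' @param values Numeric matrix, sites x samples, values in \[0, 1\] or `NA`.
#' @param groups Character vector of `"experimental"` / `"control"` labels,
#'   one per column; each group needs at least 2 samples.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, groups) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("one group label per sample column is required", call. = FALSE)
  }
  if (!all(groups %in% c("experimental", "control"))) {
    stop("group labels must be 'experimental' or 'control'", call. = FALSE)
  }
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("methylation ratios must lie in [0, 1]", call. = FALSE)
  }
  if (sum(groups == "experimental") < 2 || sum(groups == "control") < 2) {
    stop("at least 2 samples per group are required", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("site_%03d", seq_len(nrow(values)))
  }
  structure(list(values = values, groups = groups),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d sites x %d samples (%d experimental, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "experimental"), sum(x$groups == "control")))
  invisible(x)
}

#' Generate a synthetic methylation table with known effect sites
#'
#' Site-level baseline ratios are drawn uniformly from \[0.2, 0.6\]; the
#' chosen effect sites get `effect_size` added in the experimental group, so
#' the true group difference is exactly `effect_size` there (before clipping)
#' and 0 elsewhere. Gaussian noise of standard deviation `noise_sd` is added
#' per measurement and the result is clipped to \[0, 1\].
#'
#' @param n_sites Number of CpG sites.
#' @param n_per_group Samples per group (>= 2).
#' @param effect_sites Integer indices of sites carrying a true difference
#'   (may be empty).
#' @param effect_size True mean group difference at effect sites.
#' @param noise_sd Measurement noise standard deviation.
#' @param seed Integer seed.
#' @param site_ids Optional site names (e.g. amplicon-prefixed CpG ids).
#' @return A `methylation_matrix` with attributes `effect_sites` and
#'   `effect_size`.
#' @export
generate_methylation_table <- function(n_sites, n_per_group = 3L,
                                       effect_sites = integer(0),
                                       effect_size = 0.3,
                                       noise_sd = 0.05,
                                       seed = 1L,
                                       site_ids = NULL) {
  if (n_per_group < 2) {
    stop("n_per_group must be >= 2 (the permutation test is undefined otherwise)",
         call. = FALSE)
  }
  stopifnot(n_sites >= 1, all(effect_sites %in% seq_len(n_sites)))
  set.seed(seed)
  n_samp <- 2L * n_per_group
  base <- stats::runif(n_sites, 0.2, 0.6)
  vals <- matrix(rep(base, n_samp), nrow = n_sites)
  if (length(effect_sites)) {
    vals[effect_sites, seq_len(n_per_group)] <-
      vals[effect_sites, seq_len(n_per_group)] + effect_size
  }
  if (noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
  }
  vals <- pmin(pmax(vals, 0), 1)
  rownames(vals) <- if (is.null(site_ids)) {
    sprintf("site_%03d", seq_len(n_sites))
  } else site_ids
  colnames(vals) <- c(sprintf("exp_%d", seq_len(n_per_group)),
                      sprintf("ctl_%d", seq_len(n_per_group)))
  mm <- methylation_matrix(vals, c(rep("experimental", n_per_group),
                                   rep("control", n_per_group)))
  attr(mm, "effect_sites") <- as.integer(effect_sites)
  attr(mm, "effect_size") <- effect_size
  mm
}

#' Construct an expression-intensity matrix
#'
#' @param values Positive numeric matrix, transcripts x samples.
#' @param groups Two-level character vector of group labels per column,
#'   each level with >= 2 samples.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("one group label per sample column is required", call. = FALSE)
  }
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups are required", call. = FALSE)
  if (min(table(groups)) < 2) {
    stop("at least 2 samples per group are required", call. = FALSE)
  }
  bad <- which(apply(values, 1, function(r) any(!is.finite(r) | r <= 0)))
  if (length(bad)) {
    stop("non-positive or non-finite intensities in rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("tr_%05d", seq_len(nrow(values)))
  }
  structure(list(values = values, groups = groups, levels = lv),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d transcripts x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: n=%d", x$levels,
                            table(x$groups)[x$levels]), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic expression matrix with spiked fold changes
#'
#' Baseline log2 intensities are drawn uniformly from \[6, 12\] per
#' transcript; the first `n_spiked` transcripts are shifted by
#' `log2(true_fc)` in group A. Gaussian noise with standard deviation
#' `noise_sd_log2` is added on the log2 scale, and intensities are returned
#' on the linear scale (always positive).
#'
#' @param n_transcripts Number of transcripts.
#' @param n_per_group Samples per group (>= 2; the study design uses 3).
#' @param n_spiked Number of transcripts carrying a true fold change.
#' @param true_fc True linear fold change (>= 1) of group A over group B.
#' @param noise_sd_log2 Noise standard deviation on the log2 scale. A
#'   coefficient of variation of about 10% on the linear scale corresponds
#'   to `noise_sd_log2 = 0.144`.
#' @param seed Integer seed.
#' @return An `expression_matrix` with attribute `spiked` (transcript ids).
#' @export
generate_expression_matrix <- function(n_transcripts, n_per_group = 3L,
                                       n_spiked = 0L, true_fc = 2,
                                       noise_sd_log2 = 0.144,
                                       seed = 1L) {
  if (true_fc < 1) {
    stop("true_fc must be >= 1; direction is handled by the signed ",
         "fold-change convention downstream", call. = FALSE)
  }
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  stopifnot(n_transcripts >= 1, n_spiked >= 0, n_spiked <= n_transcripts)
  set.seed(seed)
  n_samp <- 2L * n_per_group
  base <- stats::runif(n_transcripts, 6, 12)
  lv <- matrix(rep(base, n_samp), nrow = n_transcripts)
  if (n_spiked > 0) {
    lv[seq_len(n_spiked), seq_len(n_per_group)] <-
      lv[seq_len(n_spiked), seq_len(n_per_group)] + log2(true_fc)
  }
  if (noise_sd_log2 > 0) {
    lv <- lv + stats::rnorm(length(lv), sd = noise_sd_log2)
  }
  vals <- 2^lv
  rownames(vals) <- sprintf("tr_%05d", seq_len(n_transcripts))
  colnames(vals) <- c(sprintf("A_%d", seq_len(n_per_group)),
                      sprintf("B_%d", seq_len(n_per_group)))
  em <- expression_matrix(vals, c(rep("A", n_per_group),
                                  rep("B", n_per_group)))
  attr(em, "spiked") <- rownames(vals)[seq_len(n_spiked)]
  em
}
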