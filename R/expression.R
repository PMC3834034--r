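#' Quantile-normalize an expression matrix
#'
#' Forces every sample's intensity distribution to be identical: each
#' column's sorted values are replaced by the row-wise mean of the sorted
#' input columns; ties within a column receive the mean of the quantile
#' values they span. Idempotent. Delegates to
#' [limma::normalizeQuantiles()], the standard microarray implementation.
#'
#' @param x An [expression_matrix()] or a positive numeric matrix without
#'   missing values.
#' @return Same type as the input, normalized.
#' @export
quantile_normalize <- function(x) {
  vals <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (anyNA(vals)) {
    stop("quantile normalization requires a complete matrix; ",
         "impute missing values first", call. = FALSE)
  }
  if (ncol(vals) < 2) stop("at least 2 columns are required", call. = FALSE)
  norm <- limma::normalizeQuantiles(vals, ties = TRUE)
  dimnames(norm) <- dimnames(vals)
  if (inherits(x, "expression_matrix")) {
    x$values <- norm
    x
  } else {
    norm
  }
}

#' Signed fold change between two group means
#'
#' The mixed-sign reporting convention of microarray gene lists: the ratio
#' `r = mean_a / mean_b` is reported as `+r` when `r >= 1` and as `-1/r`
#' when `r < 1`, so up- and down-regulation are symmetric around +/-1 and
#' `|fold| >= 1` always.
#'
#' @param mean_a,mean_b Positive group means. Vectorized.
#' @return Signed fold change.
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  if (any(mean_a <= 0) || any(mean_b <= 0)) {
    stop("group means must be positive", call. = FALSE)
  }
  r <- mean_a / mean_b
  ifelse(r >= 1, r, -1 / r)
}

#' Per-transcript two-group test
#'
#' Default: Welch's unequal-variance two-sample t-test on log2 intensities
#' (cross-group animals are distinct individuals, so an unpaired test is the
#' defensible default even where "paired t-test with unequal variance" is
#' quoted — that combination is self-contradictory). A paired mode is
#' available when an explicit pairing of group-A to group-B columns is
#' supplied. Transcripts with zero variance in both groups get their
#' standard error floored at a documented small value and are flagged.
#'
#' @param em An [expression_matrix()].
#' @param method `"welch"` (default) or `"paired"`.
#' @param pairing For `"paired"`: integer vector mapping each group-A
#'   sample (in column order) to its group-B partner column index within
#'   group B.
#' @param se_floor Smallest admissible standard error of the log2 mean
#'   difference (absolute, log2 units).
#' @return Data frame with `transcript`, `mean_a`, `mean_b` (linear group
#'   means), `fold` (signed), `log2_diff`, `t`, `df`, `p`, `low_variance`.
#' @export
de_test <- function(em, method = c("welch", "paired"), pairing = NULL,
                    se_floor = 1e-8) {
  stopifnot(inherits(em, "expression_matrix"))
  method <- match.arg(method)
  ai <- em$groups == em$levels[1]
  bi <- em$groups == em$levels[2]
  lv <- log2(em$values)
  na <- sum(ai); nb <- sum(bi)
  ma <- rowMeans(lv[, ai, drop = FALSE])
  mb <- rowMeans(lv[, bi, drop = FALSE])

  if (method == "welch") {
    va <- apply(lv[, ai, drop = FALSE], 1, stats::var)
    vb <- apply(lv[, bi, drop = FALSE], 1, stats::var)
    se2 <- va / na + vb / nb
    low <- se2 < se_floor^2
    se2[low] <- se_floor^2
    tt <- (ma - mb) / sqrt(se2)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
    df[low | !is.finite(df)] <- na + nb - 2
  } else {
    if (is.null(pairing)) {
      stop("paired mode requires an explicit pairing map", call. = FALSE)
    }
    stopifnot(length(pairing) == na, all(pairing %in% seq_len(nb)))
    d <- lv[, which(ai), drop = FALSE] -
      lv[, which(bi)[pairing], drop = FALSE]
    md <- rowMeans(d)
    sd_d <- apply(d, 1, stats::sd)
    se <- sd_d / sqrt(na)
    low <- se < se_floor
    se[low] <- se_floor
    tt <- md / se
    df <- rep(na - 1, length(md))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  p[tt == 0] <- 1
  mean_a_lin <- rowMeans(em$values[, ai, drop = FALSE])
  mean_b_lin <- rowMeans(em$values[, bi, drop = FALSE])
  data.frame(
    transcript = rownames(em$values),
    mean_a = mean_a_lin,
    mean_b = mean_b_lin,
    fold = signed_fold_change(mean_a_lin, mean_b_lin),
    log2_diff = ma - mb,
    t = tt, df = df, p = pmin(p, 1),
    low_variance = low,
    row.names = NULL
  )
}

#' Select differentially expressed genes
#'
#' A transcript is selected iff `|fold| >= fc_threshold` and
#' `p <= p_threshold`, both inclusive; selected transcripts are labeled
#' up or down by the sign of the fold.
#'
#' @param folds Signed fold changes.
#' @param pvalues Aligned p-values (same length as `folds`).
#' @param fc_threshold Fold-change threshold (>= 1); default 1.3.
#' @param p_threshold P-value threshold; default 0.05.
#' @param transcripts Optional transcript ids (defaults to indices).
#' @param adjust `"none"` (default, for parity with threshold-style gene
#'   lists) or `"BH"` for Benjamini-Hochberg adjustment before filtering.
#' @return Data frame of selected records: `transcript`, `fold`, `p`,
#'   `direction` (`"up"` / `"down"`).
#' @export
select_genes <- function(folds, pvalues, fc_threshold = 1.3,
                         p_threshold = 0.05, transcripts = NULL,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(folds) != length(pvalues)) {
    stop("folds and pvalues must be aligned (equal length)", call. = FALSE)
  }
  stopifnot(fc_threshold >= 1)
  if (is.null(transcripts)) transcripts <- as.character(seq_along(folds))
  if (length(transcripts) != length(folds)) {
    stop("transcripts must be aligned with folds", call. = FALSE)
  }
  p_use <- if (adjust == "BH") stats::p.adjust(pvalues, "BH") else pvalues
  sel <- !is.na(folds) & !is.na(p_use) &
    abs(folds) >= fc_threshold & p_use <= p_threshold
  data.frame(
    transcript = transcripts[sel],
    fold = folds[sel],
    p = p_use[sel],
    direction = ifelse(folds[sel] >= 0, "up", "down"),
    row.names = NULL
  )
}

#' Complete-separation criterion per transcript
#'
#' The alternative gene-list rule: a transcript separates the groups when
#' the highest signal in one group is at or below the lowest signal in the
#' other group.
#'
#' @param em An [expression_matrix()].
#' @return Logical vector, one entry per transcript.
#' @export
separation_criterion <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  ai <- em$groups == em$levels[1]
  bi <- em$groups == em$levels[2]
  a <- em$values[, ai, drop = FALSE]
  b <- em$values[, bi, drop = FALSE]
  max_a <- apply(a, 1, max); min_a <- apply(a, 1, min)
  max_b <- apply(b, 1, max); min_b <- apply(b, 1, min)
  (max_a <= min_b) | (max_b <= min_a)
}

#' Run the full expression-selection stage
#'
#' Quantile normalization, per-transcript testing and threshold selection
#' in one call.
#'
#' @inheritParams de_test
#' @inheritParams select_genes
#' @param normalize Quantile-normalize first (default `TRUE`).
#' @param separation Additionally require the complete-separation criterion.
#' @return List with `tests` (full [de_test()] table) and `selected`
#'   (the [select_genes()] records).
#' @export
run_expression_selection <- function(em, fc_threshold = 1.3,
                                     p_threshold = 0.05,
                                     method = c("welch", "paired"),
                                     pairing = NULL, normalize = TRUE,
                                     adjust = c("none", "BH"),
                                     separation = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  if (normalize) em <- quantile_normalize(em)
  tests <- de_test(em, method = method, pairing = pairing)
  selected <- select_genes(tests$fold, tests$p, fc_threshold, p_threshold,
                           transcripts = tests$transcript, adjust = adjust)
  if (separation) {
    sep <- separation_criterion(em)
    names(sep) <- rownames(em$values)
    selected <- selected[sep[selected$transcript], , drop = FALSE]
  }
  list(tests = tests, selected = selected)
}

#' Read an expression matrix from a TSV file plus group assignments
#'
#' @param matrix_tsv TSV with transcript rows and a header of sample ids
#'   (first column = transcript id).
#' @param groups_csv Two-column CSV `sample,group`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(matrix_tsv, groups_csv) {
  vals <- utils::read.delim(matrix_tsv, row.names = 1, check.names = FALSE)
  grp <- utils::read.csv(groups_csv, stringsAsFactors = FALSE)
  if (!all(colnames(vals) %in% grp[[1]])) {
    stop("every sample column needs a group assignment", call. = FALSE)
  }
  expression_matrix(as.matrix(vals),
                    grp[[2]][match(colnames(vals), grp[[1]])])
}
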