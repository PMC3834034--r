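#' Parse a bisulfite amplicon definition table
#'
#' Reads a tab-separated amplicon table in the published column order:
#' amplicon id, strand direction (F/R), chromosome, start and end relative
#' to the gene start (no position 0), printed amplicon length, CpG count,
#' and the tagged left/right primer sequences. Both the ASCII hyphen and the
#' Unicode minus (U+2212, as typeset in journal tables) are accepted for
#' negative coordinates.
#'
#' @param path Path to the TSV file (UTF-8), or a character vector of lines
#'   via `text`.
#' @param text Optional literal TSV text (overrides `path`).
#' @return Data frame of class `amplicon_table` with columns `amplicon`,
#'   `direction`, `chromosome`, `start_rel`, `end_rel`, `length`,
#'   `cpg_count`, `left_primer`, `right_primer`.
#' @export
parse_amplicon_table <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE))
  } else {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- length(fields) > 0 &&
    grepl("amplicon", fields[[1]][1], ignore.case = TRUE)
  if (has_header) fields <- fields[-1]
  if (!length(fields)) stop("empty amplicon table", call. = FALSE)

  to_int <- function(s, row, what) {
    s <- gsub("−", "-", trimws(s))
    v <- suppressWarnings(as.integer(s))
    if (is.na(v)) {
      stop(sprintf("row '%s': non-integer %s value '%s'", row, what, s),
           call. = FALSE)
    }
    v
  }
  rows <- lapply(fields, function(f) {
    if (length(f) < 7) {
      stop(sprintf("row '%s': expected at least 7 tab-separated columns",
                   f[1]), call. = FALSE)
    }
    id <- trimws(f[1])
    data.frame(
      amplicon = id,
      direction = trimws(f[2]),
      chromosome = trimws(f[3]),
      start_rel = to_int(f[4], id, "start"),
      end_rel = to_int(f[5], id, "end"),
      length = to_int(f[6], id, "length"),
      cpg_count = to_int(f[7], id, "CpG count"),
      left_primer = if (length(f) >= 8) trimws(f[8]) else NA_character_,
      right_primer = if (length(f) >= 9) trimws(f[9]) else NA_character_
    )
  })
  out <- do.call(rbind, rows)
  if (!all(out$direction %in% c("F", "R"))) {
    stop("direction must be 'F' or 'R'", call. = FALSE)
  }
  if (any(out$start_rel >= out$end_rel)) {
    bad <- out$amplicon[out$start_rel >= out$end_rel]
    stop("start must precede end for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("amplicon_table", "data.frame")
  out
}

#' Gene-relative amplicon span (no-zero inclusive convention)
#'
#' Gene-relative coordinates skip position 0 (the base before the start is
#' -1, the start itself +1), so the inclusive span is `end - start + 1` when
#' both ends share a sign and `|start| + end` when the amplicon crosses the
#' gene start.
#'
#' @param start_rel,end_rel Integer gene-relative coordinates
#'   (`start_rel <= end_rel`, neither 0). Vectorized.
#' @return Integer span.
#' @export
amplicon_span <- function(start_rel, end_rel) {
  stopifnot(all(start_rel != 0), all(end_rel != 0), all(start_rel <= end_rel))
  ifelse(sign(start_rel) == sign(end_rel),
         end_rel - start_rel + 1L,
         -start_rel + end_rel)
}

#' Audit amplicon coordinates against the printed lengths
#'
#' Recomputes every amplicon's span with the no-zero inclusive convention
#' and compares it to the printed length. Mismatches are reported as
#' warnings (the printed table, not the convention, may be in error) —
#' never silently corrected.
#'
#' @param amplicons An [parse_amplicon_table()] result.
#' @return The table with added columns `computed_span` and `span_ok`;
#'   a warning lists any mismatching amplicons.
#' @export
validate_amplicons <- function(amplicons) {
  stopifnot(inherits(amplicons, "amplicon_table"))
  out <- amplicons
  out$computed_span <- amplicon_span(out$start_rel, out$end_rel)
  out$span_ok <- out$computed_span == out$length
  if (any(!out$span_ok)) {
    bad <- out[!out$span_ok, ]
    warning(sprintf(
      "printed length inconsistent with computed span for %d amplicon(s): %s",
      nrow(bad),
      paste(sprintf("%s (printed %d, computed %d)",
                    bad$amplicon, bad$length, bad$computed_span),
            collapse = "; ")), call. = FALSE)
  }
  out
}

#' Bundled amplicon definition table
#'
#' Returns the path to the 38-row promoter amplicon table shipped with the
#' package (candidate genes PTPRS, PPP1R3E, SORT1, WNT5B, PDE9A, FGFR4,
#' FABP5).
#'
#' @return File path.
#' @export
amplicon_table_path <- function() {
  system.file("extdata", "amplicon_table.tsv", package = "liverLD",
              mustWork = TRUE)
}

#' Observed mean methylation difference per site
#'
#' `mean(experimental) - mean(control)` at every site, with missing values
#' excluded within each group (complete-case per site and group). A site
#' where one group is entirely missing yields `NA` with a warning.
#'
#' @param mm A [methylation_matrix()].
#' @return Named numeric vector of differences, one per site.
#' @export
observed_difference <- function(mm) {
  stopifnot(inherits(mm, "methylation_matrix"))
  ei <- mm$groups == "experimental"
  ci <- mm$groups == "control"
  me <- rowMeans(mm$values[, ei, drop = FALSE], na.rm = TRUE)
  mc <- rowMeans(mm$values[, ci, drop = FALSE], na.rm = TRUE)
  d <- me - mc
  bad <- !is.finite(d)
  if (any(bad)) {
    d[bad] <- NA_real_
    warning("site(s) skipped (one group fully missing): ",
            paste(rownames(mm$values)[bad], collapse = ", "), call. = FALSE)
  }
  d
}

#' Label-reassignment permutation test for methylation differences
#'
#' The significance procedure applied to per-CpG methylation ratios: the
#' observed experimental-minus-control mean difference is compared with the
#' differences obtained after reassigning samples to the two groups. When
#' the number of distinct relabelings `choose(n, n_experimental)` does not
#' exceed `exhaustive_cap`, all relabelings are enumerated and p-values are
#' exact rationals; otherwise `n_perm` random relabelings are drawn and the
#' observed labeling is included in the null set, so the Monte-Carlo p lies
#' in `[1/(n_perm+1), 1]`.
#'
#' Two-sided by default: `p` is the fraction of relabelings whose absolute
#' difference is at least the observed absolute difference. With 3 samples
#' per group only 20 relabelings exist and the observed split always ties
#' with its mirror image, so the smallest attainable two-sided p is 0.1 —
#' the result records the attainable level rather than silently comparing
#' to an unattainable nominal alpha.
#'
#' @param mm A [methylation_matrix()].
#' @param alpha Significance level for the `significant` flag.
#' @param n_perm Number of Monte-Carlo relabelings (used only above the
#'   exhaustive cap).
#' @param seed Integer seed (Monte-Carlo mode only; exhaustive results are
#'   seed-invariant).
#' @param exhaustive_cap Enumerate all relabelings when their number is at
#'   most this cap.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Object of class `permutation_result`: data frame `sites` with
#'   `site`, `observed_diff`, `p`, `significant`, plus fields `n_relabelings`,
#'   `mode` (`"exhaustive"` or `"monte-carlo"`), `min_attainable_p`,
#'   `alpha`, `seed`.
#' @export
permutation_test <- function(mm, alpha = 0.1, n_perm = 1000L, seed = 1L,
                             exhaustive_cap = 10000L,
                             alternative = c("two.sided", "greater", "less")) {
  stopifnot(inherits(mm, "methylation_matrix"))
  alternative <- match.arg(alternative)
  n1 <- sum(mm$groups == "experimental")
  n <- length(mm$groups)
  n_total <- choose(n, n1)
  if (n_total < 2) stop("degenerate design: only one relabeling exists",
                        call. = FALSE)
  obs <- observed_difference(mm)

  vals <- mm$values
  exhaustive <- n_total <= exhaustive_cap
  if (exhaustive) {
    combos <- utils::combn(n, n1)
  } else {
    set.seed(seed)
    combos <- vapply(seq_len(n_perm), function(i) sort(sample.int(n, n1)),
                     integer(n1))
    combos <- cbind(which(mm$groups == "experimental"), combos)
  }
  w <- matrix(-1 / (n - n1), n, ncol(combos))
  for (j in seq_len(ncol(combos))) w[combos[, j], j] <- 1 / n1
  # NA-aware group means per relabeling
  vals0 <- vals; vals0[is.na(vals0)] <- 0
  pres <- 1 - is.na(vals)
  sel <- matrix(0, n, ncol(combos)); sel[cbind(c(combos), rep(seq_len(ncol(combos)), each = n1))] <- 1
  sum_sel <- vals0 %*% sel
  cnt_sel <- pres %*% sel
  sum_all <- rowSums(vals0)
  cnt_all <- rowSums(pres)
  diff_mat <- sum_sel / cnt_sel - (sum_all - sum_sel) / (cnt_all - cnt_sel)

  eps <- 1e-12
  stat_obs <- switch(alternative,
                     two.sided = abs(obs), greater = obs, less = -obs)
  stat_perm <- switch(alternative,
                      two.sided = abs(diff_mat), greater = diff_mat,
                      less = -diff_mat)
  count <- rowSums(stat_perm >= (stat_obs - eps), na.rm = TRUE)
  denom <- if (exhaustive) n_total else ncol(combos)
  p <- count / denom
  p[is.na(obs)] <- NA_real_

  min_p <- if (exhaustive && alternative == "two.sided") 2 / n_total
           else 1 / denom
  structure(
    list(
      sites = data.frame(site = rownames(vals),
                         observed_diff = as.numeric(obs),
                         p = as.numeric(p),
                         significant = !is.na(p) & p <= alpha,
                         row.names = NULL),
      n_relabelings = denom,
      mode = if (exhaustive) "exhaustive" else "monte-carlo",
      min_attainable_p = min_p,
      alpha = alpha,
      alternative = alternative,
      seed = if (exhaustive) NA_integer_ else as.integer(seed)
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d sites, %s over %d relabelings (%s)\n",
    nrow(x$sites), x$mode, x$n_relabelings, x$alternative))
  cat(sprintf(
    "  alpha = %g; smallest attainable p = %g%s; %d significant site(s)\n",
    x$alpha, x$min_attainable_p,
    if (x$alpha < x$min_attainable_p) " (alpha is NOT attainable)" else "",
    sum(x$sites$significant, na.rm = TRUE)))
  invisible(x)
}

#' Per-amplicon report of significant CpG sites
#'
#' Maps site ids back to their amplicons (ids are expected to carry the
#' amplicon id as a prefix, e.g. `PTPRS_amp03_CpG_4`) and lists the
#' significant sites per amplicon with the amplicon's gene-relative
#' coordinates. No pooling beyond the listing is applied.
#'
#' @param result A [permutation_test()] result.
#' @param amplicons An [parse_amplicon_table()] table.
#' @return Data frame with `amplicon`, `start_rel`, `end_rel`, `site`,
#'   `observed_diff`, `p` for significant sites only (zero rows when none);
#'   unmapped site ids trigger a warning.
#' @export
summarize_promoter <- function(result, amplicons) {
  stopifnot(inherits(result, "permutation_result"),
            inherits(amplicons, "amplicon_table"))
  sites <- result$sites
  amp_of <- rep(NA_character_, nrow(sites))
  for (a in amplicons$amplicon) {
    hit <- startsWith(sites$site, paste0(a, "_"))
    amp_of[hit] <- a
  }
  if (any(is.na(amp_of))) {
    warning("unmapped site id(s): ",
            paste(utils::head(sites$site[is.na(amp_of)], 10), collapse = ", "),
            call. = FALSE)
  }
  keep <- sites$significant & !is.na(amp_of)
  if (!any(keep)) {
    return(data.frame(amplicon = character(0), start_rel = integer(0),
                      end_rel = integer(0), site = character(0),
                      observed_diff = numeric(0), p = numeric(0)))
  }
  out <- data.frame(amplicon = amp_of[keep],
                    site = sites$site[keep],
                    observed_diff = sites$observed_diff[keep],
                    p = sites$p[keep])
  out <- merge(out,
               amplicons[, c("amplicon", "start_rel", "end_rel")],
               by = "amplicon", sort = TRUE)
  out[, c("amplicon", "start_rel", "end_rel", "site", "observed_diff", "p")]
}

#' Read a methylation matrix from CSV files
#'
#' @param values_csv CSV with site rows and sample columns (first column =
#'   site id).
#' @param groups_csv Two-column CSV `sample,group` with groups
#'   `experimental` / `control`.
#' @return A [methylation_matrix()].
#' @export
read_methylation_csv <- function(values_csv, groups_csv) {
  vals <- utils::read.csv(values_csv, row.names = 1, check.names = FALSE)
  grp <- utils::read.csv(groups_csv, stringsAsFactors = FALSE)
  if (!all(colnames(vals) %in% grp[[1]])) {
    stop("every sample column needs a group assignment", call. = FALSE)
  }
  methylation_matrix(as.matrix(vals),
                     grp[[2]][match(colnames(vals), grp[[1]])])
}
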