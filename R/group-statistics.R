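#' Long-format observation table for the 2x2 group design
#'
#' One row per measured value, annotated with the two crossed factors of
#' the study design — birth weight (`U` low / `N` normal) and diet (`K`
#' ad-libitum control / `R` feed-restricted) — plus the time point.
#'
#' @param df Data frame with columns `animal`, `birth_weight` (`U`/`N`),
#'   `diet` (`K`/`R`), `timepoint` (`T1`, `T2`, `T2.1`, `T3`), `quantity`,
#'   `value`.
#' @return The validated data frame, class `observation_table`.
#' @export
observation_table <- function(df) {
  need <- c("animal", "birth_weight", "diet", "timepoint", "quantity", "value")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$birth_weight %in% c("U", "N"))) {
    stop("birth_weight must be 'U' or 'N'", call. = FALSE)
  }
  if (!all(df$diet %in% c("K", "R"))) {
    stop("diet must be 'K' or 'R'", call. = FALSE)
  }
  if (!all(df$timepoint %in% c("T1", "T2", "T2.1", "T3"))) {
    stop("timepoint must be one of T1, T2, T2.1, T3", call. = FALSE)
  }
  if (!is.numeric(df$value)) stop("value must be numeric", call. = FALSE)
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Normality gate with log transform
#'
#' Applies a Shapiro-Wilk test at level `alpha`; when normality is rejected
#' (p <= alpha) the values are natural-log transformed (requiring positive
#' values) and the transform flag is set — the conventional reading of
#' "not-normally distributed data were log-transformed". A constant vector
#' is passed through untransformed (the test is degenerate there).
#'
#' @param values Numeric vector (n between 3 and 5000 for the test).
#' @param alpha Rejection level of the normality test (default 0.05).
#' @param quantity Name used in error messages.
#' @return List with `values` (possibly transformed), `transformed` flag,
#'   and `shapiro_p` (`NA` for the degenerate constant case).
#' @export
normality_gate <- function(values, alpha = 0.05, quantity = "quantity") {
  stopifnot(is.numeric(values), length(values) >= 3)
  if (stats::sd(values) == 0) {
    return(list(values = values, transformed = FALSE, shapiro_p = NA_real_))
  }
  p <- stats::shapiro.test(values)$p.value
  if (p > alpha) {
    return(list(values = values, transformed = FALSE, shapiro_p = p))
  }
  if (any(values <= 0)) {
    stop(sprintf("'%s' fails the normality test but has non-positive values; %s",
                 quantity, "log transform impossible"), call. = FALSE)
  }
  list(values = log(values), transformed = TRUE, shapiro_p = p)
}

# Cell means and balance check for the 2x2 birth_weight x diet layout.
check_balanced_2x2 <- function(df) {
  cells <- expand.grid(birth_weight = c("U", "N"), diet = c("K", "R"),
                       stringsAsFactors = FALSE)
  n_cell <- integer(4)
  for (i in seq_len(4)) {
    n_cell[i] <- sum(df$birth_weight == cells$birth_weight[i] &
                     df$diet == cells$diet[i])
    if (n_cell[i] == 0) {
      stop(sprintf("empty design cell: birth_weight=%s, diet=%s",
                   cells$birth_weight[i], cells$diet[i]), call. = FALSE)
    }
  }
  if (length(unique(n_cell)) != 1) {
    stop("unbalanced 2x2 design (cell sizes ",
         paste(n_cell, collapse = ", "),
         "); balanced designs only", call. = FALSE)
  }
  if (n_cell[1] < 2) stop("at least 2 replicates per cell are required",
                          call. = FALSE)
  n_cell[1]
}

#' Balanced two-way ANOVA with the factors birth weight and feed restriction
#'
#' Subsets one quantity (and optionally one time point), applies the
#' normality gate, and fits `value ~ birth_weight * diet` on the balanced
#' 2x2 design via [stats::aov()]. For a balanced design the sequential sums
#' of squares of main effects, interaction and residual partition the total,
#' and every F ratio is against the residual mean square.
#'
#' @param table An [observation_table()].
#' @param quantity Quantity name to analyse.
#' @param timepoint Optional time point filter.
#' @param gate_normality Apply [normality_gate()] first (default `TRUE`).
#' @param alpha Normality-gate level.
#' @return List of class `anova_report`: `quantity`, `terms` (data frame
#'   with `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p`), `transformed`,
#'   `no_variance` flag, `cell_means`, `n_per_cell`.
#' @export
two_way_anova <- function(table, quantity, timepoint = NULL,
                          gate_normality = TRUE, alpha = 0.05) {
  stopifnot(inherits(table, "observation_table"))
  df <- table[table$quantity == quantity, ]
  if (!is.null(timepoint)) df <- df[df$timepoint == timepoint, ]
  if (!nrow(df)) stop("no observations for quantity '", quantity, "'",
                      call. = FALSE)
  check_balanced_2x2(df)

  transformed <- FALSE
  vals <- df$value
  no_var <- stats::sd(vals) == 0
  if (gate_normality && !no_var) {
    g <- normality_gate(vals, alpha = alpha, quantity = quantity)
    vals <- g$values
    transformed <- g$transformed
  }
  df$.y <- vals
  fit <- stats::aov(.y ~ birth_weight * diet, data = df)
  tab <- summary(fit)[[1]]
  terms <- data.frame(
    term = trimws(rownames(tab)),
    df = tab[["Df"]],
    sum_sq = tab[["Sum Sq"]],
    mean_sq = tab[["Mean Sq"]],
    F = tab[["F value"]],
    p = tab[["Pr(>F)"]]
  )
  cell_means <- stats::aggregate(.y ~ birth_weight + diet, data = df, mean)
  structure(
    list(quantity = quantity, terms = terms, transformed = transformed,
         no_variance = no_var, cell_means = cell_means,
         n_per_cell = nrow(df) / 4),
    class = "anova_report"
  )
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("<anova_report> %s (n = %g per cell%s%s)\n", x$quantity,
              x$n_per_cell,
              if (x$transformed) ", log-transformed" else "",
              if (x$no_variance) ", NO VARIANCE" else ""))
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bonferroni adjustment for post-hoc pairwise p-values
#'
#' `adjusted = min(1, m * raw)` for a family of `m` comparisons.
#'
#' @param p Raw p-values. Vectorized.
#' @param m Family size (>= 1); defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Percent-deviation contrast table with post-hoc significance gating
#'
#' For each requested contrast `A vs B` (groups named by birth weight +
#' diet, e.g. `"UR"` vs `"UK"`), the percent deviation
#' `100 * (mean_A - mean_B) / mean_B` is reported when the
#' Bonferroni-adjusted post-hoc p-value is at or below `alpha`; trends
#' (adjusted `alpha < p <= trend_alpha`) are shown in parentheses; anything
#' weaker prints the literal marker `"ns"`. Reductions come out negative and
#' increases positive. The post-hoc t statistic uses the residual mean
#' square of the fitted 2x2 model, and the family size is the number of
#' requested contrasts.
#'
#' @param table An [observation_table()].
#' @param quantity Quantity to contrast.
#' @param contrasts List of 2-element character vectors `c(A, B)` with
#'   group codes from `{UK, UR, NK, NR}`.
#' @param timepoint Optional time point filter.
#' @param alpha Significance level (default 0.05).
#' @param trend_alpha Upper bound of the trend band (default 0.1).
#' @param gate_normality Passed to [two_way_anova()]; the post-hoc means
#'   and percent deviations are always computed on the original scale.
#' @return Data frame with `group_a`, `group_b`, `percent`, `p_raw`,
#'   `p_adjusted`, and `cell` (the formatted table entry).
#' @export
percent_deviation_table <- function(table, quantity, contrasts,
                                    timepoint = NULL, alpha = 0.05,
                                    trend_alpha = 0.1,
                                    gate_normality = TRUE) {
  stopifnot(inherits(table, "observation_table"), length(contrasts) >= 1)
  df <- table[table$quantity == quantity, ]
  if (!is.null(timepoint)) df <- df[df$timepoint == timepoint, ]
  n_cell <- check_balanced_2x2(df)
  df$group <- paste0(df$birth_weight, df$diet)
  groups <- unique(df$group)
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% groups)) {
      stop("unknown group in contrast: ", paste(ct, collapse = " vs "),
           call. = FALSE)
    }
  }
  rep_fit <- two_way_anova(observation_table(df), quantity,
                           timepoint = NULL, gate_normality = gate_normality)
  res <- rep_fit$terms[rep_fit$terms$term == "Residuals", ]
  mse <- res$mean_sq
  dfres <- res$df
  # Post-hoc means on the analysis scale for the t statistic
  scale_vals <- if (rep_fit$transformed) log(df$value) else df$value
  m_scale <- tapply(scale_vals, df$group, mean)
  m_raw <- tapply(df$value, df$group, mean)

  m <- length(contrasts)
  rows <- lapply(contrasts, function(ct) {
    a <- ct[1]; b <- ct[2]
    tt <- (m_scale[[a]] - m_scale[[b]]) / sqrt(mse * 2 / n_cell)
    p_raw <- 2 * stats::pt(-abs(tt), dfres)
    p_adj <- bonferroni_adjust(p_raw, m)
    pct <- 100 * (m_raw[[a]] - m_raw[[b]]) / m_raw[[b]]
    cell <- if (!is.finite(p_adj)) "ns"
      else if (p_adj <= alpha) sprintf("%+.1f", pct)
      else if (p_adj <= trend_alpha) sprintf("(%+.1f)", pct)
      else "ns"
    data.frame(group_a = a, group_b = b, percent = pct,
               p_raw = p_raw, p_adjusted = p_adj, cell = cell)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
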