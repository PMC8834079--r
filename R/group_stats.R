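#' Per-group summary statistics
#'
#' @param values Numeric vector of replicate values.
#' @param groups Group label for each value.
#' @return Data frame with one row per group: `group`, `n`, `mean`, `se`
#'   (sample standard deviation over the square root of n).
#' @examples
#' summarize_groups(c(1, 2, 3), rep("WT", 3))  # mean 2, SE 0.577
#' @export
summarize_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  ns <- table(groups)
  if (any(ns < 2L)) {
    ojip_abort("every group needs at least 2 replicates",
               "ojip_insufficient_replicates_error")
  }
  out <- lapply(split(values, groups), function(v) {
    data.frame(n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))
  })
  cbind(data.frame(group = names(out), stringsAsFactors = FALSE),
        do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' One-way ANOVA with Fisher's LSD post hoc comparison
#'
#' Fits the standard homoscedastic one-way ANOVA and, for the first pair of
#' groups, computes Fisher's least significant difference
#' `t(alpha, df_within) * sqrt(MSW (1/n_i + 1/n_j))`. The pair is flagged
#' significant when the omnibus p-value is below `alpha` and the absolute
#' mean difference exceeds the LSD. For two groups the ANOVA F equals the
#' square of the pooled-variance t statistic, so the p-values coincide.
#' Degenerate case: zero within-group variance with unequal means is
#' reported as significant with the p-value at the smallest positive
#' double, never NaN.
#'
#' @param values Numeric replicate values.
#' @param groups Group label per value (>= 2 groups, each n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `group_comparison`: `summary` (per-group n,
#'   mean, se), `F_statistic`, `p_value`, `lsd_threshold`, `mean_diff`
#'   (first minus second group), `significant`, `alpha`.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  summ <- summarize_groups(values, groups)
  if (nrow(summ) < 2L) {
    ojip_abort("need at least 2 groups", "ojip_validation_error")
  }
  g <- factor(groups, levels = unique(groups))
  fit <- stats::lm(values ~ g)
  # perfect fits (zero residual variance) warn inside anova(); that case is
  # handled explicitly below
  an <- suppressWarnings(stats::anova(fit))
  msw <- an["Residuals", "Mean Sq"]
  df_w <- an["Residuals", "Df"]
  f_stat <- an[1L, "F value"]
  p <- an[1L, "Pr(>F)"]

  lev <- levels(g)
  n1 <- summ$n[summ$group == lev[1L]]
  n2 <- summ$n[summ$group == lev[2L]]
  m1 <- summ$mean[summ$group == lev[1L]]
  m2 <- summ$mean[summ$group == lev[2L]]
  lsd <- stats::qt(1 - alpha / 2, df_w) * sqrt(msw * (1 / n1 + 1 / n2))

  if (msw == 0) {
    if (abs(m1 - m2) > 0) {
      f_stat <- Inf
      p <- .Machine$double.xmin
    } else {
      f_stat <- 0
      p <- 1
    }
  }
  structure(list(summary = summ, F_statistic = f_stat, p_value = p,
                 lsd_threshold = lsd, mean_diff = m1 - m2,
                 significant = is.finite(p) && p < alpha &&
                   abs(m1 - m2) > lsd,
                 alpha = alpha),
            class = "group_comparison")
}

#' Two-group comparison from summary statistics
#'
#' Pooled-variance (or Welch) t test reconstructed from per-group n, mean
#' and standard error — the entry point for published tables that print
#' only `mean +/- SE`.
#'
#' @param n,mean,se Numeric vectors of length 2 (one entry per group).
#' @param alpha Significance level.
#' @param welch Use the Welch (unequal-variance) t test instead of the
#'   pooled-variance test.
#' @return A list of class `group_comparison` (F reported as t squared).
#' @examples
#' # chlorophyll a, green vs yellow leaves: 0.38 +/- 0.02 vs 0.07 +/- 0.003
#' anova_lsd_from_summary(n = c(3, 3), mean = c(0.38, 0.07),
#'                        se = c(0.02, 0.003))$significant
#' @export
anova_lsd_from_summary <- function(n, mean, se, alpha = 0.05,
                                   welch = FALSE) {
  stopifnot(length(n) == 2L, length(mean) == 2L, length(se) == 2L,
            all(n >= 2L), all(se >= 0))
  sd <- se * sqrt(n)
  if (welch) {
    v <- se[1L]^2 + se[2L]^2
    t_stat <- (mean[1L] - mean[2L]) / sqrt(v)
    df_w <- v^2 / (se[1L]^4 / (n[1L] - 1) + se[2L]^4 / (n[2L] - 1))
    lsd <- stats::qt(1 - alpha / 2, df_w) * sqrt(v)
  } else {
    df_w <- sum(n) - 2
    msw <- ((n[1L] - 1) * sd[1L]^2 + (n[2L] - 1) * sd[2L]^2) / df_w
    lsd <- stats::qt(1 - alpha / 2, df_w) * sqrt(msw * sum(1 / n))
    t_stat <- (mean[1L] - mean[2L]) / sqrt(msw * sum(1 / n))
  }
  if (!is.finite(t_stat)) {  # zero variance
    p <- if (mean[1L] != mean[2L]) .Machine$double.xmin else 1
    t_stat <- if (mean[1L] != mean[2L]) Inf else 0
  } else {
    p <- 2 * stats::pt(-abs(t_stat), df_w)
  }
  structure(list(
    summary = data.frame(group = c("g1", "g2"), n = n, mean = mean, se = se),
    F_statistic = t_stat^2, p_value = p, lsd_threshold = lsd,
    mean_diff = mean[1L] - mean[2L],
    significant = p < alpha && abs(mean[1L] - mean[2L]) > lsd,
    alpha = alpha),
    class = "group_comparison")
}

#' Compare every numeric column of a per-replicate table across groups
#'
#' Runs [anova_lsd()] on each numeric column and renders a publication-style
#' comparison table with `mean +/- SE` strings and a `**` marker on the
#' second group when the difference is significant at `alpha` (single
#' significance tier, no multiple-testing correction by default, matching
#' the usual per-parameter testing of physiology tables; set
#' `p_adjust = "BH"` for Benjamini-Hochberg across parameters).
#'
#' @param table Data frame with one row per replicate.
#' @param group_col Name of the group column.
#' @param alpha Significance level.
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return Data frame with one row per numeric parameter: per-group mean,
#'   se, formatted `mean +/- SE` strings, `F_statistic`, `p_value`,
#'   `significant`.
#' @export
compare_tables <- function(table, group_col = "group", alpha = 0.05,
                           p_adjust = "none") {
  stopifnot(group_col %in% names(table))
  if (length(unique(table[[group_col]])) < 2L) {
    ojip_abort("need at least 2 groups to compare", "ojip_validation_error")
  }
  skip <- c(group_col, "replicate", "ok", "error")
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, skip)
  dropped <- setdiff(names(table), c(num_cols, skip))
  if (length(dropped) > 0L) {
    message("skipping non-numeric column(s): ", paste(dropped, collapse = ", "))
  }
  if ("ok" %in% names(table)) table <- table[table$ok, ]
  groups <- as.character(table[[group_col]])
  lev <- unique(groups)

  rows <- lapply(num_cols, function(col) {
    v <- table[[col]]
    keep <- is.finite(v)
    cmp <- anova_lsd(v[keep], groups[keep], alpha = alpha)
    s <- cmp$summary
    row <- data.frame(parameter = col, stringsAsFactors = FALSE)
    for (gl in lev) {
      row[[paste0("mean_", gl)]] <- s$mean[s$group == gl]
      row[[paste0("se_", gl)]] <- s$se[s$group == gl]
    }
    row$F_statistic <- cmp$F_statistic
    row$p_value <- cmp$p_value
    row$lsd_threshold <- cmp$lsd_threshold
    row$significant <- cmp$significant
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
    out$significant <- out$p_value < alpha & out$significant
  }
  for (gl in lev) {
    mark <- ifelse(out$significant & gl == lev[length(lev)], " **", "")
    out[[paste0("display_", gl)]] <- paste0(
      signif(out[[paste0("mean_", gl)]], 3), " ± ",
      signif(out[[paste0("se_", gl)]], 2), mark)
  }
  out
}
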