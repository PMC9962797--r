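#' Per-feature fold change on the median-scaled intensity scale
#'
#' Each feature is first median-scaled — divided by its across-sample
#' median so the feature's median becomes 1, the convention used for
#' MS metabolite panels — and the fold change is the ratio of scaled group
#' means (group A over group B), reported as `log2_fc`. Zero intensities
#' are optionally imputed with half the feature's smallest positive value
#' before scaling (minimum imputation, standard for MS data). A feature
#' whose group-B mean (or across-sample median) is zero has an undefined
#' fold change and is flagged via `fc_defined = FALSE`.
#'
#' @param table A [feature_table()].
#' @param design A [group_design()].
#' @param contrast Character vector `c(group_a, group_b)`.
#' @param pseudo Impute zeros with half the smallest positive value of the
#'   feature (default `TRUE`).
#' @return A tibble: `feature`, `fc`, `log2_fc`, `fc_defined`.
#' @export
fold_change <- function(table, design, contrast, pseudo = TRUE) {
  check_design(table, design)
  stopifnot(length(contrast) == 2)
  sa <- group_samples(design, contrast[1])
  sb <- group_samples(design, contrast[2])
  vals <- ft_values(table)
  if (pseudo) vals <- impute_zeros(vals)
  med <- apply(vals, 1, median)
  scaled <- vals / ifelse(med > 0, med, NA_real_)
  ma <- rowMeans(scaled[, sa, drop = FALSE])
  mb <- rowMeans(scaled[, sb, drop = FALSE])
  fc <- ifelse(is.na(ma) | is.na(mb) | mb == 0, NA_real_, ma / mb)
  tibble(feature = table$feature,
         fc = unname(fc),
         log2_fc = unname(log2(fc)),
         fc_defined = unname(!is.na(fc)))
}

# minimum imputation: zeros replaced by half the smallest positive value of
# the same feature; all-zero rows are left untouched (flagged downstream)
impute_zeros <- function(vals) {
  for (i in seq_len(nrow(vals))) {
    z <- vals[i, ] == 0
    if (any(z) && !all(z)) vals[i, z] <- min(vals[i, !z]) / 2
  }
  vals
}

#' Volcano statistics for one contrast
#'
#' Composes [fold_change()] and [mann_whitney_exact()] into the per-feature
#' (log2 fold change, -log10 p) pairs of a volcano plot. Features with an
#' undefined fold change are excluded with a message.
#'
#' @inheritParams differential_abundance
#' @param alpha Significance threshold used for the `significant` flag.
#' @return A tibble: `feature`, `log2_fc`, `p_value`, `neg_log10_p`,
#'   `significant`.
#' @export
volcano_stats <- function(table, design, contrast, alpha = 0.05,
                          p_adjust = c("none", "BH"), pseudo = TRUE) {
  res <- differential_abundance(table, design, contrast,
                                p_adjust = match.arg(p_adjust),
                                pseudo = pseudo)
  dropped <- res$feature[!res$fc_defined]
  if (length(dropped)) {
    inform(sprintf("excluded %d feature(s) with undefined fold change: %s",
                   length(dropped),
                   paste(head(dropped, 5), collapse = ", ")))
  }
  res |>
    filter(.data$fc_defined) |>
    mutate(neg_log10_p = -log10(.data$p_value),
           significant = .data$p_value < alpha) |>
    select("feature", "log2_fc", "p_value", "neg_log10_p", "significant")
}

#' Per-feature, per-group box-plot summaries on the log scale
#'
#' Five-number summaries of log10-transformed intensities with Tukey
#' whiskers (1.5 IQR) and explicit outlier lists, matching how
#' significantly altered features are displayed. Zeros are imputed with
#' half the feature's smallest positive value before the log; all-zero
#' features are flagged and summarized as `NA`.
#'
#' @param table A [feature_table()].
#' @param design A [group_design()].
#' @param log_base Base of the log transform (default 10).
#' @return A tibble with one row per feature x group: `feature`, `group`,
#'   `n`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`, `outliers`
#'   (list-column), `all_zero`.
#' @export
boxplot_summaries <- function(table, design, log_base = 10) {
  check_design(table, design)
  vals <- impute_zeros(ft_values(table))
  rows <- list()
  for (g in design_groups(design)) {
    sub <- vals[, group_samples(design, g), drop = FALSE]
    for (f in table$feature) {
      v <- sub[f, ]
      if (all(v == 0)) {
        rows[[length(rows) + 1]] <- tibble(
          feature = f, group = g, n = length(v), median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, whisker_low = NA_real_,
          whisker_high = NA_real_, outliers = list(numeric()),
          all_zero = TRUE)
        next
      }
      lv <- log(v, base = log_base)
      q <- quantile(lv, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      lo <- q[1] - 1.5 * iqr
      hi <- q[3] + 1.5 * iqr
      inside <- lv[lv >= lo & lv <= hi]
      rows[[length(rows) + 1]] <- tibble(
        feature = f, group = g, n = length(v), median = q[2],
        q1 = q[1], q3 = q[3],
        whisker_low = min(inside), whisker_high = max(inside),
        outliers = list(unname(lv[lv < lo | lv > hi])),
        all_zero = FALSE)
    }
  }
  bind_rows(rows)
}

#' Volcano plot
#'
#' @param volcano Output of [volcano_stats()].
#' @param alpha Significance line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano, alpha = 0.05) {
  ggplot2::ggplot(volcano,
                  ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_p,
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey55")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
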