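#' Exact two-sample Mann-Whitney test
#'
#' Computes the Mann-Whitney U statistic with average ranks under ties and
#' a two-sided p-value. For small designs (`nA + nB <= exact_limit`,
#' default 14 — covering a 6-vs-6 comparison) the p-value is exact by full
#' enumeration of all `choose(nA + nB, nA)` group labelings of the observed
#' ranks, so ties are handled by conditioning on the observed tie pattern.
#' Larger designs use the normal approximation with tie and continuity
#' correction. The two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_limit Largest `nA + nB` for which full enumeration is used.
#' @return A one-row tibble: `statistic` (U of `x`), `p_value`, `method`,
#'   `n_x`, `n_y`.
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 14) {
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  if (anyNA(c(x, y))) abort("missing values are not supported")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_limit) {
    null_u <- mw_null_u(r, nx)
    p <- min(1, 2 * min(mean(null_u <= u + 1e-9), mean(null_u >= u - 1e-9)))
    method <- "exact enumeration"
  } else {
    p <- mw_approx_p(u, r, nx, ny)
    method <- "normal approximation"
  }
  tibble(statistic = u, p_value = p, method = method, n_x = nx, n_y = ny)
}

# null distribution of U for the observed rank multiset: U over every
# choose(n, nx) assignment of ranks to the first group
mw_null_u <- function(r, nx) {
  idx <- combn(length(r), nx)
  colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
}

mw_approx_p <- function(u, r, nx, ny) {
  n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(r)
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  if (sigma == 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sigma
  min(1, 2 * pnorm(-abs(z)))
}

#' Group-wise differential abundance by Mann-Whitney
#'
#' Runs [mann_whitney_exact()] feature by feature for one contrast and
#' attaches fold changes on the median-scaled intensity scale, direction,
#' and the star convention used throughout the figures (one star for
#' p < 0.05, two for p < 0.01).
#'
#' @param table A [feature_table()].
#' @param design A [group_design()].
#' @param contrast Character vector `c(group_a, group_b)`; fold changes are
#'   group A over group B.
#' @param p_adjust `"none"` (default, per-feature testing) or `"BH"`.
#' @param pseudo Replace zeros by half the feature's smallest positive
#'   value before scaling (see [fold_change()]).
#' @return A tibble with one row per feature: `feature`, `contrast`,
#'   `statistic`, `p_value`, `log2_fc`, `direction`, `stars`.
#' @export
differential_abundance <- function(table, design, contrast,
                                   p_adjust = c("none", "BH"),
                                   pseudo = TRUE) {
  p_adjust <- match.arg(p_adjust)
  check_design(table, design)
  stopifnot(length(contrast) == 2)
  sa <- group_samples(design, contrast[1])
  sb <- group_samples(design, contrast[2])
  vals <- ft_values(table)
  res <- map(table$feature, function(f) {
    mann_whitney_exact(vals[f, sa], vals[f, sb])
  })
  res <- bind_rows(res)
  fc <- fold_change(table, design, contrast, pseudo = pseudo)
  out <- tibble(feature = table$feature,
                contrast = paste(contrast[1], "vs", contrast[2]),
                statistic = res$statistic,
                p_value = res$p_value) |>
    left_join(fc[, c("feature", "log2_fc", "fc_defined")], by = "feature")
  if (p_adjust == "BH") out$p_value <- p.adjust(out$p_value, method = "BH")
  out |>
    mutate(direction = dplyr::case_when(
             !.data$fc_defined ~ NA_character_,
             .data$log2_fc > 0 ~ "up",
             .data$log2_fc < 0 ~ "down",
             TRUE ~ "none"),
           stars = ifelse(.data$p_value < 0.01, 2L,
                          ifelse(.data$p_value < 0.05, 1L, 0L)))
}
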