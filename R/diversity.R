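#' Shannon diversity of one sample
#'
#' `H = -sum(p_i * log p_i)` over nonzero proportions after renormalizing
#' the input to sum to 1. Natural log (nats) by default; the base is
#' configurable.
#'
#' @param x Non-negative abundance vector with positive sum.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (scalar).
#' @export
shannon_index <- function(x, base = exp(1)) {
  if (any(x < 0) || anyNA(x)) abort("abundances must be non-negative")
  if (sum(x) <= 0) abort("all-zero sample has no diversity")
  as.numeric(vegan::diversity(matrix(x, nrow = 1), index = "shannon",
                              base = base))
}

#' Per-sample alpha diversity with group labels
#'
#' @param table A [feature_table()].
#' @param design A [group_design()].
#' @param base Logarithm base.
#' @return A tibble: `sample`, `group`, `shannon`.
#' @export
alpha_diversity <- function(table, design, base = exp(1)) {
  check_design(table, design)
  vals <- ft_values(table)
  h <- as.numeric(vegan::diversity(t(vals), index = "shannon", base = base))
  tibble(sample = colnames(vals)) |>
    left_join(design, by = "sample") |>
    mutate(shannon = h)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `BC = sum|x_i - y_i| / sum(x_i + y_i)`, bounded in \[0, 1\].
#'
#' @param x,y Non-negative abundance vectors over the same features.
#' @return Dissimilarity scalar.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must cover the same features")
  if (any(c(x, y) < 0)) abort("abundances must be non-negative")
  if (sum(x) == 0 && sum(y) == 0) {
    abort("Bray-Curtis is undefined for two all-zero samples")
  }
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' All pairwise Bray-Curtis dissimilarities
#'
#' @param table A [feature_table()].
#' @return A tibble: `sample_a`, `sample_b`, `dissimilarity` (one row per
#'   unordered sample pair).
#' @export
bray_curtis_matrix <- function(table) {
  vals <- ft_values(table)
  d <- as.matrix(vegan::vegdist(t(vals), method = "bray"))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble(sample_a = rownames(d)[idx[, 1]],
         sample_b = colnames(d)[idx[, 2]],
         dissimilarity = d[idx])
}

#' PCA of metabolite profiles
#'
#' Intensities are zero-imputed (half minimum per feature), log-
#' transformed, and standardized feature-wise to zero mean and unit
#' variance — mapping each metabolite to a normal-like scale around zero —
#' before eigendecomposition of the sample covariance. Zero-variance
#' features are dropped with a message. The sign of each component is
#' fixed by forcing its largest-magnitude loading positive, so scores are
#' reproducible across platforms.
#'
#' @param table A [feature_table()].
#' @param design Optional [group_design()]; group labels are attached to
#'   the scores when given.
#' @param k Number of components to keep (default: all).
#' @param log_transform Log-transform intensities first (default `TRUE`;
#'   use `FALSE` for data already on a log or standardized scale).
#' @return An object of class `micromet_pca`: list with `scores` (tibble),
#'   `loadings` (matrix), `explained_variance` (numeric vector),
#'   `dropped_features` (character).
#' @export
pca_metabolites <- function(table, design = NULL, k = NULL,
                            log_transform = TRUE) {
  vals <- ft_values(table)
  if (nrow(vals) < 2 || ncol(vals) < 2) {
    abort("PCA needs at least 2 features and 2 samples")
  }
  if (log_transform) vals <- log(impute_zeros(vals))
  v <- apply(vals, 1, var)
  dropped <- rownames(vals)[v == 0]
  if (length(dropped)) {
    inform(sprintf("dropped %d zero-variance feature(s): %s",
                   length(dropped), paste(head(dropped, 5), collapse = ", ")))
    vals <- vals[v > 0, , drop = FALSE]
  }
  x <- t(scale(t(vals)))          # features standardized across samples
  fit <- prcomp(t(x), center = FALSE, scale. = FALSE)
  k <- k %||% length(fit$sdev)
  k <- min(k, length(fit$sdev))
  # deterministic sign: largest-magnitude loading of each PC positive
  for (j in seq_len(ncol(fit$rotation))) {
    s <- sign(fit$rotation[which.max(abs(fit$rotation[, j])), j])
    if (s < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- bind_cols(tibble(sample = colnames(vals)), scores)
  if (!is.null(design)) scores <- left_join(scores, design, by = "sample")
  structure(list(scores = scores,
                 loadings = fit$rotation[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 all_explained_variance = ev,
                 standardized = x,
                 dropped_features = dropped),
            class = "micromet_pca")
}

#' @export
print.micromet_pca <- function(x, ...) {
  cat(sprintf("<micromet_pca: %d sample(s), %d component(s); PC1 %.1f%%>\n",
              nrow(x$scores), length(x$explained_variance),
              100 * x$explained_variance[1]))
  invisible(x)
}

#' @export
#' @method tidy micromet_pca
tidy.micromet_pca <- function(x, ...) x$scores

#' @export
#' @method glance micromet_pca
glance.micromet_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_components = length(x$explained_variance),
         pc1_variance = x$explained_variance[1],
         pc2_variance = if (length(x$explained_variance) > 1)
           x$explained_variance[2] else NA_real_)
}

#' @export
#' @method autoplot micromet_pca
autoplot.micromet_pca <- function(object, ...) {
  sc <- object$scores
  aes <- if ("group" %in% names(sc)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
}
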