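#' Spearman rank correlation with exact small-sample p-values
#'
#' Rho is the Pearson correlation of average ranks. The two-sided p-value
#' is exact for `n <= exact_limit` (default 7) by full enumeration of all
#' `n!` permutations of one variable's ranks — conditioning on both
#' variables' tie patterns — as `P(|rho_perm| >= |rho_obs|)`. Larger
#' samples use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, or a seeded Monte-Carlo
#' permutation p when `p_mode = "perm"`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param p_mode `"auto"` (exact when `n <= exact_limit`, else
#'   approximation), `"exact"`, `"approx"`, or `"perm"`.
#' @param exact_limit Largest n for exact enumeration.
#' @param n_perm Number of Monte-Carlo permutations for `p_mode = "perm"`.
#' @param seed Seed for the Monte-Carlo mode.
#' @return A one-row tibble: `rho`, `p_value`, `method`, `n`.
#' @export
spearman_cor <- function(x, y, p_mode = c("auto", "exact", "approx", "perm"),
                         exact_limit = 7, n_perm = 1000, seed = 1L) {
  p_mode <- match.arg(p_mode)
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 3) abort("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_,
                  method = "undefined (zero variance)", n = n))
  }
  rho <- cor(rx, ry)
  if (p_mode == "auto") p_mode <- if (n <= exact_limit) "exact" else "approx"
  if (p_mode == "exact") {
    if (n > 9) abort("exact enumeration is limited to n <= 9")
    null_rho <- spearman_null_rho(rx, ry)
    p <- mean(abs(null_rho) >= abs(rho) - 1e-9)
    method <- "exact enumeration"
  } else if (p_mode == "approx") {
    p <- spearman_t_p(rho, n)
    method <- "t approximation"
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (abs(cor(rx, sample(ry))) >= abs(rho) - 1e-9) hits <- hits + 1L
      }
      (hits + 1) / (n_perm + 1)
    })
    method <- "Monte-Carlo permutation"
  }
  tibble(rho = rho, p_value = p, method = method, n = n)
}

spearman_t_p <- function(rho, n) {
  r2 <- pmin(rho^2, 1 - 1e-12)
  tstat <- rho * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[p > 1] <- 1        # keeps matrix shape, unlike pmin(1, .)
  p
}

# all permutations of seq_len(n), one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# null rho over every permutation of ry against fixed rx
spearman_null_rho <- function(rx, ry) {
  perms <- all_permutations(length(rx))
  a <- as.numeric(scale(rx))
  b <- as.numeric(scale(ry))
  (matrix(b[perms], nrow(perms)) %*% a) / (length(rx) - 1)
}

# Vectorized Spearman of every row of A against every row of B.
# Returns list(rho, p): matrices nrow(A) x nrow(B). Zero-variance rows give
# NA. Exact enumeration (conditional on tie patterns) when n <= exact_limit,
# t approximation otherwise.
spearman_matrix <- function(A, B, exact_limit = 7) {
  n <- ncol(A)
  stopifnot(ncol(B) == n)
  rA <- t(apply(A, 1, rank))
  rB <- t(apply(B, 1, rank))
  sdA <- apply(rA, 1, sd)
  sdB <- apply(rB, 1, sd)
  rho <- suppressWarnings(cor(t(rA), t(rB)))
  rho[sdA == 0, ] <- NA_real_
  rho[, sdB == 0] <- NA_real_
  if (n <= exact_limit) {
    # the permutation null of rho depends only on the two rank multisets
    # (tie signatures), so each signature pair's null is computed once and
    # shared by every feature pair carrying it
    perms <- all_permutations(n)
    nperm <- nrow(perms)
    sig <- function(r) paste(sort(r), collapse = ",")
    sigA <- apply(rA, 1, sig)
    sigB <- apply(rB, 1, sig)
    null_cache <- new.env(parent = emptyenv())
    null_for <- function(sa, sb, za, zb) {
      key <- paste(sa, sb, sep = "|")
      hit <- null_cache[[key]]
      if (!is.null(hit)) return(hit)
      nullr <- sort(abs((matrix(zb[perms], nperm) %*% za) / (n - 1)))
      null_cache[[key]] <- nullr
      nullr
    }
    zA <- t(apply(rA, 1, function(r) if (sd(r) == 0) rep(NA, n) else
      as.numeric(scale(r))))
    zB <- t(apply(rB, 1, function(r) if (sd(r) == 0) rep(NA, n) else
      as.numeric(scale(r))))
    p <- matrix(NA_real_, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) {
      if (sdA[i] == 0) next
      ok <- which(sdB != 0)
      for (sb in unique(sigB[ok])) {
        js <- ok[sigB[ok] == sb]
        nullr <- null_for(sigA[i], sb, zA[i, ], zB[js[1], ])
        th <- abs(rho[i, js]) - 1e-9
        p[i, js] <- (nperm - findInterval(th, nullr)) / nperm
      }
    }
  } else {
    p <- spearman_t_p(rho, n)
  }
  dimnames(rho) <- dimnames(p) <- list(rownames(A), rownames(B))
  list(rho = rho, p = p)
}

correlation_set <- function(rho, p, layer, method, symmetric) {
  if (symmetric) {
    idx <- which(upper.tri(rho), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(seq_len(nrow(rho)), seq_len(ncol(rho))))
  }
  tibble(feature_a = rownames(rho)[idx[, 1]],
         feature_b = colnames(rho)[idx[, 2]],
         layer = layer,
         rho = rho[idx],
         p_value = p[idx],
         method = method)
}

#' Metabolite-metabolite Spearman correlation layer
#'
#' All unordered metabolite pairs, Spearman rho and two-sided p as in
#' [spearman_cor()] (exact for small n, t approximation otherwise).
#'
#' @param metabolites A metabolite [feature_table()] (already restricted to
#'   the samples of interest, e.g. one group).
#' @param exact_limit Largest n for exact enumeration.
#' @return A correlation tibble with `layer = "TT"`.
#' @export
metabolite_spearman <- function(metabolites, exact_limit = 7) {
  vals <- ft_values(metabolites)
  res <- spearman_matrix(vals, vals, exact_limit = exact_limit)
  n <- ncol(vals)
  correlation_set(res$rho, res$p, "TT",
                  if (n <= exact_limit) "spearman exact" else "spearman t",
                  symmetric = TRUE)
}

#' Cross-modal microbe-metabolite correlation layer
#'
#' Ranks are computed within each modality's own table and Spearman
#' correlations taken between the two rank sets — operationally identical
#' to pairwise Spearman of each species against each metabolite, staged
#' per modality. Both tables must cover exactly the same samples.
#'
#' @param microbes Microbe [feature_table()].
#' @param metabolites Metabolite [feature_table()] over the same samples.
#' @param exact_limit Largest n for exact enumeration.
#' @return A correlation tibble with `layer = "MT"` (feature_a = species,
#'   feature_b = metabolite).
#' @export
cross_modal_spearman <- function(microbes, metabolites, exact_limit = 7) {
  sa <- ft_samples(microbes)
  sb <- ft_samples(metabolites)
  if (!setequal(sa, sb)) {
    abort(paste0(
      "sample sets differ; only in microbes: ",
      paste(setdiff(sa, sb), collapse = ", "), "; only in metabolites: ",
      paste(setdiff(sb, sa), collapse = ", ")))
  }
  ma <- ft_values(microbes)
  mb <- ft_values(metabolites)[, colnames(ma), drop = FALSE]
  res <- spearman_matrix(ma, mb, exact_limit = exact_limit)
  n <- ncol(ma)
  correlation_set(res$rho, res$p, "MT",
                  if (n <= exact_limit) "spearman exact" else "spearman t",
                  symmetric = FALSE)
}
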