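#' SparCC compositional microbe-microbe correlation
#'
#' Estimates correlations of the latent (basis) abundances underlying
#' compositional relative-abundance data, avoiding the negative bias that
#' closure induces in naive correlations. The core statistic is the
#' log-ratio variance `t_ij = var(log(x_i / x_j))`; under the sparsity
#' approximation (most pairs uncorrelated) the basis log variances
#' `omega_i^2` solve the linear system
#' `sum_j t_ij = (d - 2) * omega_i^2 + sum_j omega_j^2`, and
#' `rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 * omega_i * omega_j)`,
#' clipped to \[-1, 1\]. Strongly correlated pairs violate the sparsity
#' assumption, so the strongest |rho| pair above `threshold` is iteratively
#' excluded (its equations dropped) and the system re-solved, up to
#' `x_iter` rounds. Zeros are resolved by per-sample Dirichlet resampling
#' of pseudo-counts (`counts + 1`); the reported rho is the median over
#' `n_resample` resamplings. Two-sided p-values come from a seeded
#' permutation null in which every species' samples are shuffled
#' independently.
#'
#' Input columns are always renormalized to fractions first (so scaling a
#' sample's counts leaves the result unchanged) and converted to
#' pseudo-counts on a fixed grid before resampling.
#'
#' @param table A microbe [feature_table()] (fractions) or a non-negative
#'   count/fraction matrix with feature row names; needs >= 4 species and
#'   >= 4 samples.
#' @param n_resample Dirichlet resampling rounds (default 20).
#' @param x_iter Maximum strong-pair exclusion rounds per solve (default 10).
#' @param threshold Exclusion threshold on |rho| (default 0.1).
#' @param n_perm Label permutations for p-values (default 100; 0 skips
#'   p-value computation, leaving `p_value = NA`).
#' @param pseudo_scale Fractions are converted to pseudo-counts as
#'   `round(pseudo_scale * fraction)` (default 1e4).
#' @param seed Integer seed; fully determines resampling and permutations.
#' @return An object of class `sparcc_fit`: list with `correlations`
#'   (tibble: `feature_a`, `feature_b`, `layer = "MM"`, `rho`, `p_value`,
#'   `method`), and `state` (log-ratio variance matrix `t_matrix` of the
#'   first resampling, median basis variances `omega2`, `excluded` pair
#'   tibble, the call parameters, and `seed`).
#' @export
sparcc <- function(table, n_resample = 20, x_iter = 10, threshold = 0.1,
                   n_perm = 100, pseudo_scale = 1e4, seed = 1L) {
  vals <- if (inherits(table, "feature_table")) ft_values(table) else table
  d <- nrow(vals)
  n <- ncol(vals)
  if (d < 4) abort("SparCC needs at least 4 species (basis solve)")
  if (n < 4) abort("SparCC needs at least 4 samples")
  if (is.null(rownames(vals))) rownames(vals) <- paste0("f", seq_len(d))
  counts <- to_pseudo_counts(vals, pseudo_scale)

  res <- with_seed(seed, {
    rhos <- array(NA_real_, c(d, d, n_resample))
    omega2s <- matrix(NA_real_, d, n_resample)
    t_first <- NULL
    excluded_first <- NULL
    for (b in seq_len(n_resample)) {
      fr <- dirichlet_fractions(counts)
      tm <- logratio_variance(fr)
      sol <- sparcc_solve(tm, x_iter = x_iter, threshold = threshold)
      rhos[, , b] <- sol$rho
      omega2s[, b] <- sol$omega2
      if (b == 1) {
        t_first <- tm
        excluded_first <- sol$excluded
      }
    }
    rho_med <- apply(rhos, c(1, 2), median, na.rm = TRUE)
    rho_med[apply(rhos, c(1, 2), function(v) all(is.na(v)))] <- NA_real_

    p <- matrix(NA_real_, d, d)
    if (n_perm > 0) {
      exceed <- matrix(0L, d, d)
      valid <- matrix(0L, d, d)
      for (b in seq_len(n_perm)) {
        perm <- t(apply(counts, 1, sample))
        fr <- dirichlet_fractions(perm)
        sol <- sparcc_solve(logratio_variance(fr), x_iter = x_iter,
                            threshold = threshold)
        ok <- !is.na(sol$rho) & !is.na(rho_med)
        exceed[ok] <- exceed[ok] +
          (abs(sol$rho[ok]) >= abs(rho_med[ok]) - 1e-12)
        valid <- valid + ok
      }
      p <- ifelse(valid > 0, (exceed + 1) / (valid + 1), NA_real_)
      p[is.na(rho_med)] <- NA_real_
    }
    list(rho = rho_med, p = p, t_first = t_first,
         excluded = excluded_first,
         omega2 = apply(omega2s, 1, median, na.rm = TRUE))
  })

  dimnames(res$rho) <- dimnames(res$p) <- list(rownames(vals), rownames(vals))
  corr <- correlation_set(res$rho, res$p, "MM", "sparcc", symmetric = TRUE)
  structure(list(
    correlations = corr,
    state = list(t_matrix = res$t_first,
                 omega2 = setNames(res$omega2, rownames(vals)),
                 excluded = res$excluded,
                 n_resample = n_resample, x_iter = x_iter,
                 threshold = threshold, n_perm = n_perm,
                 pseudo_scale = pseudo_scale, seed = seed,
                 n_samples = n, n_species = d)),
    class = "sparcc_fit")
}

# normalize columns to fractions, then put them on a fixed pseudo-count grid
to_pseudo_counts <- function(vals, pseudo_scale) {
  cs <- colSums(vals)
  if (any(cs == 0)) abort("sample(s) with zero total abundance")
  fr <- sweep(vals, 2, cs, "/")
  round(fr * pseudo_scale)
}

# one Dirichlet(counts + 1) draw per sample, via normalized gamma variates
dirichlet_fractions <- function(counts) {
  g <- matrix(rgamma(length(counts), shape = counts + 1, rate = 1),
              nrow(counts), ncol(counts))
  sweep(g, 2, colSums(g), "/")
}

# t_ij = var(log(x_i/x_j)) for all pairs, from the covariance of log rows
logratio_variance <- function(fr) {
  lf <- log(fr)
  v <- stats::cov(t(lf))
  dv <- diag(v)
  outer(dv, dv, "+") - 2 * v
}

# solve basis variances under the sparsity approximation, iteratively
# excluding the strongest correlated pair above `threshold`
sparcc_solve <- function(tm, x_iter, threshold) {
  d <- nrow(tm)
  include <- matrix(TRUE, d, d)
  diag(include) <- FALSE
  excluded <- NULL
  rho <- basis_rho(tm, include)
  for (it in seq_len(x_iter)) {
    cand <- abs(rho$rho)
    cand[!include | !upper.tri(cand)] <- NA
    if (all(is.na(cand))) break
    m <- which.max(cand)
    if (is.na(cand[m]) || cand[m] <= threshold) break
    ij <- arrayInd(m, dim(cand))
    # never let a species drop below 2 included partners
    if (sum(include[ij[1], ]) <= 2 || sum(include[ij[2], ]) <= 2) break
    include[ij[1], ij[2]] <- include[ij[2], ij[1]] <- FALSE
    excluded <- rbind(excluded, ij)
    rho <- basis_rho(tm, include)
  }
  list(rho = rho$rho, omega2 = rho$omega2,
       excluded = if (is.null(excluded)) {
         tibble(i = integer(), j = integer())
       } else {
         tibble(i = excluded[, 1], j = excluded[, 2])
       })
}

basis_rho <- function(tm, include) {
  d <- nrow(tm)
  M <- matrix(0, d, d)
  M[include] <- 1
  diag(M) <- rowSums(include)
  t_i <- rowSums(tm * include)
  omega2 <- tryCatch(solve(M, t_i), error = function(e) rep(NA_real_, d))
  omega2[!is.na(omega2) & omega2 <= 0] <- NA_real_
  om <- sqrt(omega2)
  rho <- (outer(omega2, omega2, "+") - tm) / (2 * outer(om, om))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  list(rho = rho, omega2 = omega2)
}

#' @export
print.sparcc_fit <- function(x, ...) {
  st <- x$state
  cat(sprintf(
    "<sparcc_fit: %d species, %d samples, %d resamplings, %d permutations>\n",
    st$n_species, st$n_samples, st$n_resample, st$n_perm))
  invisible(x)
}

#' @export
#' @method tidy sparcc_fit
tidy.sparcc_fit <- function(x, ...) x$correlations

#' @export
#' @method glance sparcc_fit
glance.sparcc_fit <- function(x, ...) {
  ok <- !is.na(x$correlations$rho)
  tibble(n_species = x$state$n_species,
         n_samples = x$state$n_samples,
         n_pairs = nrow(x$correlations),
         n_undefined = sum(!ok),
         mean_abs_rho = mean(abs(x$correlations$rho[ok])),
         max_abs_rho = max(abs(x$correlations$rho[ok])))
}

#' Naive Pearson correlation on fractions
#'
#' Reference method for the compositional-bias comparison: plain Pearson
#' correlation computed directly on closed fractions, which is biased
#' negative by closure. Useful only as a contrast to [sparcc()].
#'
#' @param table Microbe [feature_table()] or matrix.
#' @return A correlation tibble with `method = "pearson on fractions"`.
#' @export
naive_fraction_pearson <- function(table) {
  vals <- if (inherits(table, "feature_table")) ft_values(table) else table
  fr <- sweep(vals, 2, colSums(vals), "/")
  rho <- cor(t(fr))
  p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  correlation_set(rho, p, "MM", "pearson on fractions", symmetric = TRUE)
}
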