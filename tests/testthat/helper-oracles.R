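# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Mann-Whitney: U and two-sided p by direct enumeration over index subsets
oracle_mann_whitney <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  us <- apply(utils::combn(n, nx), 2, u_of)
  p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  list(u = u_obs, p = p)
}

# Spearman: exact two-sided p via e1071's permutation enumeration
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  perms <- e1071::permutations(length(y))
  null_rho <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
  list(rho = rho, p = mean(abs(null_rho) >= abs(rho) - 1e-9))
}

# ATria pay: nested-loop brute force over direct edges and 2-paths
oracle_pay <- function(ids, edges) {
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(edges))) {
    W[edges$from[k], edges$to[k]] <- edges$weight[k]
    W[edges$to[k], edges$from[k]] <- edges$weight[k]
  }
  pays <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    total <- 1
    for (j in seq_along(ids)) {
      if (j == i) next
      cands <- c()
      if (W[i, j] != 0) cands <- c(cands, W[i, j])
      for (k in seq_along(ids)) {
        if (k != i && k != j && W[i, k] != 0 && W[k, j] != 0) {
          cands <- c(cands, W[i, k] * W[k, j])
        }
      }
      if (length(cands)) total <- total + cands[which.max(abs(cands))]
    }
    pays[i] <- abs(total)
  }
  pays
}

# convenience: a small paired dataset with no planted structure
null_dataset <- function(seed, n_per_group = 6, n_species = 12,
                         n_metabolites = 15, sparsity = 0.2) {
  synthesize_dataset(synth_config(
    n_per_group = n_per_group, n_species = n_species,
    n_metabolites = n_metabolites, sparsity = sparsity, seed = seed))
}

# convenience: star-network edge tibble
star_edges <- function(weight, n_leaves = 4) {
  tibble::tibble(from = "hub", to = paste0("leaf", seq_len(n_leaves)),
                 weight = weight)
}
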