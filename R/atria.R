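#' Triad-ablation (ATria) centrality ranking
#'
#' Ranks the nodes of a signed, weighted network by iterative extraction
#' of the most "paying" node. The pay of node i is
#' `|sum_j P_ij|` with `P_ii = 1` (self-pay) and, for `j != i`, `P_ij` the
#' signed value of largest magnitude among the direct edge `w_ij` and all
#' two-step products `w_ik * w_kj` (absent terms contribute 0) — so a node
#' is paid by everything it can reach within a triad, and strong negative
#' influence counts as much as positive ("driver, villain and bridge"
#' nodes). Each round the node of maximal pay is extracted (ties broken by
#' lexicographically smallest id), then ablated: the node, its incident
#' edges, and every edge closing a triangle with it are deleted, so later
#' ranks are not paid twice for the same triads. Extraction stops when
#' every remaining node's pay equals its self-pay of 1; those nodes form
#' the unranked residual.
#'
#' @param network A `hetero_network`, or a tibble of edges with columns
#'   `from`, `to`, `weight`.
#' @param path_cap Longest path contributing to pay (1 = direct edges
#'   only, 2 = triads; default 2).
#' @param ablate_triangles Also delete triangle-closing edges between the
#'   extracted node's neighbours (default `TRUE`).
#' @param tol Tolerance for "pay equals self-pay".
#' @return An object of class `atria_ranking`: tibble with columns
#'   `rank`, `node`, `pay` (at extraction), `round`, plus a `residual`
#'   attribute listing unranked nodes (lexicographic order).
#' @export
atria_rank <- function(network, path_cap = 2, ablate_triangles = TRUE,
                       tol = 1e-9) {
  edges <- if (inherits(network, "hetero_network")) network$edges else
    as_tibble(network)
  nodes <- if (inherits(network, "hetero_network")) network$nodes$node else
    sort(unique(c(edges$from, edges$to)))
  stopifnot(path_cap %in% c(1, 2))
  if (nrow(edges) && any(abs(edges$weight) > 1 + 1e-12)) {
    abort("edge weights must lie in [-1, 1]")
  }
  d <- length(nodes)
  W <- matrix(0, d, d, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    W[edges$from[k], edges$to[k]] <- edges$weight[k]
    W[edges$to[k], edges$from[k]] <- edges$weight[k]
  }
  alive <- nodes
  out <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    Wa <- W[alive, alive, drop = FALSE]
    pays <- atria_pays(Wa, path_cap)
    active <- abs(pays - 1) > tol
    if (!length(pays) || !any(active)) break
    cand <- pays
    cand[!active] <- -Inf
    best <- alive[order(-cand, alive)][1]
    out[[length(out) + 1]] <- tibble(node = best, pay = unname(pays[best]),
                                     round = round)
    nb <- alive[alive != best & W[best, alive] != 0]
    if (ablate_triangles && length(nb) > 1) {
      W[nb, nb] <- 0
    }
    W[best, ] <- 0
    W[, best] <- 0
    alive <- setdiff(alive, best)
  }
  ranked <- if (length(out)) bind_rows(out) else
    tibble(node = character(), pay = numeric(), round = integer())
  ranked <- mutate(ranked, rank = dplyr::row_number()) |>
    select("rank", "node", "pay", "round")
  structure(ranked, class = c("atria_ranking", class(tibble())),
            residual = sort(alive))
}

# pay of every node of the weight matrix under the <=path_cap rule
atria_pays <- function(W, path_cap = 2) {
  d <- nrow(W)
  if (d == 0) return(setNames(numeric(0), character(0)))
  M <- W
  if (path_cap >= 2 && d > 2) {
    for (k in seq_len(d)) {
      cand <- outer(W[, k], W[k, ])
      upd <- abs(cand) > abs(M)
      M[upd] <- cand[upd]
    }
    diag(M) <- 0
  }
  setNames(abs(1 + rowSums(M)), rownames(W))
}

#' Unranked residual nodes of a ranking
#' @param ranking An `atria_ranking`.
#' @export
atria_residual <- function(ranking) attr(ranking, "residual")

#' @export
#' @method tidy atria_ranking
tidy.atria_ranking <- function(x, ...) as_tibble(as.data.frame(x))

#' @export
print.atria_ranking <- function(x, ...) {
  cat(sprintf("<atria_ranking: %d ranked, %d residual>\n",
              nrow(x), length(attr(x, "residual"))))
  NextMethod()
}
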