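triangle_edges <- tibble::tibble(from = c("A", "A", "B"),
                                 to = c("B", "C", "C"),
                                 weight = c(0.9, 0.8, 0.1))

test_that("pays match the brute-force calculator on the triangle", {
  pays <- micromet:::atria_pays(matrix(
    c(0, 0.9, 0.8, 0.9, 0, 0.1, 0.8, 0.1, 0),
    3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  ref <- oracle_pay(c("A", "B", "C"), triangle_edges)
  expect_equal(pays, ref)
  # hand values: B is paid 0.72 for C through A, beating the direct 0.1
  expect_equal(unname(pays), c(2.7, 2.62, 2.52))
})

test_that("pays match brute force on random signed graphs", {
  set.seed(31)
  for (rep in 1:15) {
    d <- sample(3:7, 1)
    ids <- paste0("n", seq_len(d))
    pairs <- utils::combn(ids, 2)
    keep <- runif(ncol(pairs)) < 0.6
    edges <- tibble::tibble(from = pairs[1, keep], to = pairs[2, keep],
                            weight = runif(sum(keep), -1, 1))
    if (nrow(edges) == 0) next
    W <- matrix(0, d, d, dimnames = list(ids, ids))
    for (k in seq_len(nrow(edges))) {
      W[edges$from[k], edges$to[k]] <- edges$weight[k]
      W[edges$to[k], edges$from[k]] <- edges$weight[k]
    }
    expect_equal(micromet:::atria_pays(W), oracle_pay(ids, edges))
  }
})

test_that("the triangle is ranked and ablated as derived by hand", {
  rk <- atria_rank(triangle_edges)
  expect_identical(rk$node, "A")
  expect_equal(rk$pay, 2.7)
  expect_identical(rk$rank, 1L)
  # ablating A removes the triangle edge B-C, leaving B and C at self-pay
  expect_identical(atria_residual(rk), c("B", "C"))
})

test_that("positive stars put the hub first", {
  # saturated +1 weights tie every node's pay at 5 (leaf-leaf two-paths
  # through the hub contribute +1 each); the lexicographic rule then
  # extracts the hub
  rk <- atria_rank(star_edges(1))
  expect_identical(rk$node[1], "hub")
  # at weight 0.9 the hub wins strictly: 1 + 4*0.9 > 1 + 0.9 + 3*0.81
  rk2 <- atria_rank(star_edges(0.9))
  expect_identical(rk2$node[1], "hub")
  expect_equal(rk2$pay[1], 1 + 4 * 0.9)
  pays <- micromet:::atria_pays(matrix(0, 0, 0))
  expect_length(pays, 0)
})

test_that("all-negative stars still surface the hub", {
  # saturated -1 weights: hub pay |1 - 4| = 3 ties the leaves
  # (1 - 1 + 3*(+1) = 3); the tie rule favors 'hub' lexicographically,
  # and at -0.9 the hub wins strictly (2.6 vs 2.53) per the oracle
  ref <- oracle_pay(c("hub", paste0("leaf", 1:4)), star_edges(-0.9))
  expect_equal(unname(ref["hub"]), 2.6)
  expect_equal(unname(ref["leaf1"]), 2.53)
  rk <- atria_rank(star_edges(-1))
  expect_identical(rk$node[1], "hub")
  rk2 <- atria_rank(star_edges(-0.9))
  expect_identical(rk2$node[1], "hub")
  expect_equal(rk2$pay[1], abs(1 - 4 * 0.9))
})

test_that("rankings are duplicate-free with increasing extraction rounds", {
  set.seed(32)
  for (rep in 1:10) {
    d <- sample(4:9, 1)
    ids <- paste0("n", seq_len(d))
    pairs <- utils::combn(ids, 2)
    keep <- runif(ncol(pairs)) < 0.5
    edges <- tibble::tibble(from = pairs[1, keep], to = pairs[2, keep],
                            weight = runif(sum(keep), -1, 1))
    rk <- atria_rank(edges)
    expect_false(any(duplicated(rk$node)))
    expect_identical(rk$rank, seq_len(nrow(rk)))
    expect_identical(rk$round, seq_len(nrow(rk)))
    expect_true(all(is.finite(rk$pay)))
    # ranked plus residual partition the node set
    expect_setequal(c(rk$node, atria_residual(rk)),
                    unique(c(edges$from, edges$to)))
  }
})

test_that("relabeled isomorphic networks rank consistently", {
  set.seed(33)
  ids <- paste0("n", 1:6)
  pairs <- utils::combn(ids, 2)
  keep <- runif(ncol(pairs)) < 0.6
  # distinct random weights so the lexicographic tie rule never bites
  edges <- tibble::tibble(from = pairs[1, keep], to = pairs[2, keep],
                          weight = runif(sum(keep), 0.1, 1))
  rk <- atria_rank(edges)
  relabel <- setNames(paste0("x", 6:1), ids)
  edges2 <- tibble::tibble(from = unname(relabel[edges$from]),
                           to = unname(relabel[edges$to]),
                           weight = edges$weight)
  rk2 <- atria_rank(edges2)
  expect_identical(unname(relabel[rk$node]), rk2$node)
  expect_equal(rk$pay, rk2$pay)
})

test_that("an edgeless network ranks nothing", {
  net <- structure(list(
    nodes = tibble::tibble(node = c("a", "b"),
                           node_type = c("microbe", "metabolite"),
                           annotation = c("x", "y"),
                           mean_abundance = c(1, 2)),
    edges = tibble::tibble(from = character(), to = character(),
                           weight = numeric(), p_value = numeric(),
                           layer = character(), kegg_supported = logical()),
    group = "Chow"), class = "hetero_network")
  rk <- atria_rank(net)
  expect_identical(nrow(rk), 0L)
  expect_identical(atria_residual(rk), c("a", "b"))
})

test_that("path cap 1 scores direct edges only", {
  rk <- atria_rank(triangle_edges, path_cap = 1)
  # A: |1 + 0.9 + 0.8| = 2.7; B: |1 + 0.9 + 0.1| = 2.0; C: |1 + 0.8 + 0.1|
  expect_equal(rk$pay[1], 2.7)
  W <- matrix(c(0, 0.9, 0.8, 0.9, 0, 0.1, 0.8, 0.1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unname(micromet:::atria_pays(W, path_cap = 1)),
               c(2.7, 2.0, 1.9))
})
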