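corr_row <- function(a, b, layer, rho, p) {
  tibble::tibble(feature_a = a, feature_b = b, layer = layer, rho = rho,
                 p_value = p, method = "test")
}

test_that("admitted edges build a typed two-mode network", {
  ds <- null_dataset(seed = 21, n_per_group = 3, n_species = 5,
                     n_metabolites = 5)
  mt <- corr_row("sp001", "met001", "MT", 0.9, 0.01)
  net <- build_heteronet(mt = mt, microbes = ds$microbes,
                         metabolites = ds$metabolites, design = ds$design,
                         group = "Chow")
  expect_identical(nrow(net$nodes), 2L)
  expect_identical(nrow(net$edges), 1L)
  expect_gt(net$edges$weight, 0)
  expect_setequal(net$nodes$node_type, c("microbe", "metabolite"))
  expect_identical(net$nodes$annotation[net$nodes$node == "sp001"],
                   "Firmicutes")
  # node attributes are group means
  gs <- group_samples(ds$design, "Chow")
  expect_equal(net$nodes$mean_abundance[net$nodes$node == "sp001"],
               mean(ft_values(ds$microbes)["sp001", gs]))
})

test_that("edges above the admission threshold yield an empty network", {
  ds <- null_dataset(seed = 22, n_per_group = 3, n_species = 4,
                     n_metabolites = 4)
  mt <- corr_row("sp001", "met001", "MT", 0.9, 0.2)
  expect_warning(
    net <- build_heteronet(mt = mt, microbes = ds$microbes,
                           metabolites = ds$metabolites, design = ds$design,
                           group = "WD"),
    "empty network")
  expect_identical(nrow(net$nodes), 0L)
  expect_identical(nrow(net$edges), 0L)
})

test_that("undefined correlations and self-pairs are never admitted", {
  ds <- null_dataset(seed = 23, n_per_group = 3, n_species = 4,
                     n_metabolites = 4)
  mm <- dplyr::bind_rows(
    corr_row("sp001", "sp002", "MM", NA_real_, 0.01),
    corr_row("sp003", "sp003", "MM", 0.9, 0.001),
    corr_row("sp001", "sp003", "MM", -0.8, 0.04))
  net <- build_heteronet(mm = mm, microbes = ds$microbes,
                         metabolites = ds$metabolites, design = ds$design,
                         group = "Chow")
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$from, "sp001")
  expect_identical(net$edges$to, "sp003")
  expect_lt(net$edges$weight, 0)
})

test_that("BH admission is stricter than the raw threshold", {
  ds <- null_dataset(seed = 24, n_per_group = 3, n_species = 6,
                     n_metabolites = 6)
  set.seed(1)
  pairs <- utils::combn(sprintf("met%03d", 1:6), 2)
  tt <- corr_row(pairs[1, ], pairs[2, ], "TT", runif(ncol(pairs), -1, 1),
                 runif(ncol(pairs), 0.001, 0.3))
  raw <- build_heteronet(tt = tt, microbes = ds$microbes,
                         metabolites = ds$metabolites, design = ds$design,
                         group = "Chow")
  bh <- suppressWarnings(
    build_heteronet(tt = tt, microbes = ds$microbes,
                    metabolites = ds$metabolites, design = ds$design,
                    group = "Chow", p_adjust = "BH"))
  expect_lte(nrow(bh$edges), nrow(raw$edges))
})

test_that("KEGG support flags positive shared-pathway edges only", {
  ds <- null_dataset(seed = 25, n_per_group = 3, n_species = 5,
                     n_metabolites = 5)
  mt <- dplyr::bind_rows(
    corr_row("sp001", "met001", "MT", 0.8, 0.01),
    corr_row("sp001", "met002", "MT", -0.8, 0.01),
    corr_row("sp002", "met001", "MT", 0.7, 0.01))
  net <- build_heteronet(mt = mt, microbes = ds$microbes,
                         metabolites = ds$metabolites, design = ds$design,
                         group = "Chow")
  mapping <- tibble::tibble(
    feature = c("sp001", "met001", "met002", "sp002"),
    pathway = c("map00240", "map00240", "map00240", "map00999"))
  net <- kegg_support(net, mapping)
  ed <- net$edges
  # positive + shared pathway -> supported
  expect_true(ed$kegg_supported[ed$from == "sp001" & ed$to == "met001"])
  # negative correlation is never supported even with a shared pathway
  expect_false(ed$kegg_supported[ed$from == "sp001" & ed$to == "met002"])
  # disjoint pathway sets -> unsupported
  expect_false(ed$kegg_supported[ed$from == "sp002" & ed$to == "met001"])
})

test_that("network-specific metabolites are exclusive by construction", {
  ds <- null_dataset(seed = 26, n_per_group = 3, n_species = 5,
                     n_metabolites = 6)
  mk <- function(group, links) {
    mt <- dplyr::bind_rows(lapply(links, function(l)
      corr_row(l[[1]], l[[2]], "MT", 0.9, 0.01)))
    build_heteronet(mt = mt, microbes = ds$microbes,
                    metabolites = ds$metabolites, design = ds$design,
                    group = group)
  }
  nets <- list(
    Chow = mk("Chow", list(c("sp001", "met001"), c("sp001", "met003"))),
    WD = mk("WD", list(c("sp002", "met002"), c("sp002", "met003"))))
  sp <- network_specific_metabolites(nets, ds$metabolites, ds$design)
  expect_setequal(sp$feature[sp$group == "Chow"], "met001")
  expect_setequal(sp$feature[sp$group == "WD"], "met002")
  # met003 appears in both networks, so in no specific set
  expect_false("met003" %in% sp$feature)
  expect_false(any(duplicated(sp$feature)))
  expect_true(all(paste0("mean_", design_groups(ds$design)) %in% names(sp)))
  expect_error(network_specific_metabolites(nets["Chow"]), "at least 2")
})

test_that("layout is deterministic and pulls positive pairs together", {
  ds <- null_dataset(seed = 27, n_per_group = 3, n_species = 6,
                     n_metabolites = 6)
  mt <- dplyr::bind_rows(
    corr_row("sp001", "met001", "MT", 0.95, 0.01),
    corr_row("sp002", "met002", "MT", 0.9, 0.01))
  # sp003/met003 participate via a shared edge pair so they are nodes but
  # unconnected to each other
  mt <- dplyr::bind_rows(mt, corr_row("sp003", "met004", "MT", 0.9, 0.01),
                         corr_row("sp004", "met003", "MT", 0.85, 0.01))
  net <- build_heteronet(mt = mt, microbes = ds$microbes,
                         metabolites = ds$metabolites, design = ds$design,
                         group = "Chow")
  a <- layout_heteronet(net, seed = 5)
  b <- layout_heteronet(net, seed = 5)
  expect_identical(a, b)
  dist_of <- function(coords, u, v) {
    du <- coords[coords$node == u, c("x", "y")]
    dv <- coords[coords$node == v, c("x", "y")]
    sqrt(sum((du - dv)^2))
  }
  # connected positive pair ends closer than an unconnected pair
  expect_lt(dist_of(a, "sp001", "met001"), dist_of(a, "sp003", "met003"))
})

test_that("a single-node layout sits at the origin", {
  ds <- null_dataset(seed = 28, n_per_group = 3, n_species = 4,
                     n_metabolites = 4)
  net <- structure(list(
    nodes = tibble::tibble(node = "sp001", node_type = "microbe",
                           annotation = "Firmicutes", mean_abundance = 0.5),
    edges = tibble::tibble(from = character(), to = character(),
                           weight = numeric(), p_value = numeric(),
                           layer = character(), kegg_supported = logical()),
    group = "Chow"), class = "hetero_network")
  coords <- layout_heteronet(net, seed = 1)
  expect_equal(coords$x, 0)
  expect_equal(coords$y, 0)
})

test_that("planted cross-links surface as correctly signed MT edges", {
  hits <- 0
  n_seeds <- 25
  for (seed in seq_len(n_seeds)) {
    # plant on reliably detected (abundant) species: links to taxa below
    # the detection limit are not recoverable by any method
    # default community size: in very small communities the closure
    # total's variance attenuates any link to a minor taxon. Links are
    # planted on abundant-but-not-dominant taxa (reliably detected, not
    # themselves driving the closure total).
    base <- synth_config(n_groups = 1, n_per_group = 20,
                         n_metabolites = 10, group_names = "Chow",
                         seed = seed)
    ord <- names(sort(rowMeans(generate_microbiome(base)$truth$basis),
                      decreasing = TRUE))
    links <- tibble::tibble(species = ord[5:7],
                            metabolite = c("met001", "met002", "met003"),
                            rho = 0.9)
    cfg <- synth_config(n_groups = 1, n_per_group = 20,
                        n_metabolites = 10, cross_links = links,
                        group_names = "Chow", seed = seed)
    ds <- synthesize_dataset(cfg)
    cm <- cross_modal_spearman(ds$microbes, ds$metabolites)
    net <- build_heteronet(mt = cm, microbes = ds$microbes,
                           metabolites = ds$metabolites, design = ds$design,
                           group = "Chow")
    ok <- vapply(seq_len(nrow(links)), function(i) {
      ed <- net$edges
      row <- ed[ed$from == links$species[i] & ed$to == links$metabolite[i], ]
      nrow(row) == 1 && row$weight > 0
    }, logical(1))
    hits <- hits + all(ok)
  }
  expect_gte(hits / n_seeds, 0.9)
})
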