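test_that("generation is fully determined by the seed", {
  cfg <- synth_config(n_species = 15, n_metabolites = 20, seed = 42)
  a <- synthesize_dataset(cfg)
  b <- synthesize_dataset(cfg)
  expect_identical(ft_values(a$microbes), ft_values(b$microbes))
  expect_identical(ft_values(a$metabolites), ft_values(b$metabolites))
  expect_identical(a$truth$basis, b$truth$basis)
  c <- synthesize_dataset(synth_config(n_species = 15, n_metabolites = 20,
                                       seed = 43))
  expect_false(identical(ft_values(a$microbes), ft_values(c$microbes)))
})

test_that("microbiome samples are closed to unit sum", {
  for (seed in c(1, 2, 3)) {
    ds <- generate_microbiome(synth_config(sparsity = 0.5, seed = seed))
    expect_true(all(abs(colSums(ft_values(ds$table)) - 1) < 1e-9))
  }
})

test_that("noise-free, effect-free generation reproduces the basis mean", {
  cfg <- synth_config(n_species = 10, sparsity = 0, noise_sd = 0, seed = 5)
  ds <- generate_microbiome(cfg)
  vals <- ft_values(ds$table)
  expect_true(all(apply(vals, 1, function(r) diff(range(r)) < 1e-12)))
  closed_basis <- ds$truth$basis[, 1] / sum(ds$truth$basis[, 1])
  expect_equal(unname(vals[, 1]), unname(closed_basis))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_per_group = 2), "n_per_group")
  expect_error(synth_config(sparsity = 0.9), "sparsity")
  expect_error(synth_config(cross_links = tibble::tibble(
    species = "sp001", metabolite = "nope", rho = 0.5)), "unknown feature")
  expect_error(synth_config(n_species = 5, cross_links = tibble::tibble(
    species = "sp001", metabolite = "met001", rho = 1.5)), "\\[-1, 1\\]")
  expect_error(synth_config(group_effects = tibble::tibble(
    feature = "sp001", group = "NoSuch", log2fc = 1)), "unknown group")
})

test_that("extreme sparsity that empties a sample is an error", {
  cfg <- synth_config(n_species = 4, n_metabolites = 5, sparsity = 0.8,
                      seed = 2)
  expect_error(generate_microbiome(cfg), "all-zero")
})

test_that("a planted species effect raises its group mean abundance", {
  eff <- tibble::tibble(feature = "sp003", group = "WD", log2fc = 2)
  hits <- 0
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    ds <- generate_microbiome(synth_config(
      n_species = 20, n_metabolites = 5, group_effects = eff, seed = seed))
    vals <- ft_values(ds$table)
    wd <- group_samples(ds$design, "WD")
    chow <- group_samples(ds$design, "Chow")
    hits <- hits + (mean(vals["sp003", wd]) > mean(vals["sp003", chow]))
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("cross-link rho = 1 with vanishing noise gives Spearman 1", {
  cl <- tibble::tibble(species = "sp001", metabolite = "met001", rho = 1)
  cfg <- synth_config(n_species = 8, n_metabolites = 8, sparsity = 0,
                      cross_links = cl, noise_sd = 1, seed = 3)
  ds <- synthesize_dataset(cfg)
  s <- ds$truth$log_basis["sp001", ]
  m <- log(ft_values(ds$metabolites)["met001", ])
  expect_equal(unname(cor(rank(s), rank(m))), 1)
})

test_that("a zero cross-link leaves species and metabolite uncorrelated", {
  cl <- tibble::tibble(species = "sp001", metabolite = "met001", rho = 0)
  rhos <- vapply(seq_len(100), function(seed) {
    ds <- synthesize_dataset(synth_config(
      n_species = 8, n_metabolites = 8, sparsity = 0, cross_links = cl,
      seed = seed))
    cor(rank(ft_values(ds$microbes)["sp001", ]),
        rank(ft_values(ds$metabolites)["met001", ]))
  }, numeric(1))
  # no systematic association: the across-seed mean rho stays near zero
  # (the mean of |rho| cannot fall below its null expectation ~0.8/sqrt(23))
  expect_lt(abs(mean(rhos)), 0.15)
  expect_lt(mean(abs(rhos)), 3 * 0.7979 / sqrt(23))
})

test_that("a planted metabolite fold change is recovered on average", {
  eff <- tibble::tibble(feature = "met002", group = "WD+GWI", log2fc = 1)
  errs <- vapply(seq_len(50), function(seed) {
    cfg <- synth_config(n_per_group = 20, n_species = 6, n_metabolites = 8,
                        sparsity = 0, group_effects = eff, seed = seed)
    met <- generate_metabolome(cfg)
    design <- micromet:::synth_design(cfg)
    lv <- log2(ft_values(met)["met002", ])
    mean(lv[group_samples(design, "WD+GWI")]) -
      mean(lv[group_samples(design, "Chow")])
  }, numeric(1))
  expect_lt(abs(mean(errs) - 1), 0.3)
})

test_that("cross-links against a zero-variance species are an error", {
  cl <- tibble::tibble(species = "sp001", metabolite = "met001", rho = 0.5)
  cfg <- synth_config(n_species = 6, n_metabolites = 6, sparsity = 0,
                      noise_sd = 0, cross_links = cl, seed = 1)
  mb <- generate_microbiome(cfg)
  expect_error(generate_metabolome(cfg, mb$truth), "zero-variance")
})

test_that("ground truth survives a JSON round trip", {
  cfg <- synth_config(
    n_species = 6, n_metabolites = 6,
    group_effects = tibble::tibble(feature = "sp002", group = "WD",
                                   log2fc = 1.5),
    cross_links = tibble::tibble(species = "sp001", metabolite = "met001",
                                 rho = 0.8),
    species_links = tibble::tibble(species_a = "sp003", species_b = "sp004",
                                   rho = 0.6),
    seed = 9)
  truth <- generate_microbiome(cfg)$truth
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_identical(back$basis, truth$basis)
  expect_identical(back$log_basis, truth$log_basis)
  expect_equal(as.data.frame(back$effects), as.data.frame(truth$effects))
  expect_equal(as.data.frame(back$cross_links),
               as.data.frame(truth$cross_links))
  expect_equal(as.data.frame(back$species_links),
               as.data.frame(truth$species_links))
})

test_that("the planted differential regime is detectable by rank test", {
  # |log2 effect| >= 2 at n = 6/group should be flagged at p < 0.05 in a
  # large majority of runs
  eff <- tibble::tibble(feature = "met001", group = "WD", log2fc = 2)
  hits <- 0
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    cfg <- synth_config(n_species = 4, n_metabolites = 6, sparsity = 0,
                        group_effects = eff, seed = seed)
    met <- generate_metabolome(cfg)
    design <- micromet:::synth_design(cfg)
    v <- ft_values(met)["met001", ]
    p <- mann_whitney_exact(v[group_samples(design, "WD")],
                            v[group_samples(design, "Chow")])$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_seeds, 0.8)
})
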