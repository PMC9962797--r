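#' Configure the synthetic paired microbiome-metabolome generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a four-arm design (chow or Western diet, with or without Gulf
#' War chemical exposure), sparse compositional species abundances obtained
#' by closing a log-normal basis, log-normal ion-count-like metabolite
#' intensities, planted group fold-changes, planted cross-modal
#' species-metabolite correlations, and (for testing the compositional
#' correlation stage) planted species-species basis correlations.
#'
#' @param n_groups Number of experimental groups (default 4).
#' @param n_per_group Samples per group (default 6; must be >= 3).
#' @param n_species Number of microbial species (default 40).
#' @param n_metabolites Number of metabolites (default 120).
#' @param sparsity Target overall fraction of structural zeros planted in
#'   the species basis before closure, in \[0, 0.8\]. Zeros emulate a
#'   detection limit: each cell is Bernoulli-masked with a probability
#'   that rises steeply (logistic in log abundance) once its basis value
#'   falls below the table-wide `sparsity` quantile, so rare taxa are
#'   mostly zero while dominant taxa are observed in every sample.
#' @param group_effects Tibble with columns `feature`, `group`, `log2fc`:
#'   multiplicative group effects applied on the log scale before closure
#'   (species) or on log intensity (metabolites).
#' @param cross_links Tibble with columns `species`, `metabolite`, `rho`
#'   and optional `group`: each row plants a cross-modal correlation by
#'   building the metabolite's log intensity as
#'   `rho * z_s + sqrt(1 - rho^2) * eps`, with `z_s` the standardized log
#'   basis abundance of the species. When `group` is given the construction
#'   is applied within that group's samples only.
#' @param species_links Tibble with columns `species_a`, `species_b`,
#'   `rho`: plants a basis correlation between two species the same way.
#' @param noise_sd Log-scale noise standard deviation. The default 0.5
#'   keeps a planted two-fold effect at roughly 2.8 residual standard
#'   deviations, detectable by the exact rank test at n = 6 per group.
#' @param baseline_sd Spread of per-feature baseline log means; larger
#'   values give more uneven (more realistic) abundance distributions.
#' @param metab_log_mean Baseline mean of metabolite log intensities
#'   (ion-count scale; default `log(1e6)`).
#' @param group_names Group labels, recycled to `n_groups`.
#' @param seed Integer seed; fully determines the generated tables.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_groups = 4, n_per_group = 6, n_species = 40,
                         n_metabolites = 120, sparsity = 0.3,
                         group_effects = NULL, cross_links = NULL,
                         species_links = NULL,
                         noise_sd = 0.5, baseline_sd = 2,
                         metab_log_mean = log(1e6),
                         group_names = c("Chow", "Chow+GWI", "WD", "WD+GWI"),
                         seed = 1L) {
  stopifnot(is_count(n_groups), is_count(n_species), is_count(n_metabolites))
  if (!is_count(n_per_group) || n_per_group < 3) {
    abort("n_per_group must be an integer >= 3")
  }
  if (!is.numeric(sparsity) || sparsity < 0 || sparsity > 0.8) {
    abort("sparsity must lie in [0, 0.8]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  if (length(group_names) < n_groups) {
    group_names <- paste0("G", seq_len(n_groups))
  }
  group_names <- group_names[seq_len(n_groups)]
  cfg <- list(
    n_groups = n_groups, n_per_group = n_per_group,
    n_species = n_species, n_metabolites = n_metabolites,
    sparsity = sparsity,
    group_effects = normalize_effects(group_effects),
    cross_links = normalize_links(cross_links),
    species_links = normalize_species_links(species_links),
    noise_sd = noise_sd, baseline_sd = baseline_sd,
    metab_log_mean = metab_log_mean,
    group_names = group_names, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

normalize_effects <- function(x) {
  if (is.null(x)) return(tibble(feature = character(), group = character(),
                                log2fc = numeric()))
  x <- as_tibble(x)
  stopifnot(all(c("feature", "group", "log2fc") %in% names(x)))
  x
}

normalize_links <- function(x) {
  if (is.null(x)) {
    return(tibble(species = character(), metabolite = character(),
                  rho = numeric(), group = character()))
  }
  x <- as_tibble(x)
  stopifnot(all(c("species", "metabolite", "rho") %in% names(x)))
  if (!"group" %in% names(x)) x$group <- NA_character_
  x
}

normalize_species_links <- function(x) {
  if (is.null(x)) {
    return(tibble(species_a = character(), species_b = character(),
                  rho = numeric()))
  }
  x <- as_tibble(x)
  stopifnot(all(c("species_a", "species_b", "rho") %in% names(x)))
  x
}

species_ids <- function(n) sprintf("sp%03d", seq_len(n))
metabolite_ids <- function(n) sprintf("met%03d", seq_len(n))

# fixed synthetic taxonomy: four phyla assigned round-robin, mirroring the
# phyla typically dominating the murine gut
synthetic_phyla <- function(n) {
  rep(c("Firmicutes", "Actinobacteria", "Proteobacteria", "Bacteroidetes"),
      length.out = n)
}

synthetic_pathways <- function(n) {
  rep(sprintf("map%05d", c(240, 250, 61, 30, 520, 10)), length.out = n)
}

validate_synth_config <- function(cfg) {
  sp <- species_ids(cfg$n_species)
  mt <- metabolite_ids(cfg$n_metabolites)
  known <- c(sp, mt)
  bad <- setdiff(cfg$group_effects$feature, known)
  if (length(bad)) {
    abort(paste0("group_effects refer to unknown feature(s): ",
                 paste(bad, collapse = ", ")))
  }
  badg <- setdiff(stats::na.omit(c(cfg$group_effects$group,
                                   cfg$cross_links$group)),
                  cfg$group_names)
  if (length(badg)) {
    abort(paste0("unknown group(s) in planted effects: ",
                 paste(badg, collapse = ", ")))
  }
  if (length(setdiff(cfg$cross_links$species, sp)) ||
      length(setdiff(cfg$cross_links$metabolite, mt)) ||
      length(setdiff(c(cfg$species_links$species_a,
                       cfg$species_links$species_b), sp))) {
    abort("planted link refers to an unknown feature id")
  }
  if (any(abs(cfg$cross_links$rho) > 1) ||
      any(abs(cfg$species_links$rho) > 1)) {
    abort("planted correlations must lie in [-1, 1]")
  }
  invisible(cfg)
}

#' Sample-to-group design implied by a synthetic configuration
#'
#' @param cfg A [synth_config()].
#' @return A [group_design()] with `n_groups * n_per_group` samples.
#' @export
synth_design <- function(cfg) {
  samples <- sprintf("s%02d", seq_len(cfg$n_groups * cfg$n_per_group))
  group_design(tibble(sample = samples,
                      group = rep(cfg$group_names, each = cfg$n_per_group)),
               levels = cfg$group_names)
}

#' Generate a synthetic microbiome table
#'
#' Species basis abundances are drawn log-normally (per-species baseline
#' means, shared log-scale noise), multiplied by any planted group effects,
#' masked with structural zeros, and closed so each sample's abundances sum
#' to 1. The pre-closure basis is kept in the ground truth so compositional
#' correlation recovery can be checked against it.
#'
#' @param config A [synth_config()].
#' @return A list with elements `table` (a compositional
#'   [feature_table()]), `design` (a [group_design()]), and `truth` (a
#'   `ground_truth` list carrying planted effects, planted links, and the
#'   pre-closure basis matrix).
#' @export
generate_microbiome <- function(config) {
  cfg <- validate_synth_config(config)
  design <- synth_design(cfg)
  n <- nrow(design)
  sp <- species_ids(cfg$n_species)
  with_seed(cfg$seed, {
    mu <- rnorm(cfg$n_species, 0, cfg$baseline_sd)
    eps <- matrix(rnorm(cfg$n_species * n, 0, cfg$noise_sd),
                  cfg$n_species, n, dimnames = list(sp, design$sample))
    # planted species-species basis correlation: rebuild the second
    # species' noise from the first's standardized noise
    for (i in seq_len(nrow(cfg$species_links))) {
      l <- cfg$species_links[i, ]
      za <- eps[l$species_a, ]
      if (sd(za) == 0) abort("species link against zero-variance species")
      za <- (za - mean(za)) / sd(za)
      eb <- rnorm(n)
      eps[l$species_b, ] <- cfg$noise_sd *
        (l$rho * za + sqrt(1 - l$rho^2) * eb)
    }
    logb <- mu + eps
    fx <- cfg$group_effects[cfg$group_effects$feature %in% sp, ]
    for (i in seq_len(nrow(fx))) {
      idx <- design$sample[design$group == fx$group[i]]
      logb[fx$feature[i], idx] <- logb[fx$feature[i], idx] +
        fx$log2fc[i] * log(2)
    }
    basis <- exp(logb)
    # structural zeros mimic a detection limit: cells are Bernoulli-masked
    # with probability rising steeply (logistic, 0.5 log-unit softness) as
    # the basis abundance falls below the table-wide `sparsity` quantile,
    # so rare taxa are mostly zero while dominant taxa are always seen
    mask <- matrix(FALSE, nrow(basis), ncol(basis))
    if (cfg$sparsity > 0) {
      tau <- quantile(logb, cfg$sparsity, names = FALSE)
      q <- stats::plogis((tau - logb) / 0.5)
      mask <- matrix(runif(length(basis)) < q, nrow(basis), ncol(basis))
    }
    basis_masked <- basis
    basis_masked[mask] <- 0
    dead <- colSums(basis_masked) == 0
    if (any(dead)) {
      abort(sprintf(
        "sparsity %.2f left sample(s) all-zero (%s); lower it",
        cfg$sparsity, paste(design$sample[dead], collapse = ", ")))
    }
    fractions <- sweep(basis_masked, 2, colSums(basis_masked), "/")
  })
  ann <- tibble(feature = sp, annotation = synthetic_phyla(cfg$n_species))
  table <- feature_table(fractions, kind = "microbe", annotations = ann,
                         compositional = TRUE)
  truth <- structure(list(
    config = cfg,
    effects = cfg$group_effects,
    cross_links = cfg$cross_links,
    species_links = cfg$species_links,
    basis = basis,
    log_basis = logb), class = "ground_truth")
  list(table = table, design = design, truth = truth)
}

#' Generate a synthetic metabolome table
#'
#' Metabolite log intensities are normal around an ion-count-scale baseline
#' with planted group effects; each planted cross-modal link replaces the
#' metabolite's noise with `rho * z_s + sqrt(1 - rho^2) * eps`, where `z_s`
#' standardizes the linked species' log basis abundance (pre-closure), so
#' the compositional distortion of closure is part of what the correlation
#' stages must overcome.
#'
#' @param config A [synth_config()].
#' @param truth The `ground_truth` returned by [generate_microbiome()]
#'   (required when `cross_links` are planted).
#' @return A [feature_table()] of kind `"metabolite"`.
#' @export
generate_metabolome <- function(config, truth = NULL) {
  cfg <- validate_synth_config(config)
  design <- synth_design(cfg)
  n <- nrow(design)
  mt <- metabolite_ids(cfg$n_metabolites)
  if (nrow(cfg$cross_links) > 0 && is.null(truth)) {
    abort("cross_links are planted: pass the microbiome ground truth")
  }
  with_seed(cfg$seed + 1L, {
    mu <- rnorm(cfg$n_metabolites, cfg$metab_log_mean, 1)
    eps <- matrix(rnorm(cfg$n_metabolites * n),
                  cfg$n_metabolites, n, dimnames = list(mt, design$sample))
    for (i in seq_len(nrow(cfg$cross_links))) {
      l <- cfg$cross_links[i, ]
      idx <- if (is.na(l$group)) design$sample else
        design$sample[design$group == l$group]
      zs <- truth$log_basis[l$species, idx]
      if (sd(zs) == 0) {
        abort(sprintf("cross link against zero-variance species '%s'",
                      l$species))
      }
      zs <- (zs - mean(zs)) / sd(zs)
      eps[l$metabolite, idx] <- l$rho * zs +
        sqrt(1 - l$rho^2) * rnorm(length(idx))
    }
    logi <- mu + cfg$noise_sd * eps
    fx <- cfg$group_effects[cfg$group_effects$feature %in% mt, ]
    for (i in seq_len(nrow(fx))) {
      idx <- design$sample[design$group == fx$group[i]]
      logi[fx$feature[i], idx] <- logi[fx$feature[i], idx] +
        fx$log2fc[i] * log(2)
    }
    intens <- exp(logi)
  })
  ann <- tibble(feature = mt, annotation = synthetic_pathways(cfg$n_metabolites))
  feature_table(intens, kind = "metabolite", annotations = ann,
                compositional = FALSE)
}

#' Generate a full paired synthetic dataset
#'
#' Convenience wrapper running [generate_microbiome()] then
#' [generate_metabolome()] under one configuration.
#'
#' @param config A [synth_config()].
#' @return A list with `microbes`, `metabolites`, `design`, `truth`.
#' @export
synthesize_dataset <- function(config) {
  mb <- generate_microbiome(config)
  met <- generate_metabolome(config, mb$truth)
  list(microbes = mb$table, metabolites = met,
       design = mb$design, truth = mb$truth)
}

#' Write a synthetic dataset to an output directory
#'
#' Emits `microbes.tsv`, `metabolites.tsv`, annotation TSVs, `metadata.tsv`
#' and `ground_truth.json`.
#'
#' @param dataset A list from [synthesize_dataset()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(dataset$microbes, file.path(outdir, "microbes.tsv"),
                      file.path(outdir, "microbe_annotations.tsv"))
  write_feature_table(dataset$metabolites,
                      file.path(outdir, "metabolites.tsv"),
                      file.path(outdir, "metabolite_annotations.tsv"))
  write_group_design(dataset$design, file.path(outdir, "metadata.tsv"))
  write_ground_truth(dataset$truth, file.path(outdir, "ground_truth.json"))
  invisible(outdir)
}

#' Serialize planted ground truth to JSON
#'
#' The full pre-closure basis is stored so a write/read round trip
#' reproduces the object exactly.
#'
#' @param truth A `ground_truth` object.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    effects = truth$effects,
    cross_links = truth$cross_links,
    species_links = truth$species_links,
    basis = list(features = rownames(truth$basis),
                 samples = colnames(truth$basis),
                 values = as.vector(truth$basis)),
    log_basis = list(values = as.vector(truth$log_basis)))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read planted ground truth back from JSON
#' @param path JSON path written by [write_ground_truth()].
#' @return A `ground_truth` object (without the generating config).
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- c(length(raw$basis$features), length(raw$basis$samples))
  dn <- list(raw$basis$features, raw$basis$samples)
  links <- as_tibble(raw$cross_links)
  if (nrow(links) > 0 && !"group" %in% names(links)) links$group <- NA_character_
  structure(list(
    effects = as_tibble(raw$effects),
    cross_links = links,
    species_links = as_tibble(raw$species_links),
    basis = matrix(raw$basis$values, dims[1], dims[2], dimnames = dn),
    log_basis = matrix(raw$log_basis$values, dims[1], dims[2],
                       dimnames = dn)), class = "ground_truth")
}
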