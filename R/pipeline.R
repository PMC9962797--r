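#' Compute all three correlation layers for one group
#'
#' Restricts both tables to the group's samples, then runs SparCC on the
#' microbes, Spearman on the metabolites, and cross-modal Spearman between
#' the two — the per-group inputs of [build_heteronet()].
#'
#' @param microbes Microbe [feature_table()] (all samples).
#' @param metabolites Metabolite [feature_table()] (all samples).
#' @param design A [group_design()].
#' @param group Group label.
#' @param sparcc_args List of extra arguments for [sparcc()].
#' @param seed Integer seed for the SparCC stage.
#' @return List with `mm`, `tt`, `mt` correlation tibbles and the
#'   `sparcc_fit`.
#' @export
group_correlations <- function(microbes, metabolites, design, group,
                               sparcc_args = list(), seed = 1L) {
  gs <- group_samples(design, group)
  mb <- ft_subset(microbes, gs)
  mt <- ft_subset(metabolites, gs)
  fit <- do.call(sparcc, c(list(table = mb, seed = seed), sparcc_args))
  list(mm = fit$correlations,
       tt = metabolite_spearman(mt),
       mt = cross_modal_spearman(mb, mt),
       sparcc_fit = fit)
}

#' Read a pipeline run configuration from YAML
#'
#' The configuration either names input files (`microbes`, `metabolites`,
#'   `metadata`, optional `kegg_mapping`) or carries a `synthetic` block of
#'   [synth_config()] fields. Optional fields: `contrasts` (list of
#'   two-element group vectors), `p_threshold`, `p_adjust`, `seed`,
#'   `sparcc` (argument list).
#'
#' @param path YAML file path.
#' @return A named list usable as [run_pipeline()]'s `config`.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full per-group network pipeline
#'
#' Orchestrates the whole analysis from one configuration: data generation
#' (or loading), group-wise differential statistics for every requested
#' contrast, alpha and beta diversity, metabolite PCA, the three
#' correlation layers per group, per-group heterogeneous networks with
#' ATria rankings and layouts, KEGG support annotation when a mapping is
#' given, and network-specific metabolites across groups. All outputs are
#' plain text (TSV / GraphML / JSON); a manifest records the configuration
#' hash, seeds and package version, and a rerun with the same
#' configuration reproduces every numeric output byte for byte.
#'
#' @param config A named list (see [read_run_config()]) or a YAML path.
#' @param outdir Output directory.
#' @return Invisibly, a list with the loaded `data`, per-group `networks`,
#'   `rankings`, `specific` metabolites and the `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  p_threshold <- config$p_threshold %||% 0.05
  p_adjust <- config$p_adjust %||% "none"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  log_path <- file.path(outdir, "run.log")
  cat(sprintf("pipeline start seed=%d\n", seed), file = log_path)
  stage <- function(name, code) {
    cat(sprintf("stage %s\n", name), file = log_path, append = TRUE)
    tryCatch(code, error = function(e) {
      cat(sprintf("stage %s FAILED: %s\n", name, conditionMessage(e)),
          file = log_path, append = TRUE)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  data <- stage("load", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      args$seed <- args$seed %||% seed
      for (f in c("group_effects", "cross_links", "species_links")) {
        if (!is.null(args[[f]])) args[[f]] <- bind_rows(args[[f]])
      }
      ds <- synthesize_dataset(do.call(synth_config, args))
      write_synthetic_dataset(ds, file.path(outdir, "data"))
      ds
    } else {
      microbes <- read_feature_table(config$microbes, kind = "microbe")
      metabolites <- read_feature_table(config$metabolites,
                                        kind = "metabolite")
      design <- read_group_design(config$metadata)
      list(microbes = microbes, metabolites = metabolites, design = design)
    }
  })
  check_design(data$microbes, data$design)
  check_design(data$metabolites, data$design)
  groups <- design_groups(data$design)
  required <- config$groups %||% groups
  missing <- setdiff(required, groups)
  if (length(missing)) {
    abort(paste0("configured group(s) absent from the data: ",
                 paste(missing, collapse = ", ")))
  }

  contrasts <- config$contrasts %||%
    utils::combn(groups, 2, simplify = FALSE)
  stage("differential", {
    diff_dir <- file.path(outdir, "differential")
    dir.create(diff_dir, showWarnings = FALSE)
    for (ct in contrasts) {
      ct <- unlist(ct)
      tag <- gsub("[^A-Za-z0-9]+", "_", paste(ct, collapse = "_vs_"))
      readr::write_tsv(
        differential_abundance(data$microbes, data$design, ct),
        file.path(diff_dir, paste0("microbes_", tag, ".tsv")),
        progress = FALSE)
      readr::write_tsv(
        differential_abundance(data$metabolites, data$design, ct),
        file.path(diff_dir, paste0("metabolites_", tag, ".tsv")),
        progress = FALSE)
    }
  })

  stage("ordination", {
    ord_dir <- file.path(outdir, "ordination")
    dir.create(ord_dir, showWarnings = FALSE)
    readr::write_tsv(alpha_diversity(data$microbes, data$design),
                     file.path(ord_dir, "alpha_shannon.tsv"),
                     progress = FALSE)
    readr::write_tsv(bray_curtis_matrix(data$microbes),
                     file.path(ord_dir, "bray_curtis.tsv"), progress = FALSE)
    pca <- pca_metabolites(data$metabolites, data$design,
                           k = min(5L, length(ft_samples(data$metabolites))))
    readr::write_tsv(pca$scores, file.path(ord_dir, "pca_scores.tsv"),
                     progress = FALSE)
    readr::write_tsv(
      tibble(component = seq_along(pca$all_explained_variance),
             explained_variance = pca$all_explained_variance),
      file.path(ord_dir, "pca_variance.tsv"), progress = FALSE)
  })

  kegg <- NULL
  if (!is.null(config$kegg_mapping)) {
    kegg <- stage("kegg", read_kegg_mapping(config$kegg_mapping))
  }

  networks <- list()
  rankings <- list()
  seeds <- derive_seeds(seed, length(groups), offset = 100L)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    gdir <- file.path(outdir, "groups", gsub("[^A-Za-z0-9]+", "_", g))
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    corr <- stage(paste0("correlate:", g), {
      group_correlations(data$microbes, data$metabolites, data$design, g,
                         sparcc_args = config$sparcc %||% list(),
                         seed = seeds[gi])
    })
    for (layer in c("mm", "tt", "mt")) {
      readr::write_tsv(corr[[layer]],
                       file.path(gdir, paste0("correlations_", layer, ".tsv")),
                       progress = FALSE)
    }
    net <- stage(paste0("network:", g), {
      net <- build_heteronet(corr$mm, corr$tt, corr$mt,
                             data$microbes, data$metabolites, data$design,
                             g, p_threshold = p_threshold,
                             p_adjust = p_adjust)
      if (!is.null(kegg)) net <- kegg_support(net, kegg)
      net
    })
    rk <- atria_rank(net)
    coords <- layout_heteronet(net, seed = seeds[gi])
    export_graphml(net, file.path(gdir, "network.graphml"), ranking = rk)
    export_edge_tsv(net, file.path(gdir, "edges.tsv"))
    readr::write_tsv(tidy(rk), file.path(gdir, "atria_ranking.tsv"),
                     progress = FALSE)
    readr::write_tsv(coords, file.path(gdir, "layout.tsv"), progress = FALSE)
    networks[[g]] <- net
    rankings[[g]] <- rk
  }

  specific <- stage("specific_metabolites", {
    sp <- network_specific_metabolites(networks, data$metabolites,
                                       data$design)
    readr::write_tsv(sp, file.path(outdir, "network_specific_metabolites.tsv"),
                     progress = FALSE)
    sp
  })

  manifest <- list(
    package = "micromet",
    version = as.character(utils::packageVersion("micromet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    group_seeds = as.list(setNames(seeds, groups)),
    p_threshold = p_threshold,
    p_adjust = p_adjust,
    config_hash = rlang::hash(config),
    groups = groups)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cat("pipeline done\n", file = log_path, append = TRUE)
  invisible(list(data = data, networks = networks, rankings = rankings,
                 specific = specific, manifest = manifest))
}
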