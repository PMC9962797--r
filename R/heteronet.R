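#' Assemble a per-group heterogeneous co-occurrence network
#'
#' Builds a signed, weighted, two-mode graph for one experimental group
#' from the three correlation layers: microbe-microbe (SparCC),
#' metabolite-metabolite (Spearman) and microbe-metabolite (cross-modal
#' Spearman). An edge is admitted when its p-value is at or below the
#' admission threshold (optionally after Benjamini-Hochberg adjustment
#' across each layer); its weight is the signed correlation. A node exists
#' for every feature with at least one admitted edge, and carries its
#' type, phylum or pathway annotation, and its group-mean abundance
#' (relative abundance for microbes, median-scaled intensity for
#' metabolites).
#'
#' @param mm,tt,mt Correlation tibbles (as produced by [sparcc()],
#'   [metabolite_spearman()], [cross_modal_spearman()]) computed on this
#'   group's samples; any may be `NULL` to omit a layer.
#' @param microbes,metabolites The full feature tables (all samples), used
#'   for node annotation.
#' @param design A [group_design()].
#' @param group Group label.
#' @param p_threshold Admission threshold (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"` (adjustment within layer).
#' @return An object of class `hetero_network`: list with `nodes`
#'   (tibble: `node`, `node_type`, `annotation`, `mean_abundance`),
#'   `edges` (tibble: `from`, `to`, `weight`, `p_value`, `layer`,
#'   `kegg_supported`), and `group`.
#' @export
build_heteronet <- function(mm = NULL, tt = NULL, mt = NULL,
                            microbes, metabolites, design, group,
                            p_threshold = 0.05,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  layers <- purrr::compact(list(mm, tt, mt))
  edges <- if (length(layers)) bind_rows(layers) else
    tibble(feature_a = character(), feature_b = character(),
           layer = character(), rho = numeric(), p_value = numeric(),
           method = character())
  edges <- filter(edges, !is.na(.data$rho), !is.na(.data$p_value),
                  .data$feature_a != .data$feature_b)
  if (p_adjust == "BH" && nrow(edges)) {
    edges <- edges |>
      group_by(.data$layer) |>
      mutate(p_value = p.adjust(.data$p_value, method = "BH")) |>
      ungroup()
  }
  edges <- filter(edges, .data$p_value <= p_threshold)
  edges <- edges[!duplicated(paste(edges$layer,
                                   pair_key(edges$feature_a,
                                            edges$feature_b))), ]
  if (nrow(edges) == 0) {
    warn(sprintf("no edge admitted at p <= %g for group '%s': empty network",
                 p_threshold, group))
  }
  edge_tbl <- tibble(from = edges$feature_a, to = edges$feature_b,
                     weight = edges$rho, p_value = edges$p_value,
                     layer = edges$layer, kegg_supported = NA)
  node_ids <- sort(unique(c(edge_tbl$from, edge_tbl$to)))
  nodes <- node_attributes(node_ids, microbes, metabolites, design, group)
  structure(list(nodes = nodes, edges = edge_tbl, group = group),
            class = "hetero_network")
}

node_attributes <- function(node_ids, microbes, metabolites, design, group) {
  gs <- group_samples(design, group)
  mb_vals <- ft_values(microbes)[, gs, drop = FALSE]
  mt_raw <- impute_zeros(ft_values(metabolites))
  med <- apply(mt_raw, 1, median)
  mt_vals <- (mt_raw / ifelse(med > 0, med, NA_real_))[, gs, drop = FALSE]
  ann <- bind_rows(ft_annotations(microbes), ft_annotations(metabolites))
  rows <- map(node_ids, function(id) {
    if (id %in% rownames(mb_vals)) {
      tibble(node = id, node_type = "microbe",
             mean_abundance = mean(mb_vals[id, ]))
    } else if (id %in% rownames(mt_vals)) {
      tibble(node = id, node_type = "metabolite",
             mean_abundance = mean(mt_vals[id, ]))
    } else {
      abort(sprintf("edge endpoint '%s' not found in either table", id))
    }
  })
  nodes <- bind_rows(rows)
  if (nrow(nodes) == 0) {
    return(tibble(node = character(), node_type = character(),
                  annotation = character(), mean_abundance = numeric()))
  }
  nodes |>
    left_join(rename(ann, node = "feature"), by = "node") |>
    mutate(annotation = dplyr::coalesce(.data$annotation, "unknown")) |>
    select("node", "node_type", "annotation", "mean_abundance")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf(
    "<hetero_network '%s': %d node(s) (%d microbe, %d metabolite), %d edge(s)>\n",
    x$group, nrow(x$nodes), sum(x$nodes$node_type == "microbe"),
    sum(x$nodes$node_type == "metabolite"), nrow(x$edges)))
  invisible(x)
}

#' @export
#' @method tidy hetero_network
tidy.hetero_network <- function(x, ...) x$edges

#' @export
#' @method glance hetero_network
glance.hetero_network <- function(x, ...) {
  tibble(group = x$group,
         n_nodes = nrow(x$nodes),
         n_microbes = sum(x$nodes$node_type == "microbe"),
         n_metabolites = sum(x$nodes$node_type == "metabolite"),
         n_edges = nrow(x$edges),
         n_positive = sum(x$edges$weight > 0),
         n_negative = sum(x$edges$weight < 0))
}

#' Convert a heterogeneous network to an igraph object
#'
#' @param network A `hetero_network`.
#' @param ranking Optional [atria_rank()] result; adds a `rank` node
#'   attribute (`NA` for unranked nodes).
#' @return An undirected igraph graph with typed node and edge attributes.
#' @export
heteronet_igraph <- function(network, ranking = NULL) {
  nodes <- network$nodes
  rank <- rep(NA_real_, nrow(nodes))
  if (!is.null(ranking)) {
    idx <- match(nodes$node, ranking$node)
    rank <- ranking$rank[idx]
  }
  vertices <- data.frame(name = nodes$node, node_type = nodes$node_type,
                         annotation = nodes$annotation,
                         mean_abundance = nodes$mean_abundance,
                         rank = as.numeric(rank),
                         stringsAsFactors = FALSE)
  edges <- as.data.frame(network$edges)
  edges$kegg_supported <- as.numeric(edges$kegg_supported)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Write a heterogeneous network to GraphML
#'
#' Node attributes `node_type`, `annotation`, `mean_abundance`, `rank` and
#' edge attributes `weight` (signed correlation), `p_value`, `layer`,
#' `kegg_supported` are all encoded, so negative correlations and layer
#' provenance survive re-import.
#'
#' @param network A `hetero_network`.
#' @param path Output path.
#' @param ranking Optional [atria_rank()] result for the `rank` attribute.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path, ranking = NULL) {
  nodes <- network$nodes
  rank <- rep(NA_real_, nrow(nodes))
  if (!is.null(ranking)) rank <- ranking$rank[match(nodes$node, ranking$node)]
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c("g_group", "graph", "group", "string"),
    c("v_node_type", "node", "node_type", "string"),
    c("v_annotation", "node", "annotation", "string"),
    c("v_mean_abundance", "node", "mean_abundance", "double"),
    c("v_rank", "node", "rank", "double"),
    c("e_weight", "edge", "weight", "double"),
    c("e_p_value", "edge", "p_value", "double"),
    c("e_layer", "edge", "layer", "string"),
    c("e_kegg_supported", "edge", "kegg_supported", "boolean"))
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                        "attr.name" = k[3], "attr.type" = k[4])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "undirected")
  data_node <- function(parent, key, value) {
    if (is.na(value)) return(invisible())
    txt <- if (is.numeric(value)) sprintf("%.17g", value)
    else if (is.logical(value)) tolower(as.character(value))
    else as.character(value)
    xml2::xml_add_child(parent, "data", key = key, txt)
  }
  data_node(graph, "g_group", network$group)
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = nodes$node[i])
    data_node(nd, "v_node_type", nodes$node_type[i])
    data_node(nd, "v_annotation", nodes$annotation[i])
    data_node(nd, "v_mean_abundance", nodes$mean_abundance[i])
    data_node(nd, "v_rank", rank[i])
  }
  ed <- network$edges
  for (i in seq_len(nrow(ed))) {
    eg <- xml2::xml_add_child(graph, "edge", source = ed$from[i],
                              target = ed$to[i])
    data_node(eg, "e_weight", ed$weight[i])
    data_node(eg, "e_p_value", ed$p_value[i])
    data_node(eg, "e_layer", ed$layer[i])
    data_node(eg, "e_kegg_supported", ed$kegg_supported[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a heterogeneous network back from GraphML
#'
#' @param path GraphML file written by [export_graphml()].
#' @return A `hetero_network`.
#' @export
import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  get_data <- function(node, key) {
    hit <- xml2::xml_find_first(node, sprintf("./data[@key='%s']", key))
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  graph <- xml2::xml_find_first(doc, "./graph")
  group <- get_data(graph, "g_group")
  nnodes <- xml2::xml_find_all(graph, "./node")
  nodes <- tibble(
    node = xml2::xml_attr(nnodes, "id"),
    node_type = vapply(nnodes, get_data, character(1), "v_node_type"),
    annotation = vapply(nnodes, get_data, character(1), "v_annotation"),
    mean_abundance = as.numeric(
      vapply(nnodes, get_data, character(1), "v_mean_abundance")))
  nedges <- xml2::xml_find_all(graph, "./edge")
  kegg_raw <- vapply(nedges, get_data, character(1), "e_kegg_supported")
  edges <- tibble(
    from = xml2::xml_attr(nedges, "source"),
    to = xml2::xml_attr(nedges, "target"),
    weight = as.numeric(vapply(nedges, get_data, character(1), "e_weight")),
    p_value = as.numeric(vapply(nedges, get_data, character(1), "e_p_value")),
    layer = vapply(nedges, get_data, character(1), "e_layer"),
    kegg_supported = ifelse(is.na(kegg_raw), NA, kegg_raw == "true"))
  structure(list(nodes = nodes, edges = edges, group = group),
            class = "hetero_network")
}

#' Write a network's edges as a flat TSV
#'
#' @param network A `hetero_network`.
#' @param path Output TSV path.
#' @export
export_edge_tsv <- function(network, path) {
  readr::write_tsv(network$edges, path, progress = FALSE)
  invisible(path)
}

#' Flag KEGG-supported edges
#'
#' An edge is KEGG-supported when its correlation is positive and both
#' endpoints share at least one pathway identifier in the mapping —
#' mirroring the annotation of positive correlations backed by documented
#' pathways. Features absent from the mapping are simply unsupported.
#'
#' @param network A `hetero_network`.
#' @param mapping A tibble with columns `feature`, `pathway` (see
#'   [read_kegg_mapping()]).
#' @return The network with its `kegg_supported` edge flag filled in.
#' @export
kegg_support <- function(network, mapping) {
  mapping <- as_tibble(mapping)
  stopifnot(all(c("feature", "pathway") %in% names(mapping)))
  paths <- split(mapping$pathway, mapping$feature)
  shared <- function(a, b) {
    pa <- paths[[a]]
    pb <- paths[[b]]
    !is.null(pa) && !is.null(pb) && length(intersect(pa, pb)) > 0
  }
  network$edges <- network$edges |>
    mutate(kegg_supported = .data$weight > 0 &
             purrr::map2_lgl(.data$from, .data$to, shared))
  network
}

#' Network-specific metabolites across groups
#'
#' A metabolite is specific to group G when it participates (has at least
#' one admitted edge, i.e. is a node) in G's network and in no other
#' group's network. Each specific metabolite is reported with its
#' group-mean median-scaled intensity in every group, so descriptive
#' fold-change statements can be checked alongside.
#'
#' @param networks Named list of `hetero_network` objects, one per group
#'   (>= 2).
#' @param metabolites Optional full metabolite [feature_table()]; with
#'   `design`, adds `mean_<group>` intensity columns.
#' @param design Optional [group_design()].
#' @return A tibble: `group`, `feature`, plus per-group mean columns when
#'   tables are supplied. Specific sets are disjoint by construction.
#' @export
network_specific_metabolites <- function(networks, metabolites = NULL,
                                         design = NULL) {
  if (length(networks) < 2) abort("need networks for at least 2 groups")
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    names(networks) <- vapply(networks, function(n) n$group, character(1))
  }
  members <- purrr::imap(networks, function(net, g) {
    tibble(group = g,
           feature = net$nodes$node[net$nodes$node_type == "metabolite"])
  }) |> bind_rows()
  specific <- members |>
    group_by(.data$feature) |>
    filter(dplyr::n() == 1) |>
    ungroup() |>
    arrange(.data$group, .data$feature)
  if (!is.null(metabolites) && !is.null(design)) {
    raw <- impute_zeros(ft_values(metabolites))
    med <- apply(raw, 1, median)
    scaled <- raw / ifelse(med > 0, med, NA_real_)
    for (g in design_groups(design)) {
      gm <- rowMeans(scaled[, group_samples(design, g), drop = FALSE])
      specific[[paste0("mean_", g)]] <- unname(gm[specific$feature])
    }
  }
  specific
}

#' Force-directed layout of a heterogeneous network
#'
#' Fruchterman-Reingold layout in which attraction acts only along
#' positive-weight edges while repulsion acts between all node pairs, so
#' positively correlated entities end up in close proximity and negative
#' correlations contribute no pull. Deterministic given `seed`;
#' coordinates are centred on the origin.
#'
#' @param network A `hetero_network`.
#' @param seed Integer seed.
#' @param iterations Layout iterations (default 200).
#' @return A tibble: `node`, `x`, `y`.
#' @export
layout_heteronet <- function(network, seed = 1L, iterations = 200) {
  nodes <- network$nodes$node
  if (length(nodes) == 0) return(tibble(node = character(), x = numeric(),
                                        y = numeric()))
  pos <- filter(network$edges, .data$weight > 0)
  g <- igraph::graph_from_data_frame(
    pos[, c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(name = nodes))
  xy <- with_seed(seed, {
    if (length(nodes) == 1) matrix(0, 1, 2) else
      igraph::layout_with_fr(g, niter = iterations,
                             weights = if (nrow(pos)) pos$weight else NULL)
  })
  xy <- sweep(xy, 2, colMeans(xy))
  tibble(node = nodes, x = xy[, 1], y = xy[, 2])
}

#' @export
#' @method autoplot hetero_network
autoplot.hetero_network <- function(object, seed = 1L, ...) {
  coords <- layout_heteronet(object, seed = seed)
  ed <- object$edges |>
    left_join(rename(coords, from = "node", x0 = "x", y0 = "y"),
              by = "from") |>
    left_join(rename(coords, to = "node", x1 = "x", y1 = "y"), by = "to")
  nd <- left_join(object$nodes, coords, by = "node")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1,
                   colour = .data$weight > 0),
      alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#27ae60", `FALSE` = "#c0392b"),
      labels = c(`TRUE` = "positive", `FALSE` = "negative"),
      name = "correlation") +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$node_type,
                   size = .data$mean_abundance, fill = .data$annotation),
      colour = "grey20") +
    ggplot2::scale_shape_manual(values = c(microbe = 21, metabolite = 22)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = object$group)
}
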