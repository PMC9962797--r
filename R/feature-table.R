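#' Construct a feature table
#'
#' A feature table holds one omics layer as a features-by-samples tibble:
#' the first column `feature` carries unique feature identifiers and every
#' remaining column is one sample. Microbe tables hold relative abundances
#' (each sample column sums to 1 when `compositional = TRUE`); metabolite
#' tables hold non-negative ion-count intensities. Per-feature annotations
#' (phylum for microbes, biochemical pathway for metabolites) ride along as
#' an attribute and survive the TSV round trip.
#'
#' @param values A data frame with a `feature` character column followed by
#'   numeric sample columns, or a numeric matrix with feature row names and
#'   sample column names.
#' @param kind `"microbe"` or `"metabolite"`.
#' @param annotations Optional tibble with columns `feature` and
#'   `annotation` (phylum or pathway label).
#' @param compositional Should sample columns be required to sum to 1
#'   (within 1e-6)? Defaults to `TRUE` for microbe tables.
#' @return A tibble of class `feature_table`.
#' @export
feature_table <- function(values, kind = c("microbe", "metabolite"),
                          annotations = NULL,
                          compositional = NULL) {
  kind <- match.arg(kind)
  if (is.matrix(values)) {
    if (is.null(rownames(values)) || is.null(colnames(values))) {
      abort("matrix input needs feature row names and sample column names")
    }
    values <- bind_cols(tibble(feature = rownames(values)),
                        as_tibble(values, .name_repair = "minimal"))
  }
  values <- as_tibble(values)
  if (!identical(names(values)[1], "feature")) {
    abort("first column of a feature table must be named 'feature'")
  }
  compositional <- compositional %||% (kind == "microbe")
  out <- structure(values,
                   class = c("feature_table", class(tibble())),
                   kind = kind,
                   compositional = compositional,
                   annotations = annotations)
  validate_feature_table(out)
  out
}

validate_feature_table <- function(x) {
  vals <- ft_values(x)
  feats <- x$feature
  if (anyDuplicated(feats)) {
    abort(paste0("duplicated feature id(s): ",
                 paste(unique(feats[duplicated(feats)]), collapse = ", ")))
  }
  samp <- colnames(vals)
  if (anyDuplicated(samp)) {
    abort(paste0("duplicated sample id(s): ",
                 paste(unique(samp[duplicated(samp)]), collapse = ", ")))
  }
  if (!all(vapply(as.data.frame(vals), is.numeric, logical(1)))) {
    bad <- samp[!vapply(as.data.frame(vals), is.numeric, logical(1))]
    abort(paste0("non-numeric sample column(s): ", paste(bad, collapse = ", ")))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value at feature '%s', sample '%s'",
                  feats[idx[1]], samp[idx[2]]))
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative value at feature '%s', sample '%s'",
                  feats[idx[1]], samp[idx[2]]))
  }
  if (isTRUE(attr(x, "compositional"))) {
    sums <- colSums(vals)
    off <- which(abs(sums - 1) > 1e-6)
    if (length(off)) {
      abort(sprintf(
        "compositional check failed: sample '%s' sums to %.6g, expected 1",
        samp[off[1]], sums[off[1]]))
    }
  }
  ann <- attr(x, "annotations")
  if (!is.null(ann)) {
    if (!all(c("feature", "annotation") %in% names(ann))) {
      abort("annotations need columns 'feature' and 'annotation'")
    }
    missing <- setdiff(ann$feature, feats)
    if (length(missing)) {
      abort(paste0("annotation refers to unknown feature(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Extract the numeric value matrix of a feature table
#'
#' @param x A [feature_table()].
#' @return Numeric matrix, features as rows, samples as columns.
#' @export
ft_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$feature
  m
}

#' Sample identifiers of a feature table
#' @param x A [feature_table()].
#' @export
ft_samples <- function(x) setdiff(names(x), "feature")

#' Feature annotations of a feature table
#' @param x A [feature_table()].
#' @return A tibble with columns `feature`, `annotation` (possibly empty).
#' @export
ft_annotations <- function(x) {
  ann <- attr(x, "annotations")
  if (is.null(ann)) {
    return(tibble(feature = character(), annotation = character()))
  }
  as_tibble(ann)
}

#' Kind of a feature table
#' @param x A [feature_table()].
#' @export
ft_kind <- function(x) attr(x, "kind")

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d %s feature(s) x %d sample(s)%s>\n",
              nrow(x), ft_kind(x), ncol(x) - 1,
              if (isTRUE(attr(x, "compositional"))) ", compositional" else ""))
  NextMethod()
}

#' Construct a group design
#'
#' Maps each sample to exactly one experimental group. The default group
#' order follows the four-arm diet-by-exposure design (chow or Western diet
#' crossed with Gulf War chemical exposure).
#'
#' @param data A data frame with columns `sample` and `group`.
#' @param levels Canonical group order; defaults to the four-arm design.
#' @return A tibble of class `group_design` with `group` as a factor.
#' @export
group_design <- function(data,
                         levels = c("Chow", "Chow+GWI", "WD", "WD+GWI")) {
  data <- as_tibble(data)
  if (!all(c("sample", "group") %in% names(data))) {
    abort("group design needs columns 'sample' and 'group'")
  }
  if (anyDuplicated(data$sample)) {
    abort(paste0("sample(s) assigned more than once: ",
                 paste(unique(data$sample[duplicated(data$sample)]),
                       collapse = ", ")))
  }
  groups <- as.character(data$group)
  levels <- union(levels[levels %in% groups], unique(groups))
  out <- tibble(sample = as.character(data$sample),
                group = factor(groups, levels = levels))
  empty <- setdiff(levels, groups)
  if (length(empty)) {
    abort(paste0("empty group(s): ", paste(empty, collapse = ", ")))
  }
  structure(out, class = c("group_design", class(tibble())))
}

#' Group labels present in a design
#' @param design A [group_design()].
#' @export
design_groups <- function(design) levels(design$group)

#' Samples belonging to one group
#' @param design A [group_design()].
#' @param group Group label.
#' @export
group_samples <- function(design, group) {
  if (!group %in% levels(design$group)) {
    abort(sprintf("unknown group '%s'", group))
  }
  design$sample[design$group == group]
}

# check every table sample is assigned to exactly one group
check_design <- function(table, design) {
  samp <- ft_samples(table)
  missing <- setdiff(samp, design$sample)
  if (length(missing)) {
    abort(paste0("sample(s) missing from design: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Subset a feature table to a set of samples
#'
#' Preserves kind, annotations and the compositional declaration; useful
#' for restricting a table to one experimental group's samples.
#'
#' @param x A [feature_table()].
#' @param samples Character vector of sample ids to keep.
#' @return A [feature_table()] over `samples`.
#' @export
ft_subset <- function(x, samples) {
  missing <- setdiff(samples, ft_samples(x))
  if (length(missing)) {
    abort(paste0("unknown sample(s): ", paste(missing, collapse = ", ")))
  }
  feature_table(x[, c("feature", samples)], kind = ft_kind(x),
                annotations = attr(x, "annotations"),
                compositional = attr(x, "compositional"))
}
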