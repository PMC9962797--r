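#' Read a feature table from TSV
#'
#' Expects a tab-delimited UTF-8 file: first column the feature id, one
#' column per sample, '.' decimal separator. An optional companion
#' annotation file (columns `feature`, `annotation`) may be given.
#'
#' @param path Path to the TSV file.
#' @param kind `"microbe"` or `"metabolite"`.
#' @param annotations_path Optional path to an annotation TSV.
#' @param compositional Enforce unit column sums (default: microbe tables).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, kind = c("microbe", "metabolite"),
                               annotations_path = NULL,
                               compositional = NULL) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(raw) < 2) abort("feature table needs at least one sample column")
  names(raw)[1] <- "feature"
  raw$feature <- as.character(raw$feature)
  # numeric conversion through strtod so 17-digit output re-reads exactly
  for (j in seq(2, ncol(raw))) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(num) && !all(is.na(raw[[j]]))) {
      bad <- which(is.na(num) & !is.na(raw[[j]]))[1]
      abort(sprintf("non-numeric cell at row %d, column '%s' of %s",
                    bad, names(raw)[j], path))
    }
    raw[[j]] <- num
  }
  ann <- NULL
  if (!is.null(annotations_path)) {
    ann <- readr::read_tsv(annotations_path, show_col_types = FALSE,
                           progress = FALSE)
  }
  feature_table(raw, kind = kind, annotations = ann,
                compositional = compositional)
}

#' Write a feature table to TSV
#'
#' @param x A [feature_table()].
#' @param path Output TSV path.
#' @param annotations_path Optional path for the annotation TSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, annotations_path = NULL) {
  out <- as_tibble(as.data.frame(x))
  # serialize doubles with 17 significant digits so write-then-read is the
  # identity down to the last bit
  for (j in seq(2, ncol(out))) {
    out[[j]] <- sprintf("%.17g", out[[j]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(annotations_path)) {
    readr::write_tsv(ft_annotations(x), annotations_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a sample-to-group design from TSV
#'
#' @param path TSV with columns `sample` and `group`.
#' @param levels Canonical group order.
#' @return A [group_design()].
#' @export
read_group_design <- function(path,
                              levels = c("Chow", "Chow+GWI", "WD", "WD+GWI")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  group_design(raw, levels = levels)
}

#' Write a group design to TSV
#' @param design A [group_design()].
#' @param path Output TSV path.
#' @export
write_group_design <- function(design, path) {
  out <- tibble(sample = design$sample, group = as.character(design$group))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a feature-to-KEGG-pathway mapping
#'
#' The mapping is a two-column TSV (`feature`, `pathway`); a feature may
#' appear on several rows, one per pathway. Malformed rows (missing either
#' field) are skipped with a warning stating how many were dropped.
#'
#' @param path Path to the mapping TSV.
#' @return A tibble with columns `feature` and `pathway`.
#' @export
read_kegg_mapping <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(raw) < 2) abort("KEGG mapping needs columns 'feature' and 'pathway'")
  names(raw)[1:2] <- c("feature", "pathway")
  ok <- !is.na(raw$feature) & !is.na(raw$pathway) &
    nzchar(raw$feature) & nzchar(raw$pathway)
  if (any(!ok)) {
    warn(sprintf("skipped %d malformed mapping row(s)", sum(!ok)))
  }
  distinct(raw[ok, c("feature", "pathway")])
}
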