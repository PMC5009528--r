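#' Expression sets
#'
#' An `expression_set` couples a genes-by-samples matrix of non-negative
#' expression values (RSEM, TPM, microarray intensity, ...) with a sample
#' metadata table assigning every sample to a group (e.g. `tumor` / `normal`,
#' stages, smoking status, drug response). It is the unit consumed by
#' [filter_expressed_genes()] and [build_cepin()].
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); all values finite and `>= 0`.
#' @param metadata data frame with columns `sample_id` and `group` (extra
#'   columns are preserved as annotations); every sample in `values` must be
#'   present with a non-missing group label.
#' @return An object of class `expression_set` with elements `values` and
#'   `samples` (a tibble).
#' @export
expression_set <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (nrow(values) > 0L && is.null(rownames(values))) {
    abort("`values` must have gene rownames.")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (ncol(values) > 0L && is.null(colnames(values))) {
    abort("`values` must have sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf("duplicate gene symbol: '%s'",
                  rownames(values)[duplicated(rownames(values))][1L]))
  }
  if (anyDuplicated(colnames(values))) abort("duplicate sample IDs in `values`.")
  if (any(!is.finite(values))) abort("expression values must all be finite.")
  if (any(values < 0)) abort("expression values must be non-negative.")
  metadata <- as_tibble(metadata)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort("metadata must contain columns `sample_id` and `group`.")
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$group <- as.character(metadata$group)
  missing <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing)) {
    abort(sprintf("sample(s) without metadata: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  samples <- metadata[match(colnames(values), metadata$sample_id), ]
  if (anyNA(samples$group)) abort("every sample must have a group label.")
  structure(list(values = values, samples = samples), class = "expression_set")
}

#' Load an expression matrix and its sample metadata
#'
#' The matrix file is a TSV with gene symbols in the first column and sample
#' IDs in the header; the metadata file is a TSV with columns `sample_id` and
#' `group`. The returned set is restricted to samples present in both files;
#' samples found on only one side are dropped with a warning.
#'
#' @param matrix_path path to the expression TSV.
#' @param metadata_path path to the metadata TSV.
#' @return An [expression_set()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("expression matrix needs a gene column and >= 1 sample.")
  genes <- trimws(raw[[1L]])
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene symbol in '%s': '%s'",
                  matrix_path, genes[duplicated(genes)][1L]))
  }
  num <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(raw)[-1L]))
  bad <- which(is.na(num) & !is.na(as.matrix(raw[-1L])), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-numeric value at gene '%s', sample '%s' in '%s'",
                  genes[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], matrix_path))
  }
  rownames(num) <- genes
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort(sprintf("metadata '%s' must contain columns `sample_id` and `group`.",
                  metadata_path))
  }
  shared <- intersect(colnames(num), meta$sample_id)
  drop_expr <- setdiff(colnames(num), shared)
  drop_meta <- setdiff(meta$sample_id, shared)
  if (length(drop_expr)) {
    warn(sprintf("dropping %d sample(s) absent from metadata: %s",
                 length(drop_expr), paste(head(drop_expr, 5L), collapse = ", ")))
  }
  if (length(drop_meta)) {
    warn(sprintf("dropping %d metadata row(s) absent from matrix: %s",
                 length(drop_meta), paste(head(drop_meta, 5L), collapse = ", ")))
  }
  if (!length(shared)) abort("no samples shared between matrix and metadata.")
  expression_set(num[, shared, drop = FALSE],
                 meta[meta$sample_id %in% shared, ])
}

#' Write an expression set back to TSV files
#'
#' Values round-trip through [read_expression()] at full precision.
#'
#' @param expr an `expression_set`.
#' @param matrix_path,metadata_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, matrix_path, metadata_path) {
  stopifnot(inherits(expr, "expression_set"))
  tab <- as_tibble(expr$values, rownames = "gene")
  readr::write_tsv(tab, matrix_path)
  readr::write_tsv(expr$samples, metadata_path)
  invisible(matrix_path)
}

#' Two-step expressed-gene filter
#'
#' Reproduces the standard two-step definition of an expressed gene on a
#' cohort-wide matrix. Step (i): within each sample, the empirical
#' `sample_quantile` quantile of all genes' values is computed (linear
#' interpolation between order statistics, `type = 7`); a gene counts as
#' expressed in that sample only if its value is strictly greater than the
#' quantile — so ties at the threshold, and in particular an all-constant
#' sample, count as not expressed. Step (ii): a gene is retained when the
#' fraction of samples in which it is expressed is at least
#' `min_sample_frac` (inclusive).
#'
#' The filter is applied once to the full matrix (all groups pooled), so the
#' same gene universe underlies every group's co-expression network.
#'
#' @param expr an [expression_set()].
#' @param sample_quantile per-sample expression quantile below (or at) which a
#'   gene is considered silent in that sample; default 0.20.
#' @param min_sample_frac minimum fraction of samples in which a gene must be
#'   expressed; default 0.20.
#' @return The gene-filtered `expression_set`; the logical expressed-indicator
#'   matrix for all input genes is attached as attribute `"expressed"`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' es <- expression_set(m, data.frame(sample_id = c("s1", "s2"),
#'                                    group = "tumor"))
#' dim(filter_expressed_genes(es)$values)
#' @export
filter_expressed_genes <- function(expr, sample_quantile = 0.20,
                                   min_sample_frac = 0.20) {
  stopifnot(inherits(expr, "expression_set"))
  stopifnot_scalar_number(sample_quantile, "sample_quantile", 0, 1)
  stopifnot_scalar_number(min_sample_frac, "min_sample_frac", 0, 1)
  v <- expr$values
  if (!nrow(v) || !ncol(v)) abort("expression set is empty.")
  thresholds <- apply(v, 2L, quantile, probs = sample_quantile,
                      names = FALSE, type = 7)
  expressed <- sweep(v, 2L, thresholds, `>`)
  frac <- rowMeans(expressed)
  keep <- frac >= min_sample_frac
  out <- expression_set(v[keep, , drop = FALSE], expr$samples)
  attr(out, "expressed") <- expressed
  attr(out, "filter") <- list(sample_quantile = sample_quantile,
                              min_sample_frac = min_sample_frac,
                              genes_in = nrow(v), genes_kept = sum(keep))
  out
}

#' Samples belonging to one metadata group
#'
#' @param expr an `expression_set`.
#' @param group group label to select.
#' @return Character vector of sample IDs.
#' @export
group_samples <- function(expr, group) {
  stopifnot(inherits(expr, "expression_set"))
  if (!group %in% expr$samples$group) {
    abort(sprintf("group '%s' not present in metadata (available: %s)",
                  group, paste(unique(expr$samples$group), collapse = ", ")))
  }
  expr$samples$sample_id[expr$samples$group == group]
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("# expression_set: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  grp <- table(x$samples$group)
  cat("# groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}
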