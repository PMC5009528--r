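#' Read a gene set (one symbol per line)
#'
#' @param path file with one gene symbol per line; blank lines ignored.
#' @return Character vector of unique symbols.
#' @export
read_gene_set <- function(path) {
  syms <- trimws(readLines(path, warn = FALSE))
  syms <- unique(syms[nzchar(syms)])
  if (!length(syms)) abort(sprintf("gene-set file '%s' is empty", path))
  syms
}

default_run_config <- function() {
  list(
    network = NULL, expression = NULL, metadata = NULL,
    gene_sets = NULL,
    sample_quantile = 0.20, min_sample_frac = 0.20,
    transform = "log2p1", alpha_motif = 0.05,
    groups = NULL    # NULL = all pairwise contrasts among metadata groups
  )
}

resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  cfg <- utils::modifyList(default_run_config(), config)
  for (field in c("network", "expression", "metadata")) {
    if (is.null(cfg[[field]])) abort(sprintf("config field `%s` is required.", field))
    if (!file.exists(cfg[[field]])) {
      abort(sprintf("config field `%s`: file not found: '%s'", field, cfg[[field]]))
    }
  }
  stopifnot_scalar_number(cfg$sample_quantile, "sample_quantile", 0, 1)
  stopifnot_scalar_number(cfg$min_sample_frac, "min_sample_frac", 0, 1)
  stopifnot_scalar_number(cfg$alpha_motif, "alpha_motif", 0, 1, lower_open = TRUE)
  if (!cfg$transform %in% c("log2p1", "none")) {
    abort("`transform` must be 'log2p1' or 'none'.")
  }
  cfg
}

#' Run the full CePIN entropy / motif pipeline
#'
#' Orchestrates load → expressed-gene filter → per-group CePIN → entropy
#' profile → signed-motif census → all pairwise group contrasts, and
#' optionally writes every result table plus a JSON run report.
#'
#' @param config a named list or the path of a YAML file with fields
#'   `network`, `expression`, `metadata` (paths; required), optional
#'   `gene_sets` (named list of gene-set file paths), and parameters
#'   `sample_quantile`, `min_sample_frac`, `transform`, `alpha_motif`,
#'   `groups` (character vector restricting/ordering the contrasted groups;
#'   default: every group in the metadata, all pairs).
#' @param output_dir optional directory; when given, writes per-group CePIN
#'   and entropy TSVs, motif-census JSON, a flat contrast TSV, and
#'   `report.json` embedding the resolved configuration.
#' @return A `cepin_report` list: `config` (resolved), `counts`
#'   (dropped-record accounting), `entropy_summaries` (one row per group),
#'   `censuses` (one row per group), `contrasts` (flat tibble, one row per
#'   contrast and gene set), and `comparisons` (the underlying
#'   [compare_groups()] objects, named `"a_vs_b"`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- resolve_run_config(config)
  net <- read_network(cfg$network)
  expr <- read_expression(cfg$expression, cfg$metadata)
  filtered <- filter_expressed_genes(expr, cfg$sample_quantile, cfg$min_sample_frac)
  gene_sets <- if (!is.null(cfg$gene_sets)) {
    purrr::map(cfg$gene_sets, read_gene_set)
  }
  groups <- cfg$groups %||% sort(unique(filtered$samples$group))
  missing <- setdiff(groups, filtered$samples$group)
  if (length(missing)) {
    abort(sprintf("group(s) absent from metadata: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(groups) < 2L) abort("need at least two groups to contrast.")
  cepins <- purrr::map(
    setNames(groups, groups),
    function(g) build_cepin(net, filtered, g, transform = cfg$transform)
  )
  profiles <- purrr::map(cepins, entropy_profile)
  censuses <- purrr::map(cepins, motif_census, alpha = cfg$alpha_motif)
  pairs <- combn(groups, 2L, simplify = FALSE)
  comparisons <- purrr::map(
    setNames(pairs, purrr::map_chr(pairs, paste, collapse = "_vs_")),
    function(p) compare_groups(cepins[[p[1L]]], cepins[[p[2L]]],
                               gene_sets = gene_sets,
                               alpha_motif = cfg$alpha_motif)
  )
  report <- structure(
    list(
      config = cfg,
      counts = list(
        network_dropped = attr(net, "dropped"),
        genes_in = attr(filtered, "filter")$genes_in,
        genes_expressed = attr(filtered, "filter")$genes_kept,
        undefined_correlation_edges = purrr::map_int(
          cepins, ~ as.integer(attr(.x, "dropped_undefined"))
        )
      ),
      entropy_summaries = bind_rows(purrr::map(profiles, glance)),
      censuses = bind_rows(purrr::map(censuses, glance)),
      contrasts = bind_rows(purrr::map(comparisons, tidy)),
      comparisons = comparisons
    ),
    class = "cepin_report"
  )
  if (!is.null(output_dir)) write_report(report, cepins, profiles, output_dir)
  report
}

write_report <- function(report, cepins, profiles, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(cepins)) {
    write_cepin(cepins[[g]], file.path(output_dir, sprintf("cepin_%s.tsv", g)))
    write_entropy_profile(profiles[[g]],
                          file.path(output_dir, sprintf("entropy_%s.tsv", g)))
  }
  readr::write_tsv(report$contrasts, file.path(output_dir, "contrasts.tsv"))
  jsonlite::write_json(
    list(
      config = report$config,
      counts = report$counts,
      entropy_summaries = report$entropy_summaries,
      censuses = report$censuses,
      contrasts = report$contrasts
    ),
    file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(output_dir)
}

#' @export
print.cepin_report <- function(x, ...) {
  cat(sprintf("# CePIN pipeline report: %d group(s), %d contrast row(s)\n",
              nrow(x$entropy_summaries), nrow(x$contrasts)))
  cat(sprintf("# genes: %d in, %d expressed\n",
              x$counts$genes_in, x$counts$genes_expressed))
  print(x$entropy_summaries, ...)
  print(x$censuses, ...)
  invisible(x)
}
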