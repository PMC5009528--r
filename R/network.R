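#' Interaction networks
#'
#' An `interaction_network` is a tibble of undirected edges over gene symbols
#' (columns `gene_a`, `gene_b`, normalized so `gene_a < gene_b`), carrying the
#' node set — which may include isolated genes — as an attribute. It is the
#' scaffold onto which per-group co-expression is mapped.
#'
#' Gene identity is the exact symbol string after whitespace trimming; case is
#' preserved. Inputs must therefore already be harmonized to a single symbol
#' namespace (no identifier mapping is performed here).
#'
#' @param edges a data frame whose first two columns are gene symbols, one row
#'   per interaction. Self-loops are dropped and duplicate pairs (either
#'   orientation) are collapsed.
#' @param nodes optional character vector of node symbols; the union with all
#'   edge endpoints is kept, so isolated nodes can be retained.
#' @return A tibble of class `interaction_network` with columns `gene_a`,
#'   `gene_b`; attributes `nodes` (character) and `dropped` (counts of
#'   discarded self-loops and duplicates).
#' @examples
#' net <- as_interaction_network(
#'   data.frame(a = c("TP53", "EGFR", "TP53"), b = c("MDM2", "GRB2", "MDM2"))
#' )
#' network_nodes(net)
#' @export
as_interaction_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    abort("`edges` must be a data frame with at least two columns.")
  }
  a <- trimws(as.character(edges[[1L]]))
  b <- trimws(as.character(edges[[2L]]))
  bad <- is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b)
  if (any(bad)) {
    abort(sprintf("empty gene symbol in edge row(s) %s",
                  paste(head(which(bad), 5L), collapse = ", ")))
  }
  self <- a == b
  pairs <- normalize_pairs(a[!self], b[!self])
  dup <- duplicated(pairs)
  cleaned <- pairs[!dup, ]
  node_set <- sort(unique(c(cleaned$gene_a, cleaned$gene_b,
                            if (!is.null(nodes)) trimws(as.character(nodes)))))
  new_interaction_network(
    cleaned[order(cleaned$gene_a, cleaned$gene_b), ],
    nodes = node_set,
    dropped = list(self_loops = sum(self), duplicates = sum(dup))
  )
}

new_interaction_network <- function(edges, nodes, dropped = NULL,
                                    modules = NULL, signs = NULL) {
  out <- as_tibble(edges)
  attr(out, "nodes") <- nodes
  attr(out, "dropped") <- dropped
  attr(out, "modules") <- modules
  attr(out, "signs") <- signs
  class(out) <- c("interaction_network", class(tibble()))
  out
}

#' Read a protein-interaction network from an edge-list file
#'
#' Accepts a two-column delimited edge list (tab, comma, or whitespace,
#' auto-detected) or a three-column SIF record (`node relation node`; the
#' relation is ignored). A header line is recognized when both of its first
#' fields match common column names (`from`/`to`, `gene_a`/`gene_b`,
#' `protein1`/`protein2`, ...). Self-loops and duplicated pairs are removed
#' and their counts reported via a message and the `dropped` attribute.
#'
#' @param path path to the edge-list file.
#' @param quiet suppress the dropped-record message.
#' @return An [as_interaction_network()] object.
#' @export
read_network <- function(path, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) abort(sprintf("network file '%s' is empty", path))
  line_no <- which(keep)
  lines <- lines[keep]
  delim <- sniff_delim(lines[[1L]])
  fields <- strsplit(lines, delim)
  fields <- lapply(fields, function(f) f[nzchar(trimws(f))])
  nf <- lengths(fields)
  sif <- all(nf == 3L)
  bad <- if (sif) integer(0) else which(nf != 2L)
  if (length(bad)) {
    abort(sprintf(
      "malformed network line %d: expected 2 fields, found %d",
      line_no[bad[1L]], nf[bad[1L]]
    ))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", if (sif) 3L else 2L)
  header_names <- c(
    "from", "to", "gene_a", "gene_b", "source", "target", "node1", "node2",
    "protein1", "protein2", "interactor_a", "interactor_b", "genea", "geneb"
  )
  if (tolower(trimws(a[1L])) %in% header_names &&
      tolower(trimws(b[1L])) %in% header_names) {
    a <- a[-1L]
    b <- b[-1L]
  }
  if (!length(a)) abort(sprintf("network file '%s' has a header but no edges", path))
  net <- as_interaction_network(tibble(gene_a = a, gene_b = b))
  d <- attr(net, "dropped")
  if (!quiet && (d$self_loops + d$duplicates) > 0L) {
    inform(sprintf(
      "read_network: dropped %d self-loop and %d duplicate record(s) from '%s'",
      d$self_loops, d$duplicates, path
    ))
  }
  net
}

#' Write a cleaned network as a tab-separated edge list
#'
#' @param net an `interaction_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  readr::write_tsv(as_tibble(net)[, c("gene_a", "gene_b")], path)
  invisible(path)
}

#' Induced subgraph on a gene set
#'
#' Restricts a network to the genes in `genes`: the node set becomes the
#' intersection, and only edges with both endpoints retained survive. An empty
#' intersection yields an empty network.
#'
#' @param net an `interaction_network`.
#' @param genes character vector of gene symbols.
#' @return An `interaction_network`.
#' @export
induce_subgraph <- function(net, genes) {
  stopifnot(inherits(net, "interaction_network"))
  genes <- unique(trimws(as.character(genes)))
  nodes <- intersect(network_nodes(net), genes)
  keep <- net$gene_a %in% nodes & net$gene_b %in% nodes
  modules <- attr(net, "modules")
  signs <- attr(net, "signs")
  new_interaction_network(
    as_tibble(net)[keep, c("gene_a", "gene_b")],
    nodes = nodes,
    dropped = attr(net, "dropped"),
    modules = if (!is.null(modules)) modules[intersect(names(modules), nodes)],
    signs = if (!is.null(signs)) signs[intersect(names(signs), nodes)]
  )
}

#' Node set and degrees of a network
#'
#' `network_nodes()` returns every node, including isolated ones;
#' `network_degrees()` tabulates the degree \eqn{k_i} of each node (0 for
#' isolated nodes).
#'
#' @param net an `interaction_network` (or a CePIN, whose edge table is laid
#'   out the same way).
#' @return `network_nodes()`: a character vector. `network_degrees()`: a
#'   tibble with columns `gene` and `degree`.
#' @export
network_nodes <- function(net) {
  attr(net, "nodes") %||% sort(unique(c(net$gene_a, net$gene_b)))
}

#' @rdname network_nodes
#' @export
network_degrees <- function(net) {
  nodes <- network_nodes(net)
  tab <- table(factor(c(net$gene_a, net$gene_b), levels = nodes))
  tibble(gene = nodes, degree = as.integer(tab))
}

#' @export
print.interaction_network <- function(x, ...) {
  d <- attr(x, "dropped")
  cat(sprintf(
    "# interaction_network: %d nodes, %d edges%s\n",
    length(network_nodes(x)), nrow(x),
    if (!is.null(d)) sprintf(" (dropped %d self-loops, %d duplicates)",
                             d$self_loops, d$duplicates) else ""
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
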