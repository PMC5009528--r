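# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (set-based dedup, all-triples triangle
# classification, per-node entropy loops, exhaustive permutation nulls) so
# that agreement is evidence, not tautology.

# build a cepin directly from an edge table with correlations
make_test_cepin <- function(gene_a, gene_b, pcc, n = 30L, group = "test") {
  cepinet:::new_cepin(
    tibble::tibble(gene_a = gene_a, gene_b = gene_b),
    pcc = pcc, n = n, group = group, transform = "none",
    nodes = sort(unique(c(gene_a, gene_b))), dropped = 0L
  )
}

# seeded random simple graph as a normalized unique edge tibble
random_edge_table <- function(n_nodes, p_edge, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%03d", seq_len(n_nodes))
    pairs <- t(utils::combn(nodes, 2L))
    keep <- stats::runif(nrow(pairs)) < p_edge
    tibble::tibble(gene_a = pairs[keep, 1L], gene_b = pairs[keep, 2L])
  })
}

# oracle: entropy of one node by direct high-precision evaluation
oracle_entropy <- function(weights) {
  p <- weights / sum(weights)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(weights))
}

# oracle: per-node entropies of a weighted edge list via an explicit loop
oracle_entropy_profile <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  out <- list()
  for (v in nodes) {
    w <- c(edges$weight[edges$gene_a == v], edges$weight[edges$gene_b == v])
    if (length(w) >= 2L && sum(w) > 0) {
      out[[v]] <- tibble::tibble(gene = v, degree = length(w),
                                 entropy = oracle_entropy(w))
    }
  }
  dplyr::bind_rows(out)
}

# oracle: all triangles by exhaustive all-triples membership testing
oracle_triangles <- function(edges) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  edge_set <- key(edges$gene_a, edges$gene_b)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (length(nodes) < 3L) {
    return(tibble::tibble(gene_a = character(0), gene_b = character(0),
                          gene_c = character(0)))
  }
  triples <- t(utils::combn(nodes, 3L))
  hit <- key(triples[, 1L], triples[, 2L]) %in% edge_set &
    key(triples[, 2L], triples[, 3L]) %in% edge_set &
    key(triples[, 1L], triples[, 3L]) %in% edge_set
  tibble::tibble(gene_a = triples[hit, 1L], gene_b = triples[hit, 2L],
                 gene_c = triples[hit, 3L])
}

# oracle: motif-type counts by classifying the exhaustive triangle list
oracle_motif_counts <- function(edges) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  sgn <- setNames(sign(edges$pcc), key(edges$gene_a, edges$gene_b))
  tri <- oracle_triangles(edges)
  pos <- integer(nrow(tri))
  for (i in seq_len(nrow(tri))) {
    s <- c(sgn[key(tri$gene_a[i], tri$gene_b[i])],
           sgn[key(tri$gene_b[i], tri$gene_c[i])],
           sgn[key(tri$gene_a[i], tri$gene_c[i])])
    pos[i] <- sum(s > 0)
  }
  c(unbalanced_I = sum(pos == 0L), balanced_II = sum(pos == 1L),
    unbalanced_II = sum(pos == 2L), balanced_I = sum(pos == 3L))
}

# oracle: exact two-sided permutation p-value for |r| over all n! pairings
oracle_perm_pvalue <- function(x, y) {
  all_perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(all_perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  r0 <- abs(cor(x, y))
  rs <- vapply(all_perms(seq_along(y)), function(p) abs(cor(x, y[p])), 0)
  mean(rs >= r0 - 1e-12)
}

# convenience: run the generator + CePIN pipeline for one seed
simulate_contrast <- function(cfg) {
  net <- generate_network(cfg)
  coh <- generate_expression(net, cfg, "coherent")
  deg <- generate_expression(net, cfg, "degraded")
  es <- expression_set(cbind(coh$values, deg$values),
                       rbind(coh$samples, deg$samples))
  fe <- filter_expressed_genes(es)
  list(
    net = net, expr = fe,
    coherent = suppressMessages(build_cepin(net, fe, "coherent")),
    degraded = suppressMessages(build_cepin(net, fe, "degraded"))
  )
}
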