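#' Sign of a co-expression edge
#'
#' An edge is positive when its Pearson correlation is `> 0` and negative when
#' `< 0`. A correlation of exactly 0 cannot be signed; it also cannot occur on
#' a significance-filtered CePIN (r = 0 has p = 1), so a zero here signals
#' misuse on unfiltered input and raises an error.
#'
#' @param pcc numeric vector of correlations in `[-1, 1]`.
#' @return Integer vector of `+1` / `-1`.
#' @export
edge_sign <- function(pcc) {
  if (any(!is.finite(pcc)) || any(abs(pcc) > 1)) {
    abort("`pcc` must be finite and within [-1, 1].")
  }
  if (any(pcc == 0)) {
    abort("unsigned edge: PCC of exactly 0 (was the CePIN significance-filtered?)")
  }
  ifelse(pcc > 0, 1L, -1L)
}

#' Enumerate all triangles of a simple undirected graph
#'
#' Degree-ordered neighbor intersection: nodes are ranked by increasing degree
#' (ties broken lexicographically), each edge is oriented from lower to higher
#' rank, and for every edge the higher-rank neighborhoods of its endpoints are
#' intersected. Each triangle is reported exactly once; rows and the genes
#' within a row are returned in lexicographic order, independent of edge
#' insertion order.
#'
#' @param net an `interaction_network` or `cepin` edge table.
#' @return A tibble with columns `gene_a`, `gene_b`, `gene_c`
#'   (`gene_a < gene_b < gene_c`).
#' @export
enumerate_triangles <- function(net) {
  edges <- normalize_pairs(net$gene_a, net$gene_b)
  empty <- tibble(gene_a = character(0), gene_b = character(0),
                  gene_c = character(0))
  if (nrow(edges) < 3L) return(empty)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes))
  rank <- setNames(order(order(deg, nodes)), nodes)   # degree, then lexicographic
  lo <- ifelse(rank[edges$gene_a] < rank[edges$gene_b], edges$gene_a, edges$gene_b)
  hi <- ifelse(rank[edges$gene_a] < rank[edges$gene_b], edges$gene_b, edges$gene_a)
  succ <- split(hi, factor(lo, levels = nodes))       # higher-rank neighbors
  tri <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    common <- intersect(succ[[lo[e]]], succ[[hi[e]]])
    if (length(common)) {
      tri[[e]] <- tibble(x = lo[e], y = hi[e], z = common)
    }
  }
  tri <- bind_rows(tri)
  if (!nrow(tri)) return(empty)
  m <- t(apply(as.matrix(tri), 1L, sort))
  out <- tibble(gene_a = m[, 1L], gene_b = m[, 2L], gene_c = m[, 3L])
  arrange(out, .data$gene_a, .data$gene_b, .data$gene_c)
}

motif_levels <- c("balanced_I", "balanced_II", "unbalanced_I", "unbalanced_II")

# 0..3 positive edges -> motif type (balanced iff odd positive count)
motif_type_of <- function(positive_count) {
  factor(
    c("unbalanced_I", "balanced_II", "unbalanced_II", "balanced_I")[positive_count + 1L],
    levels = motif_levels
  )
}

#' Signed-triangle motif census of a CePIN
#'
#' Applies the significance filter ([significant_subnetwork()]), signs every
#' surviving edge by the sign of its correlation, enumerates triangles, and
#' classifies each by its number of positive edges following structural
#' balance theory: balanced motifs have an odd number (3: type I, i.e. all
#' positive; 1: type II) and unbalanced motifs an even number (0: type I;
#' 2: type II — two positive and one negative edge). The unbalanced-motif
#' ratio \eqn{p_{um} = N_{um} / N_{tm}} indexes the disorder of the network
#' structure.
#'
#' @param cepin a [build_cepin()] result (or an already-filtered CePIN).
#' @param alpha significance threshold for the edge filter; default 0.05.
#' @return A `motif_census` object: counts per motif type, `n_triangles`,
#'   `n_balanced`, `n_unbalanced`, `p_um`, `p_bm`, and the per-triangle table
#'   in `$triangles`. When no triangle survives, the fractions are `NA` (not
#'   0) and a warning is emitted. [tidy()] returns per-type counts and
#'   fractions; [glance()] a one-row summary.
#' @export
motif_census <- function(cepin, alpha = 0.05) {
  stopifnot(inherits(cepin, "cepin"))
  filtered <- significant_subnetwork(cepin, alpha)
  signs <- edge_sign(filtered$pcc)
  names(signs) <- pair_key(filtered$gene_a, filtered$gene_b)
  tri <- enumerate_triangles(filtered)
  if (nrow(tri)) {
    s_ab <- signs[pair_key(tri$gene_a, tri$gene_b)]
    s_bc <- signs[pair_key(tri$gene_b, tri$gene_c)]
    s_ac <- signs[pair_key(tri$gene_a, tri$gene_c)]
    pos <- (s_ab > 0) + (s_bc > 0) + (s_ac > 0)
    tri <- mutate(tri,
                  sign_ab = as.integer(s_ab), sign_bc = as.integer(s_bc),
                  sign_ac = as.integer(s_ac),
                  positive_count = as.integer(pos),
                  motif_type = motif_type_of(as.integer(pos)))
  } else {
    warn(sprintf("no triangles in the p < %g CePIN of group '%s'; fractions undefined",
                 alpha, attr(cepin, "group") %||% "?"))
    tri <- mutate(tri, sign_ab = integer(0), sign_bc = integer(0),
                  sign_ac = integer(0), positive_count = integer(0),
                  motif_type = motif_type_of(integer(0)))
  }
  counts <- table(tri$motif_type)
  n_tm <- nrow(tri)
  n_bm <- sum(counts[c("balanced_I", "balanced_II")])
  n_um <- sum(counts[c("unbalanced_I", "unbalanced_II")])
  structure(
    list(
      group = attr(cepin, "group"),
      alpha = alpha,
      n_triangles = n_tm,
      counts = setNames(as.integer(counts), names(counts)),
      n_balanced = as.integer(n_bm),
      n_unbalanced = as.integer(n_um),
      p_um = if (n_tm > 0) n_um / n_tm else NA_real_,
      p_bm = if (n_tm > 0) n_bm / n_tm else NA_real_,
      triangles = tri
    ),
    class = "motif_census"
  )
}

#' @export
tidy.motif_census <- function(x, ...) {
  tibble(
    group = x$group %||% NA_character_,
    motif_type = motif_levels,
    balance = ifelse(grepl("^balanced", motif_levels), "balanced", "unbalanced"),
    n = unname(as.integer(x$counts[motif_levels])),
    fraction = if (x$n_triangles > 0) {
      unname(x$counts[motif_levels] / x$n_triangles)
    } else {
      rep(NA_real_, 4L)
    }
  )
}

#' @export
glance.motif_census <- function(x, ...) {
  tibble(
    group = x$group %||% NA_character_,
    alpha = x$alpha,
    n_triangles = x$n_triangles,
    n_balanced = x$n_balanced,
    n_unbalanced = x$n_unbalanced,
    fraction_balanced = x$p_bm,
    fraction_unbalanced = x$p_um,
    p_um = x$p_um
  )
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("# motif_census [group '%s', p < %g]: %d triangles\n",
              x$group %||% "?", x$alpha, x$n_triangles))
  if (x$n_triangles > 0) {
    cat(sprintf("#   balanced   %.3f  (I: %d, II: %d)\n",
                x$p_bm, x$counts[["balanced_I"]], x$counts[["balanced_II"]]))
    cat(sprintf("#   unbalanced %.3f  (I: %d, II: %d)\n",
                x$p_um, x$counts[["unbalanced_I"]], x$counts[["unbalanced_II"]]))
  } else {
    cat("#   no triangles; fractions undefined\n")
  }
  invisible(x)
}
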