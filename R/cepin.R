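#' Pearson correlation with regression-F significance
#'
#' Computes the sample Pearson correlation of two expression profiles and its
#' two-sided significance from the simple-regression overall F statistic,
#' \eqn{F = t^2} with \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{(1, n-2)}
#' degrees of freedom — identical to the two-sided t-test for a correlation.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return A list with elements `r`, `p` and `n`.
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3L) abort("correlation significance needs n >= 3 (df = n - 2 >= 1).")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("values must be finite.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: zero variance input",
          class = "cepinet_undefined_correlation")
  }
  r <- cor(x, y)
  list(r = r, p = cor_pvalue(r, n), n = n)
}

# two-sided p for Pearson r via F = t^2 on (1, n-2) df; |r| = 1 -> 0
cor_pvalue <- function(r, n) {
  r2 <- pmin(r * r, 1)
  p <- ifelse(r2 >= 1, 0,
              pf(r2 * (n - 2) / (1 - r2), 1, n - 2, lower.tail = FALSE))
  as.numeric(p)
}

#' Build a co-expressed protein interaction network (CePIN) for one group
#'
#' Restricts the interaction network to genes present in the (already
#' expression-filtered) matrix, then annotates every surviving edge with the
#' Pearson correlation of its endpoint genes across the selected group's
#' samples, the edge weight \eqn{w_{ij} = (1 + \mathrm{PCC}_{ij})/2 \in [0,1]},
#' and the correlation's F-test p-value. Edges touching a gene that is
#' constant within the group carry no co-expression evidence and are dropped
#' (their count is recorded in the `dropped_undefined` attribute).
#'
#' @param net an [as_interaction_network()] scaffold.
#' @param expr an [expression_set()], typically after
#'   [filter_expressed_genes()].
#' @param group metadata group label selecting at least 3 samples.
#' @param transform value transform applied before correlation: `"log2p1"`
#'   (\eqn{\log_2(x+1)}, the default for count-like RNA-Seq values) or
#'   `"none"` (for already-log microarray intensities).
#' @return A tibble of class `cepin` with columns `gene_a`, `gene_b`, `pcc`,
#'   `weight`, `pvalue`; attributes `group`, `n_samples`, `transform`,
#'   `nodes`, and `dropped_undefined`.
#' @export
build_cepin <- function(net, expr, group, transform = c("log2p1", "none")) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(expr, "expression_set"))
  transform <- match.arg(transform)
  samples <- group_samples(expr, group)
  n <- length(samples)
  if (n < 3L) {
    abort(sprintf("group '%s' has %d sample(s); >= 3 are required.", group, n))
  }
  sub <- induce_subgraph(net, rownames(expr$values))
  v <- expr$values[, samples, drop = FALSE]
  if (transform == "log2p1") v <- log2(v + 1)
  edges <- as_tibble(sub)[, c("gene_a", "gene_b")]
  if (!nrow(edges)) {
    return(new_cepin(edges[, c("gene_a", "gene_b")],
                     pcc = numeric(0), n = n, group = group,
                     transform = transform, nodes = network_nodes(sub),
                     dropped = 0L))
  }
  mu <- rowMeans(v)
  cv <- v - mu
  ss <- sqrt(rowSums(cv * cv))
  ok <- ss > 0
  z <- cv / ifelse(ok, ss, 1)        # unit-norm centered profiles
  defined <- ok[edges$gene_a] & ok[edges$gene_b]
  dropped <- sum(!defined)
  if (dropped) {
    inform(sprintf(
      "build_cepin('%s'): dropped %d edge(s) with undefined correlation (constant gene in group)",
      group, dropped
    ))
  }
  edges <- edges[defined, ]
  r <- unname(rowSums(z[edges$gene_a, , drop = FALSE] *
                        z[edges$gene_b, , drop = FALSE]))
  r <- pmin(pmax(r, -1), 1)
  new_cepin(edges, pcc = r, n = n, group = group, transform = transform,
            nodes = network_nodes(sub), dropped = dropped)
}

new_cepin <- function(edges, pcc, n, group, transform, nodes, dropped,
                      alpha = NULL) {
  out <- tibble(
    gene_a = edges$gene_a,
    gene_b = edges$gene_b,
    pcc = pcc,
    weight = (1 + pcc) / 2,
    pvalue = if (length(pcc)) cor_pvalue(pcc, n) else numeric(0)
  )
  attr(out, "group") <- group
  attr(out, "n_samples") <- n
  attr(out, "transform") <- transform
  attr(out, "nodes") <- nodes
  attr(out, "dropped_undefined") <- dropped
  attr(out, "alpha") <- alpha
  class(out) <- c("cepin", class(tibble()))
  out
}

#' Significance-filtered CePIN
#'
#' Retains edges whose co-expression p-value is strictly below `alpha`
#' (p-values exactly at `alpha` are removed); the node set shrinks to the
#' endpoints of surviving edges. This is the filter applied before the
#' signed-motif census; entropy profiles use the full, unfiltered CePIN.
#'
#' @param cepin a [build_cepin()] result.
#' @param alpha significance threshold in `(0, 1]`; default 0.05.
#' @return A `cepin` with the filter recorded in the `alpha` attribute.
#' @export
significant_subnetwork <- function(cepin, alpha = 0.05) {
  stopifnot(inherits(cepin, "cepin"))
  stopifnot_scalar_number(alpha, "alpha", 0, 1, lower_open = TRUE)
  keep <- cepin$pvalue < alpha
  edges <- as_tibble(cepin)[keep, ]
  new_cepin(edges, pcc = edges$pcc, n = attr(cepin, "n_samples"),
            group = attr(cepin, "group"), transform = attr(cepin, "transform"),
            nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
            dropped = attr(cepin, "dropped_undefined"), alpha = alpha)
}

#' Read/write CePIN edge tables
#'
#' Serializes a CePIN as a TSV with columns `gene_a`, `gene_b`, `pcc`,
#' `weight`, `pvalue`, `n_samples`, `group`.
#'
#' @param cepin a `cepin`.
#' @param path file path.
#' @return `write_cepin()`: `path`, invisibly. `read_cepin()`: a `cepin`.
#' @export
write_cepin <- function(cepin, path) {
  stopifnot(inherits(cepin, "cepin"))
  tab <- as_tibble(cepin)
  tab$n_samples <- attr(cepin, "n_samples")
  tab$group <- attr(cepin, "group")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_cepin
#' @export
read_cepin <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ccdddic", progress = FALSE)
  need <- c("gene_a", "gene_b", "pcc", "weight", "pvalue", "n_samples", "group")
  if (!all(need %in% names(tab))) {
    abort(sprintf("'%s' is not a CePIN table (missing %s)", path,
                  paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  new_cepin(tab, pcc = tab$pcc, n = tab$n_samples[1L] %||% NA_integer_,
            group = tab$group[1L] %||% NA_character_, transform = NA_character_,
            nodes = sort(unique(c(tab$gene_a, tab$gene_b))), dropped = NA_integer_)
}

#' @export
print.cepin <- function(x, ...) {
  cat(sprintf(
    "# CePIN [group '%s']: %d nodes, %d weighted edges (n = %d samples%s)\n",
    attr(x, "group"), length(network_nodes(x)), nrow(x),
    attr(x, "n_samples"),
    if (!is.null(attr(x, "alpha"))) sprintf(", p < %g", attr(x, "alpha")) else ""
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
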