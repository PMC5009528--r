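#' Normalized local Shannon entropy of one gene's incident weights
#'
#' For a gene with \eqn{k \ge 2} neighbors and incident edge weights
#' \eqn{w_{ij} \ge 0} with positive total, the weight proportions are
#' \eqn{p_{ij} = w_{ij} / \sum_j w_{ij}} and the local entropy is
#' \deqn{S_i = -\frac{1}{\log k_i} \sum_{j \in N(i)} p_{ij} \log p_{ij},}
#' with the convention \eqn{0 \log 0 \equiv 0} (weights of exactly 0 arise
#' from perfectly anti-correlated pairs). Natural logarithms are used; the
#' base cancels in the ratio, so \eqn{S_i \in [0, 1]}: 1 for uniform incident
#' weights, 0 when all weight sits on a single neighbor.
#'
#' @param weights numeric vector of a gene's incident edge weights; its length
#'   is the gene's degree \eqn{k_i}, including zero-weight edges.
#' @return The entropy \eqn{S_i}, a number in `[0, 1]`.
#' @examples
#' local_entropy(c(0.4, 0.4, 0.4))  # uniform -> 1
#' local_entropy(c(1, 0))           # concentrated -> 0
#' @export
local_entropy <- function(weights) {
  k <- length(weights)
  if (k < 2L) {
    abort("undefined entropy: degree < 2 (log k = 0)",
          class = "cepinet_undefined_entropy")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("weights must be finite and non-negative.")
  }
  total <- sum(weights)
  if (total <= 0) {
    abort("undefined entropy: total incident weight is zero",
          class = "cepinet_undefined_entropy")
  }
  p <- weights / total
  s <- -sum(p[p > 0] * log(p[p > 0])) / log(k)
  min(max(s, 0), 1)
}

#' Per-gene entropy profile of a CePIN
#'
#' Computes the normalized local entropy of every eligible gene on the full
#' CePIN (no significance filtering — that filter belongs to the motif
#' census). A gene is eligible when its CePIN degree is at least 2 and its
#' incident weights do not all vanish; ineligible genes are listed with
#' reasons in the `excluded` attribute. Summary statistics (mean, SD, SEM,
#' median, n) are available via [glance()].
#'
#' @param cepin a [build_cepin()] result.
#' @return A tibble of class `entropy_profile` with columns `gene`, `degree`,
#'   `entropy`, plus attributes `group` and `excluded`.
#' @export
entropy_profile <- function(cepin) {
  stopifnot(inherits(cepin, "cepin"))
  if (!nrow(cepin)) abort("cannot profile an empty CePIN (no edges).")
  incident <- bind_rows(
    tibble(gene = cepin$gene_a, weight = cepin$weight),
    tibble(gene = cepin$gene_b, weight = cepin$weight)
  )
  per_gene <- incident %>%
    group_by(.data$gene) %>%
    summarise(
      degree = dplyr::n(),
      total = sum(.data$weight),
      plogp = {
        p <- .data$weight[.data$weight > 0] / sum(.data$weight)
        if (length(p)) sum(p * log(p)) else 0
      },
      .groups = "drop"
    )
  eligible <- per_gene$degree >= 2L & per_gene$total > 0
  prof <- per_gene[eligible, ] %>%
    mutate(entropy = pmin(pmax(-.data$plogp / log(.data$degree), 0), 1)) %>%
    select("gene", "degree", "entropy") %>%
    arrange(.data$gene)
  isolated <- setdiff(network_nodes(cepin), per_gene$gene)
  excluded <- bind_rows(
    tibble(gene = per_gene$gene[per_gene$degree < 2L], reason = "degree_lt_2"),
    tibble(gene = per_gene$gene[per_gene$degree >= 2L & per_gene$total <= 0],
           reason = "zero_total_weight"),
    tibble(gene = isolated, reason = "no_edges")
  )
  out <- new_tibble(prof, class = "entropy_profile")
  attr(out, "group") <- attr(cepin, "group")
  attr(out, "excluded") <- excluded
  out
}

#' Restrict an entropy profile to a gene set
#'
#' Used for entropy analyses of curated sets (significantly mutated genes,
#' Cancer Gene Census, oncogenes, tumor suppressors, drug-sensitivity genes).
#' Set members missing from the profile — absent from the CePIN or ineligible
#' for entropy — are counted and reported.
#'
#' @param profile an [entropy_profile()].
#' @param gene_set character vector of gene symbols.
#' @param set_name optional label carried into reports.
#' @return An `entropy_profile` restricted to `gene_set`.
#' @export
gene_set_profile <- function(profile, gene_set, set_name = NULL) {
  stopifnot(inherits(profile, "entropy_profile"))
  gene_set <- unique(trimws(as.character(gene_set)))
  hit <- profile$gene %in% gene_set
  if (!any(hit)) {
    abort(sprintf(
      "gene set%s has 0 of %d member(s) in the %d-gene entropy profile",
      if (is.null(set_name)) "" else sprintf(" '%s'", set_name),
      length(gene_set), nrow(profile)
    ))
  }
  out <- new_tibble(as_tibble(profile)[hit, ], class = "entropy_profile")
  attr(out, "group") <- attr(profile, "group")
  attr(out, "excluded") <- attr(profile, "excluded")
  attr(out, "gene_set") <- list(
    name = set_name, size = length(gene_set),
    profiled = sum(hit), absent = length(gene_set) - sum(hit)
  )
  out
}

#' @export
glance.entropy_profile <- function(x, ...) {
  tibble(
    group = attr(x, "group") %||% NA_character_,
    n_genes = nrow(x),
    mean_entropy = mean(x$entropy),
    sd_entropy = sd(x$entropy),
    sem_entropy = sd(x$entropy) / sqrt(nrow(x)),
    median_entropy = median(x$entropy)
  )
}

#' Write a per-gene entropy table
#'
#' TSV with columns `gene`, `degree`, `entropy`, `group`.
#'
#' @param profile an `entropy_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_entropy_profile <- function(profile, path) {
  stopifnot(inherits(profile, "entropy_profile"))
  tab <- as_tibble(profile)
  tab$group <- attr(profile, "group") %||% NA_character_
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @export
print.entropy_profile <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "# entropy_profile [group '%s']: %d genes, mean S = %.4f +/- %.4f (SEM), median %.4f\n",
    g$group, g$n_genes, g$mean_entropy, g$sem_entropy, g$median_entropy
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
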