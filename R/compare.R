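#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin wrapper around [stats::wilcox.test()] with the conventions used for
#' all distributional contrasts here: exact null distribution when the
#' smaller sample has at most 8 values and the pooled data are tie-free,
#' otherwise the normal approximation with tie and continuity correction.
#' When every pooled value is identical the test is vacuous: the p-value is
#' 1, with a warning.
#'
#' @param values_a,values_b numeric vectors (finite, each nonempty).
#' @return A list with `statistic` (the Mann-Whitney U of `values_a`),
#'   `pvalue`, and `method`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    abort("both groups must be nonempty.")
  }
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    abort("values must be finite.")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    warn("all values identical across both groups; rank-sum test is vacuous (p = 1)")
    return(list(statistic = length(values_a) * length(values_b) / 2,
                pvalue = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- min(length(values_a), length(values_b)) <= 8L && !ties
  ht <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided",
                exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), pvalue = min(ht$p.value, 1),
       method = if (exact) "exact" else "normal approximation")
}

median_direction <- function(a, b, label_a, label_b) {
  d <- median(b) - median(a)
  if (d > 0) label_b else if (d < 0) label_a else "none"
}

#' Contrast two CePINs: entropy distributions and motif ratios
#'
#' The genome-wide contrast runs an unpaired two-sided Wilcoxon rank-sum test
#' on the two per-gene entropy vectors, computed on the full (unfiltered)
#' CePINs — genes eligible in only one CePIN stay in their own group's
#' vector, matching pooled boxplot comparisons. The signed-motif censuses of
#' both groups (computed on the `alpha_motif`-filtered CePINs) are attached,
#' together with the difference in unbalanced-motif ratio. Each supplied gene
#' set is contrasted the same way on the restricted entropy profiles.
#'
#' @param cepin_a,cepin_b CePINs built on the same scaffold and filtered gene
#'   universe.
#' @param gene_sets optional named list of gene-symbol vectors.
#' @param alpha_motif significance threshold for the motif censuses.
#' @param paired if `TRUE`, run a Wilcoxon signed-rank test on genes shared
#'   by both profiles instead of the unpaired rank-sum (non-default
#'   alternative for matched designs).
#' @return A `cepin_comparison` object; [tidy()] flattens it to one row per
#'   contrast (genome-wide plus each gene set), [glance()] to the genome-wide
#'   row.
#' @export
compare_groups <- function(cepin_a, cepin_b, gene_sets = NULL,
                           alpha_motif = 0.05, paired = FALSE) {
  stopifnot(inherits(cepin_a, "cepin"), inherits(cepin_b, "cepin"))
  prof_a <- entropy_profile(cepin_a)
  prof_b <- entropy_profile(cepin_b)
  census_a <- motif_census(cepin_a, alpha_motif)
  census_b <- motif_census(cepin_b, alpha_motif)
  label_a <- attr(cepin_a, "group") %||% "a"
  label_b <- attr(cepin_b, "group") %||% "b"
  contrasts <- c(
    list(genome_wide = list(a = prof_a, b = prof_b)),
    if (!is.null(gene_sets)) {
      purrr::imap(gene_sets, function(set, nm) {
        list(a = gene_set_profile(prof_a, set, nm),
             b = gene_set_profile(prof_b, set, nm))
      })
    }
  )
  rows <- purrr::imap(contrasts, function(pr, nm) {
    ea <- pr$a$entropy
    eb <- pr$b$entropy
    test <- if (paired) {
      shared <- intersect(pr$a$gene, pr$b$gene)
      if (!length(shared)) abort("paired mode: no shared genes between profiles.")
      da <- ea[match(shared, pr$a$gene)]
      db <- eb[match(shared, pr$b$gene)]
      ht <- suppressWarnings(wilcox.test(da, db, paired = TRUE))
      list(statistic = unname(ht$statistic), pvalue = ht$p.value,
           method = "signed-rank (paired)")
    } else {
      wilcoxon_rank_sum(ea, eb)
    }
    tibble(
      contrast = nm,
      group_a = label_a, group_b = label_b,
      n_a = length(ea), n_b = length(eb),
      mean_a = mean(ea), sem_a = sd(ea) / sqrt(length(ea)),
      median_a = median(ea),
      mean_b = mean(eb), sem_b = sd(eb) / sqrt(length(eb)),
      median_b = median(eb),
      statistic = test$statistic, pvalue = test$pvalue,
      direction = median_direction(ea, eb, label_a, label_b)
    )
  })
  structure(
    list(
      group_a = label_a, group_b = label_b,
      contrasts = bind_rows(rows),
      profile_a = prof_a, profile_b = prof_b,
      census_a = census_a, census_b = census_b,
      p_um_a = census_a$p_um, p_um_b = census_b$p_um,
      p_um_diff = census_b$p_um - census_a$p_um,
      alpha_motif = alpha_motif,
      paired = paired
    ),
    class = "cepin_comparison"
  )
}

#' @export
tidy.cepin_comparison <- function(x, ...) {
  mutate(x$contrasts,
         p_um_a = x$p_um_a, p_um_b = x$p_um_b, p_um_diff = x$p_um_diff)
}

#' @export
glance.cepin_comparison <- function(x, ...) {
  tidy(x)[x$contrasts$contrast == "genome_wide", ]
}

#' @export
print.cepin_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("# CePIN contrast: '%s' (n = %d genes) vs '%s' (n = %d genes)\n",
              x$group_a, g$n_a, x$group_b, g$n_b))
  cat(sprintf("#   median entropy  %.4f vs %.4f  (rank-sum p = %.3g, higher: %s)\n",
              g$median_a, g$median_b, g$pvalue, g$direction))
  cat(sprintf("#   p_um            %.3f vs %.3f  (difference %+0.3f, p < %g edges)\n",
              x$p_um_a, x$p_um_b, x$p_um_diff, x$alpha_motif))
  if (nrow(x$contrasts) > 1L) {
    cat("# gene-set contrasts:\n")
    print(x$contrasts[x$contrasts$contrast != "genome_wide", ], ...)
  }
  invisible(x)
}
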