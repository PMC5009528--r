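# presentation helpers; analyses never depend on these

#' Plot an entropy profile
#'
#' Histogram of per-gene local network entropy.
#'
#' @param object an [entropy_profile()].
#' @param bins histogram bins.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.entropy_profile <- function(object, bins = 40, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$entropy)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(
      x = expression(S[i]),
      y = "genes",
      title = sprintf("Local network entropy [%s]",
                      attr(object, "group") %||% "")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a motif census
#'
#' Bar chart of the four signed-triangle motif fractions.
#'
#' @param object a [motif_census()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.motif_census <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$motif_type, y = .data$fraction,
                               fill = .data$balance)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(balanced = "#2166ac",
                                          unbalanced = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "fraction of triangles",
                  title = sprintf("Signed motifs [%s]", object$group %||% "")) +
    ggplot2::theme_minimal()
}

#' Boxplot of entropy distributions for a group contrast
#'
#' Mirrors the conventional tumor-versus-normal entropy boxplots.
#'
#' @param object a [compare_groups()] result.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.cepin_comparison <- function(object, ...) {
  df <- bind_rows(
    tibble(group = object$group_a, entropy = object$profile_a$entropy),
    tibble(group = object$group_b, entropy = object$profile_b$entropy)
  )
  g <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$entropy)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(
      x = NULL, y = expression(S[i]),
      title = "Genome-wide local network entropy",
      subtitle = sprintf("Wilcoxon rank-sum p = %.3g", g$pvalue)
    ) +
    ggplot2::theme_minimal()
}
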