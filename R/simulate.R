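#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' sparse interactome with dense, triangle-rich modules, and two expression
#' cohorts driven by per-module latent factors. In the `coherent`
#' ("normal-like") cohort the factor loading is strong, so module edges carry
#' concentrated, strongly-signed correlations (low entropy, mostly balanced
#' triangles); in the `degraded` ("tumor-like") cohort the loading is weak,
#' correlations shrink toward 0, edge weights toward 1/2, and entropy rises
#' while more mixed-sign triangles appear.
#'
#' @param n_genes number of genes (`>= 10`); default 300.
#' @param n_samples_per_group samples per cohort; default 60.
#' @param network_model background wiring between/outside modules:
#'   `"erdos_renyi"` (each non-module pair independently with
#'   `background_density`) or `"barabasi_albert"` (preferential-attachment
#'   backbone with power `attachment_power`).
#' @param background_density edge probability of the Erdős–Rényi background;
#'   default 0.01.
#' @param attachment_power preferential-attachment exponent; default 1.
#' @param n_modules,module_size module count and size
#'   (`n_modules * module_size <= n_genes`); defaults 10 and 24.
#' @param within_module_density edge probability inside a module; default 0.5.
#' @param loading_coherent,loading_degraded latent-factor loadings of the two
#'   cohorts, `0 <= loading_degraded <= loading_coherent < 1`; defaults 0.8
#'   and 0.3. Within-module correlations scale as
#'   \eqn{\lambda^2/(\lambda^2+\sigma^2)} in magnitude.
#' @param negative_fraction probability that a module gene loads negatively
#'   on its factor (creates signed co-expression structure); default 0.3.
#' @param noise_sd residual standard deviation \eqn{\sigma}; default 0.25.
#'   The default keeps the degraded cohort's strongest within-module
#'   correlations (\eqn{0.09/(0.09+\sigma^2) \approx 0.59}) comfortably above
#'   twice the correlation detectable at p < 0.05 with 60 samples
#'   (\eqn{\approx 0.25}) — a geometric requirement for mixed-sign triangles
#'   to survive the significance filter at all (see the methods vignette).
#' @param baseline_expression non-negative offset added before clipping at 0;
#'   default 5.
#' @param seed integer master seed; the network and each cohort use
#'   independent streams derived from it, so adding a cohort never perturbs
#'   the network.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 300L,
                             n_samples_per_group = 60L,
                             network_model = c("erdos_renyi", "barabasi_albert"),
                             background_density = 0.01,
                             attachment_power = 1,
                             n_modules = 10L,
                             module_size = 24L,
                             within_module_density = 0.5,
                             loading_coherent = 0.8,
                             loading_degraded = 0.3,
                             negative_fraction = 0.3,
                             noise_sd = 0.25,
                             baseline_expression = 5,
                             seed = 1L) {
  network_model <- match.arg(network_model)
  stopifnot_scalar_number(n_genes, "n_genes", 10, Inf)
  stopifnot_scalar_number(n_samples_per_group, "n_samples_per_group", 3, Inf)
  stopifnot_scalar_number(background_density, "background_density", 0, 1)
  stopifnot_scalar_number(within_module_density, "within_module_density", 0, 1)
  stopifnot_scalar_number(loading_coherent, "loading_coherent", 0, 1,
                          upper_open = TRUE)
  stopifnot_scalar_number(loading_degraded, "loading_degraded", 0, 1,
                          upper_open = TRUE)
  stopifnot_scalar_number(negative_fraction, "negative_fraction", 0, 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0, Inf, lower_open = TRUE)
  stopifnot_scalar_number(baseline_expression, "baseline_expression", 0, Inf)
  if (loading_degraded > loading_coherent) {
    abort("`loading_degraded` must not exceed `loading_coherent`.")
  }
  if (n_modules * module_size > n_genes) {
    abort("`n_modules * module_size` must not exceed `n_genes`.")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_samples_per_group = as.integer(n_samples_per_group),
      network_model = network_model,
      background_density = background_density,
      attachment_power = attachment_power,
      n_modules = as.integer(n_modules),
      module_size = as.integer(module_size),
      within_module_density = within_module_density,
      loading_coherent = loading_coherent,
      loading_degraded = loading_degraded,
      negative_fraction = negative_fraction,
      noise_sd = noise_sd,
      baseline_expression = baseline_expression,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# independent RNG streams derived from the master seed (kept below 2^31)
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) + stream * 1000003) %% 2147483647)
}

#' Generate a modular synthetic interactome
#'
#' Module genes are wired densely within their module (so triangles exist
#' inside modules) and the remaining pairs follow the configured background
#' model. Module membership and each gene's factor-loading sign are annotated
#' on the network (attributes `modules` and `signs`) so that expression
#' generation for any number of cohorts reuses the same architecture.
#'
#' @param cfg a [synthetic_config()].
#' @return An `interaction_network` with `modules` (named integer, `NA` for
#'   background genes) and `signs` (named, +1/-1) attributes.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  module <- rep(NA_integer_, cfg$n_genes)
  module[seq_len(cfg$n_modules * cfg$module_size)] <-
    rep(seq_len(cfg$n_modules), each = cfg$module_size)
  names(module) <- genes
  withr::with_seed(derive_seed(cfg$seed, 0), {
    signs <- setNames(
      ifelse(stats::runif(cfg$n_genes) < cfg$negative_fraction, -1, 1),
      genes
    )
    within <- purrr::map(seq_len(cfg$n_modules), function(m) {
      members <- genes[which(module == m)]
      pairs <- t(combn(members, 2L))
      keep <- stats::runif(nrow(pairs)) < cfg$within_module_density
      tibble(gene_a = pairs[keep, 1L], gene_b = pairs[keep, 2L])
    })
    background <- if (cfg$network_model == "erdos_renyi") {
      pairs <- t(combn(genes, 2L))
      ma <- module[pairs[, 1L]]
      mb <- module[pairs[, 2L]]
      same_module <- !is.na(ma) & !is.na(mb) & ma == mb
      candidates <- pairs[!same_module, , drop = FALSE]
      keep <- stats::runif(nrow(candidates)) < cfg$background_density
      tibble(gene_a = candidates[keep, 1L], gene_b = candidates[keep, 2L])
    } else {
      g <- igraph::sample_pa(cfg$n_genes, power = cfg$attachment_power,
                             directed = FALSE)
      el <- igraph::as_edgelist(g, names = FALSE)
      tibble(gene_a = genes[el[, 1L]], gene_b = genes[el[, 2L]])
    }
    edges <- bind_rows(c(within, list(background)))
  })
  if (!nrow(edges)) abort("configuration produced an empty edge set.")
  net <- as_interaction_network(edges, nodes = genes)
  attr(net, "modules") <- module
  attr(net, "signs") <- signs
  net
}

#' Generate one cohort's expression matrix on a synthetic interactome
#'
#' Each module carries a two-dimensional latent program: per sample, two
#' independent standard-normal factors \eqn{f_1, f_2} are drawn for every
#' module, and gene \eqn{g} of module \eqn{m} sits at an angle \eqn{\theta_g}
#' in that program plane, taking the value
#' \deqn{x_g = \mathrm{baseline} + \lambda (\cos\theta_g f_{1m} +
#'   \sin\theta_g f_{2m}) + \varepsilon, \quad
#'   \varepsilon \sim N(0, \mathrm{noise\_sd}),}
#' where \eqn{\lambda} is the cohort's loading. In the `coherent` cohort
#' every gene lies on the primary axis (\eqn{\theta_g = 0} or \eqn{\pi} by
#' its annotated sign \eqn{s_g}), so the model reduces to
#' \eqn{\mathrm{baseline} + s_g \lambda f_{1m} + \varepsilon} and
#' within-module correlations are strong with signs \eqn{s_g s_h} —
#' concentrated weights, balanced triangles. In the `degraded` cohort the
#' angles are jittered by \eqn{\delta \cdot U(-\pi, \pi)} with dispersion
#' \eqn{\delta = 1 - \lambda_{deg}/\lambda_{coh}}: correlations
#' (\eqn{\propto \lambda^2 \cos(\theta_g - \theta_h)}) shrink and their signs
#' lose the product structure, so mixed-sign, unbalanced triangles appear —
#' the loss of one coherent program per module is what the single knob
#' \eqn{\lambda} degrades. When the two loadings are equal, \eqn{\delta = 0}
#' and both cohorts are generated by an identical process.
#'
#' Background genes are pure noise. Values are clipped at 0. The result is
#' fully determined by the configuration, its seed, and the cohort name.
#'
#' @param net a [generate_network()] result (carries module annotations).
#' @param cfg the same [synthetic_config()].
#' @param group `"coherent"` or `"degraded"`.
#' @return An [expression_set()] whose samples are labelled with `group`.
#' @export
generate_expression <- function(net, cfg, group = c("coherent", "degraded")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  group <- match.arg(group)
  module <- attr(net, "modules")
  signs <- attr(net, "signs")
  if (is.null(module) || is.null(signs)) {
    abort("`net` lacks module annotations; use generate_network().")
  }
  lambda <- switch(group,
                   coherent = cfg$loading_coherent,
                   degraded = cfg$loading_degraded)
  dispersion <- if (group == "degraded" && cfg$loading_coherent > 0) {
    1 - cfg$loading_degraded / cfg$loading_coherent
  } else {
    0
  }
  genes <- names(module)
  n_s <- cfg$n_samples_per_group
  vals <- withr::with_seed(
    derive_seed(cfg$seed, match(group, c("coherent", "degraded"))),
    {
      theta <- ifelse(signs > 0, 0, pi) +
        dispersion * stats::runif(length(genes), -pi, pi)
      f1 <- matrix(rnorm(cfg$n_modules * n_s), cfg$n_modules, n_s)
      f2 <- matrix(rnorm(cfg$n_modules * n_s), cfg$n_modules, n_s)
      noise <- matrix(rnorm(length(genes) * n_s, sd = cfg$noise_sd),
                      length(genes), n_s)
      signal <- matrix(0, length(genes), n_s)
      in_mod <- !is.na(module)
      signal[in_mod, ] <- lambda *
        (cos(theta[in_mod]) * f1[module[in_mod], , drop = FALSE] +
         sin(theta[in_mod]) * f2[module[in_mod], , drop = FALSE])
      pmax(cfg$baseline_expression + signal + noise, 0)
    }
  )
  rownames(vals) <- genes
  colnames(vals) <- sprintf("%s_s%03d", group, seq_len(n_s))
  expression_set(
    vals,
    tibble(sample_id = colnames(vals), group = group)
  )
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the exact files the pipeline consumes: `network.tsv` (edge list),
#' `expression.tsv` (both cohorts, genes in rows), `metadata.tsv`
#' (`sample_id`, `group`), `modules.tsv` (gene, module, loading sign), and
#' `config.yaml` (the resolved configuration, for provenance) — 5 files.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @param force overwrite existing files; without it, an existing target file
#'   is an error.
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_dataset <- function(cfg, dir, force = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "network.tsv"),
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    modules = file.path(dir, "modules.tsv"),
    config = file.path(dir, "config.yaml")
  )
  clash <- paths[file.exists(paths)]
  if (length(clash) && !force) {
    abort(sprintf("output file exists (use force = TRUE): %s", clash[[1L]]))
  }
  net <- generate_network(cfg)
  coh <- generate_expression(net, cfg, "coherent")
  deg <- generate_expression(net, cfg, "degraded")
  write_network(net, paths[["network"]])
  values <- cbind(coh$values, deg$values)
  samples <- bind_rows(coh$samples, deg$samples)
  write_expression(expression_set(values, samples),
                   paths[["expression"]], paths[["metadata"]])
  readr::write_tsv(
    tibble(gene = names(attr(net, "modules")),
           module = attr(net, "modules"),
           loading_sign = as.integer(attr(net, "signs"))),
    paths[["modules"]]
  )
  yaml::write_yaml(unclass(cfg), paths[["config"]])
  invisible(paths)
}
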