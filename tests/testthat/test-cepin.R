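test_that("pearson_with_p reproduces hand-computed values", {
  # perfect correlation
  res <- pearson_with_p(c(1, 2, 3, 5), c(1, 2, 3, 5))
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  # r = 0.8 by hand: cov terms 4, centered norms sqrt(5) each
  res <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  t <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p, 2 * stats::pt(-t, df = 2))
  expect_equal(res$p, stats::pf(t^2, 1, 2, lower.tail = FALSE))
})

test_that("degenerate correlation inputs raise the documented conditions", {
  expect_error(pearson_with_p(1:2, 2:3), "n >= 3")
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)),
               class = "cepinet_undefined_correlation")
  expect_error(pearson_with_p(1:4, 1:3), "equal length")
})

test_that("F-test p-values track an exhaustive permutation oracle at small n", {
  cases <- withr::with_seed(21, {
    lapply(1:6, function(i) list(x = rnorm(6), y = rnorm(6)))
  })
  for (cs in cases) {
    p_f <- pearson_with_p(cs$x, cs$y)$p
    p_perm <- oracle_perm_pvalue(cs$x, cs$y)
    # the F p-value approximates the exact permutation null at df = 4
    expect_lt(abs(p_f - p_perm), 0.05)
  }
})

test_that("build_cepin reproduces a brute-force per-edge correlation loop", {
  cfg <- synthetic_config(n_genes = 40, n_modules = 2, module_size = 12,
                          n_samples_per_group = 20, seed = 9)
  sim <- simulate_contrast(cfg)
  cep <- sim$coherent
  v <- log2(sim$expr$values[, group_samples(sim$expr, "coherent")] + 1)
  for (i in seq_len(nrow(cep))) {
    res <- pearson_with_p(v[cep$gene_a[i], ], v[cep$gene_b[i], ])
    expect_equal(cep$pcc[i], res$r, tolerance = 1e-12)
    expect_equal(cep$pvalue[i], res$p, tolerance = 1e-12)
    expect_equal(cep$weight[i], (1 + res$r) / 2, tolerance = 1e-12)
  }
})

test_that("perfectly anti-correlated genes get weight 0; constant genes drop out", {
  net <- as_interaction_network(
    data.frame(a = c("up", "up", "down"), b = c("down", "flat", "flat"))
  )
  x <- c(1, 2, 3, 4, 5)
  m <- rbind(up = x, down = 10 - x, flat = rep(2, 5))
  colnames(m) <- paste0("s", 1:5)
  es <- expression_set(m, tibble::tibble(sample_id = paste0("s", 1:5),
                                         group = "g"))
  expect_message(cep <- build_cepin(net, es, "g", transform = "none"),
                 "2 edge")
  expect_equal(nrow(cep), 1L)
  expect_equal(cep$pcc, -1)
  expect_equal(cep$weight, 0)
  expect_equal(attr(cep, "dropped_undefined"), 2L)
})

test_that("groups with fewer than 3 samples or unknown labels are rejected", {
  net <- as_interaction_network(data.frame(a = "A", b = "B"))
  m <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  es <- expression_set(m, tibble::tibble(sample_id = c("s1", "s2"), group = "g"))
  expect_error(build_cepin(net, es, "g"), ">= 3")
  expect_error(build_cepin(net, es, "nope"), "not present")
})

test_that("the weight map is a strictly increasing bijection with w(r)+w(-r)=1", {
  r <- seq(-1, 1, by = 0.125)
  cep <- make_test_cepin(sprintf("a%02d", seq_along(r)),
                         sprintf("b%02d", seq_along(r)), pcc = r)
  expect_equal(cep$weight + rev(cep$weight), rep(1, length(r)))
  expect_true(all(diff(cep$weight) > 0))
  expect_equal(cep$weight[r == 0], 0.5)
  expect_true(all(cep$weight >= 0 & cep$weight <= 1))
})

test_that("significance filtering is strict and validated", {
  cep <- make_test_cepin(c("A", "B", "C"), c("B", "C", "D"),
                         pcc = c(0.9, 0.5, 0.1), n = 10L)
  # manufacture an edge with p exactly at alpha
  alpha <- cep$pvalue[2]
  kept <- significant_subnetwork(cep, alpha)
  expect_false(any(kept$pvalue == alpha))
  expect_true(all(kept$pvalue < alpha))
  # alpha = 1 keeps every edge with finite t
  expect_equal(nrow(significant_subnetwork(cep, 1)), 3L)
  # node set shrinks to surviving endpoints
  expect_setequal(network_nodes(kept), c("A", "B"))
  expect_error(significant_subnetwork(cep, 0), "alpha")
  expect_error(significant_subnetwork(cep, 1.2), "alpha")
  # re-filter oracle on a random CePIN
  withr::with_seed(14, {
    cep2 <- make_test_cepin(sprintf("x%03d", 1:200), sprintf("y%03d", 1:200),
                            pcc = runif(200, -1, 1), n = 8L)
  })
  expect_equal(nrow(significant_subnetwork(cep2, 0.05)),
               sum(cep2$pvalue < 0.05))
})

test_that("CePIN tables round-trip through TSV", {
  cep <- make_test_cepin(c("A", "B"), c("B", "C"), pcc = c(0.4, -0.7),
                         n = 12L, group = "tumor")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cepin(cep, path)
  back <- read_cepin(path)
  expect_equal(back$pcc, cep$pcc)
  expect_equal(attr(back, "group"), "tumor")
  expect_equal(attr(back, "n_samples"), 12L)
})

test_that("null data produce ~5% significant edges (type-I calibration)", {
  n_edges <- 2500
  n_s <- 50
  withr::with_seed(77, {
    vals <- matrix(rexp(2 * n_edges * n_s, rate = 0.1), ncol = n_s)
  })
  rownames(vals) <- sprintf("g%05d", seq_len(2 * n_edges))
  colnames(vals) <- sprintf("s%02d", seq_len(n_s))
  net <- as_interaction_network(
    data.frame(a = rownames(vals)[seq(1, 2 * n_edges, 2)],
               b = rownames(vals)[seq(2, 2 * n_edges, 2)])
  )
  es <- expression_set(vals, tibble::tibble(sample_id = colnames(vals),
                                            group = "null"))
  cep <- build_cepin(net, es, "null", transform = "none")
  frac <- mean(cep$pvalue < 0.05)
  se <- sqrt(0.05 * 0.95 / n_edges)
  expect_lt(abs(frac - 0.05), 3 * se)
})
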