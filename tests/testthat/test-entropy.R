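test_that("local entropy hits its analytic endpoints and hand values", {
  expect_equal(local_entropy(c(0.4, 0.4, 0.4)), 1)
  expect_equal(local_entropy(c(1, 0)), 0)
  # k = 2, proportions (0.8, 0.2)
  expect_equal(local_entropy(c(0.8, 0.2)),
               -(0.8 * log(0.8) + 0.2 * log(0.2)) / log(2),
               tolerance = 1e-15)
  expect_equal(round(local_entropy(c(0.8, 0.2)), 5), 0.72193)
})

test_that("entropy eligibility rules raise typed conditions", {
  expect_error(local_entropy(0.7), class = "cepinet_undefined_entropy")
  expect_error(local_entropy(c(0, 0, 0)), class = "cepinet_undefined_entropy")
  expect_error(local_entropy(c(0.2, -0.1)), "non-negative")
})

test_that("entropy is invariant to positive rescaling of incident weights", {
  withr::with_seed(31, w <- runif(7))
  expect_equal(local_entropy(w), local_entropy(w * 123.4), tolerance = 1e-12)
})

test_that("a zero-weight edge changes k but not the plogp sum", {
  w <- c(0.3, 0.7)
  s2 <- local_entropy(w)
  s3 <- local_entropy(c(w, 0))
  expect_equal(s3, s2 * log(2) / log(3), tolerance = 1e-12)
})

test_that("shrinking all correlations toward zero weakly increases entropy", {
  withr::with_seed(32, {
    edges <- random_edge_table(30, 0.3, seed = 32)
    pcc <- runif(nrow(edges), -1, 1)
  })
  for (c_shrink in c(0.7, 0.3)) {
    p1 <- entropy_profile(make_test_cepin(edges$gene_a, edges$gene_b, pcc))
    p2 <- entropy_profile(make_test_cepin(edges$gene_a, edges$gene_b,
                                          pcc * c_shrink))
    shared <- intersect(p1$gene, p2$gene)
    expect_true(all(
      p2$entropy[match(shared, p2$gene)] >=
        p1$entropy[match(shared, p1$gene)] - 1e-12
    ))
  }
})

test_that("profiles match a brute-force per-node loop to 12 decimals", {
  withr::with_seed(33, {
    edges <- random_edge_table(60, 0.12, seed = 33)
    pcc <- runif(nrow(edges), -1, 1)
  })
  cep <- make_test_cepin(edges$gene_a, edges$gene_b, pcc)
  prof <- entropy_profile(cep)
  oracle <- oracle_entropy_profile(tibble::tibble(
    gene_a = cep$gene_a, gene_b = cep$gene_b, weight = cep$weight
  ))
  expect_equal(prof$gene, oracle$gene)
  expect_equal(prof$degree, oracle$degree)
  expect_equal(prof$entropy, oracle$entropy, tolerance = 1e-12)
})

test_that("uniform-weight CePINs give entropy exactly 1 with SEM 0", {
  edges <- tibble::tibble(gene_a = c("A", "A", "B", "C"),
                          gene_b = c("B", "C", "C", "D"))
  cep <- make_test_cepin(edges$gene_a, edges$gene_b, pcc = rep(0.5, 4))
  prof <- entropy_profile(cep)
  expect_equal(prof$entropy, rep(1, nrow(prof)), tolerance = 1e-12)
  g <- glance(prof)
  expect_equal(g$mean_entropy, 1, tolerance = 1e-12)
  expect_equal(g$sem_entropy, 0, tolerance = 1e-12)
})

test_that("star centers with one dominant weight score 0; leaves are excluded", {
  cep <- make_test_cepin(rep("HUB", 3), c("L1", "L2", "L3"),
                         pcc = c(1, -1, -1))  # weights 1, 0, 0
  prof <- entropy_profile(cep)
  expect_equal(prof$gene, "HUB")
  expect_equal(prof$entropy, 0)
  excluded <- attr(prof, "excluded")
  expect_setequal(excluded$gene[excluded$reason == "degree_lt_2"],
                  c("L1", "L2", "L3"))
})

test_that("all-anticorrelated nodes are excluded with zero_total_weight", {
  cep <- make_test_cepin(c("X", "X", "A"), c("A", "B", "B"),
                         pcc = c(-1, -1, 0.5))
  prof <- entropy_profile(cep)
  excluded <- attr(prof, "excluded")
  expect_true("X" %in% excluded$gene[excluded$reason == "zero_total_weight"])
  expect_false("X" %in% prof$gene)
})

test_that("gene-set restriction equals direct recomputation over the subset", {
  withr::with_seed(34, {
    edges <- random_edge_table(50, 0.15, seed = 34)
    pcc <- runif(nrow(edges), -1, 1)
  })
  prof <- entropy_profile(make_test_cepin(edges$gene_a, edges$gene_b, pcc))
  subset <- withr::with_seed(35, sample(prof$gene, nrow(prof) %/% 2))
  sub <- gene_set_profile(prof, subset, "half")
  expect_setequal(sub$gene, subset)
  expect_equal(glance(sub)$mean_entropy,
               mean(prof$entropy[prof$gene %in% subset]))
  # identity on all genes
  expect_equal(glance(gene_set_profile(prof, prof$gene)), glance(prof))
  # disjoint set errors with counts
  expect_error(gene_set_profile(prof, c("NOPE1", "NOPE2")), "0 of 2")
})
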