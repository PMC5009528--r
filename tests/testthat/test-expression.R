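write_expr_fixture <- function(values, meta) {
  mp <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  dp <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(tibble::as_tibble(values, rownames = "gene"), mp)
  readr::write_tsv(meta, dp)
  list(matrix = mp, metadata = dp)
}

test_that("expression loads with metadata matching and sample dropping", {
  m <- matrix(1:6, nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  meta <- tibble::tibble(sample_id = c("s1", "s2"), group = c("t", "n"))
  fx <- write_expr_fixture(m, meta)
  es <- read_expression(fx$matrix, fx$metadata)
  expect_equal(dim(es$values), c(3L, 2L))
  expect_equal(es$samples$group, c("t", "n"))

  # metadata missing one sample -> that column dropped with a warning
  fx2 <- write_expr_fixture(m, meta[1, ])
  expect_warning(es2 <- read_expression(fx2$matrix, fx2$metadata), "s2")
  expect_equal(dim(es2$values), c(3L, 1L))
})

test_that("duplicate genes and non-numeric cells are rejected with coordinates", {
  m <- matrix(1:4, nrow = 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  meta <- tibble::tibble(sample_id = c("s1", "s2"), group = "t")
  fx <- write_expr_fixture(m, meta)
  expect_error(read_expression(fx$matrix, fx$metadata), "duplicate gene")

  mp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\toops", "g2\t3\t4"), mp)
  dp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(meta, dp)
  err <- expect_error(read_expression(mp, dp))
  expect_match(conditionMessage(err), "g1")
  expect_match(conditionMessage(err), "s2")
})

test_that("expression values round-trip at full precision", {
  withr::with_seed(11, {
    m <- matrix(rexp(12) * 1000, nrow = 4,
                dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:3)))
  })
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:3), group = "t")
  es <- expression_set(m, meta)
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(es, mp, dp)
  back <- read_expression(mp, dp)
  expect_identical(back$values, es$values)
})

test_that("all-constant matrices lose every gene under the strict rule", {
  m <- matrix(7, nrow = 4, ncol = 3,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:3)))
  es <- expression_set(m, tibble::tibble(sample_id = sprintf("s%d", 1:3),
                                         group = "t"))
  expect_equal(nrow(filter_expressed_genes(es)$values), 0L)
})

test_that("retained genes match an explicit sort-and-interpolate quantile oracle", {
  vals <- c(1, 2, 3, 4, 5)
  m <- matrix(vals, ncol = 1, dimnames = list(sprintf("g%d", 1:5), "s1"))
  es <- expression_set(m, tibble::tibble(sample_id = "s1", group = "t"))
  kept <- rownames(filter_expressed_genes(es, 0.20, 0.20)$values)
  # oracle: linear interpolation between order statistics at probability 0.2
  srt <- sort(vals)
  h <- (length(vals) - 1) * 0.2
  q <- srt[floor(h) + 1] + (h - floor(h)) * (srt[floor(h) + 2] - srt[floor(h) + 1])
  expect_equal(kept, rownames(m)[vals > q])

  # a larger random sample against the same oracle
  withr::with_seed(3, x <- round(rexp(40) * 100, 1))
  m2 <- matrix(x, ncol = 1, dimnames = list(sprintf("g%02d", 1:40), "s1"))
  es2 <- expression_set(m2, tibble::tibble(sample_id = "s1", group = "t"))
  kept2 <- rownames(filter_expressed_genes(es2, 0.20, 0.20)$values)
  srt <- sort(x)
  h <- (length(x) - 1) * 0.2
  q2 <- srt[floor(h) + 1] + (h - floor(h)) * (srt[floor(h) + 2] - srt[floor(h) + 1])
  expect_equal(kept2, rownames(m2)[x > q2])
})

test_that("the expressed-in-enough-samples boundary is inclusive", {
  # 10 samples, min_sample_frac 0.2 -> expressed-in count must reach 2.
  # gene "hi" exceeds the per-sample quantile in exactly 2 samples,
  # gene "lo" in exactly 1.
  n_s <- 10
  base <- matrix(rep(c(1, 2, 3, 4, 5), n_s), nrow = 5)
  m <- rbind(base, hi = c(10, 10, rep(0, n_s - 2)), lo = c(10, rep(0, n_s - 1)))
  rownames(m) <- c(sprintf("g%d", 1:5), "hi", "lo")
  colnames(m) <- sprintf("s%02d", 1:n_s)
  es <- expression_set(m, tibble::tibble(sample_id = colnames(m), group = "t"))
  filt <- filter_expressed_genes(es, 0.20, 0.20)
  expressed <- attr(filt, "expressed")
  expect_equal(sum(expressed["hi", ]), 2L)
  expect_equal(sum(expressed["lo", ]), 1L)
  expect_true("hi" %in% rownames(filt$values))
  expect_false("lo" %in% rownames(filt$values))
})

test_that("filtering is monotone in min_sample_frac and never adds genes", {
  withr::with_seed(5, {
    m <- matrix(rexp(600) * 50, nrow = 60,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10)))
  })
  es <- expression_set(m, tibble::tibble(sample_id = colnames(m), group = "t"))
  fracs <- c(0.1, 0.2, 0.5, 0.9)
  kept <- lapply(fracs, function(f) rownames(filter_expressed_genes(es, 0.2, f)$values))
  for (i in seq_along(kept)) {
    expect_true(all(kept[[i]] %in% rownames(m)))
    if (i > 1) expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("filter parameters outside [0,1] are rejected", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  es <- expression_set(m, tibble::tibble(sample_id = c("s1", "s2"), group = "t"))
  expect_error(filter_expressed_genes(es, -0.1, 0.2), "sample_quantile")
  expect_error(filter_expressed_genes(es, 0.2, 1.5), "min_sample_frac")
})
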