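test_that("t-score handles null, separating, and degenerate features", {
  labels <- c(0, 0, 0, 1, 1, 1)
  # identical distribution in both classes
  expect_equal(t_score(c(1, 2, 3, 1, 2, 3), labels), 0)
  # zero variance in both classes, unequal means -> signed Inf sentinel
  expect_equal(t_score(c(0, 0, 0, 1, 1, 1), labels), -Inf)
  expect_equal(t_score(c(1, 1, 1, 0, 0, 0), labels), Inf)
  # zero variance, equal means -> 0
  expect_equal(t_score(rep(2, 6), labels), 0)
  expect_error(t_score(c(1, 2, 3), c(0, 0, 0)), "Both classes")
})

test_that("t-score matches textbook Welch and pooled formulas to 1e-10", {
  for (i in 1:100) {
    draw <- withr::with_seed(i, {
      n0 <- sample(3:12, 1); n1 <- sample(3:12, 1)
      list(z = rnorm(n0 + n1, sd = runif(1, 0.5, 3)),
           labels = sample(rep(c(0, 1), c(n0, n1))))
    })
    expect_equal(t_score(draw$z, draw$labels),
                 oracle_welch(draw$z, draw$labels), tolerance = 1e-10)
    expect_equal(t_score(draw$z, draw$labels, "pooled"),
                 oracle_pooled(draw$z, draw$labels), tolerance = 1e-10)
  }
})

test_that("t-score agrees with stats::t.test on both variants", {
  draw <- withr::with_seed(7, list(z = rnorm(30), labels = rep(c(0, 1), 15)))
  z0 <- draw$z[draw$labels == 0]; z1 <- draw$z[draw$labels == 1]
  expect_equal(t_score(draw$z, draw$labels),
               unname(t.test(z0, z1)$statistic), tolerance = 1e-12)
  expect_equal(t_score(draw$z, draw$labels, "pooled"),
               unname(t.test(z0, z1, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("|t| is invariant under label swap (t negates)", {
  draw <- withr::with_seed(5, list(z = rnorm(24), labels = rep(c(0, 1), 12)))
  t1 <- t_score(draw$z, draw$labels)
  t2 <- t_score(draw$z, 1 - draw$labels)
  expect_equal(t1, -t2)
})

test_that("a two-gene matrix yields exactly one pair regardless of top_n", {
  ds <- make_expr(m = 2, n = 10, seed = 1)
  expect_warning(res <- scan_pairs(ds, "abs", top_n = 5), "exceeds")
  expect_equal(nrow(res), 1)
  expect_equal(res$rank, 1L)
})

test_that("blockwise scan equals the double-loop brute force for all conversions", {
  ds <- make_expr(m = 12, n = 20, seed = 17)
  r <- rank_transform(ds)
  for (conv in c("sum", "diff", "mul", "sign", "abs")) {
    res <- scan_pairs(r, conv, top_n = 5)
    ref <- oracle_scan(r, conv, 5)
    expect_equal(res$gene_p, rownames(r$ranks)[ref$p], info = conv)
    expect_equal(res$gene_q, rownames(r$ranks)[ref$q], info = conv)
    expect_equal(res$t_score, ref$t, info = conv)
  }
})

test_that("scan output is independent of block size", {
  ds <- make_expr(m = 15, n = 18, seed = 23)
  r <- rank_transform(ds)
  a <- scan_pairs(r, "abs", top_n = 8, block_size = 1)
  b <- scan_pairs(r, "abs", top_n = 8, block_size = 3)
  c <- scan_pairs(r, "abs", top_n = 8, block_size = 512)
  expect_identical(tidy(a), tidy(b))
  expect_identical(tidy(a), tidy(c))
})

test_that("abs scan is invariant under reversing gene order", {
  ds <- make_expr(m = 10, n = 16, seed = 31)
  rev_ds <- expression_dataset(ds$values[nrow(ds$values):1, ], ds$labels)
  a <- scan_pairs(ds, "abs", top_n = 6)
  b <- scan_pairs(rev_ds, "abs", top_n = 6)
  canon <- function(res) {
    pairs <- mapply(function(p, q) paste(sort(c(p, q)), collapse = "|"),
                    res$gene_p, res$gene_q)
    ord <- order(-abs(res$t_score), pairs)
    data.frame(pair = unname(pairs[ord]), t = abs(res$t_score[ord]))
  }
  expect_equal(canon(a), canon(b))
})

test_that("planted abs-pair is recovered at the top of the scan", {
  hits <- vapply(1:20, function(s) {
    ds <- simulate_table4(k = 1, n = 200, seed = s, n_noise = 10)
    top <- scan_pairs(ds, "abs", top_n = 1)
    top$gene_p == "X1" && top$gene_q == "X2"
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("individual ranking finds a perfectly separating gene and matches the oracle", {
  ds <- withr::with_seed(2, {
    v <- matrix(rnorm(6 * 20), nrow = 6)
    v[4, ] <- rep(c(0, 5), each = 10) + rnorm(20, sd = 0.01)
    expression_dataset(v, labels = rep(c(0, 1), each = 10))
  })
  res <- rank_individual(ds, top_n = 6)
  expect_equal(res$gene_p[1], "gene4")
  expect_true(all(is.na(res$gene_q)))
  oracle <- vapply(seq_len(6), function(i) {
    oracle_welch(ds$values[i, ], unname(ds$labels))
  }, numeric(1))
  expect_equal(sort(abs(res$t_score), decreasing = TRUE),
               sort(abs(oracle), decreasing = TRUE), tolerance = 1e-10)
  # top_n = m returns every gene with consecutive ranks
  expect_equal(res$rank, 1:6)
})

test_that("gene union deduplicates in first-appearance order", {
  ds <- make_expr(m = 6, n = 12, seed = 3)
  res <- scan_pairs(ds, "sum", top_n = 5)
  u <- gene_union(res)
  expect_equal(u, unique(as.vector(t(cbind(res$gene_p, res$gene_q)))))
  expect_lte(length(u), 2 * nrow(res))
  expect_equal(anyDuplicated(u), 0L)
})

test_that("overlap matrix counts set intersections and checks universes", {
  ds <- make_expr(m = 10, n = 20, seed = 19)
  res_abs <- scan_pairs(ds, "abs", top_n = 4)
  res_sum <- scan_pairs(ds, "sum", top_n = 4)
  res_ind <- rank_individual(ds, top_n = 5)
  ov <- overlap_matrix(list(abs = res_abs, sum = res_sum, ind = res_ind))
  expect_equal(ov["abs", "abs"], length(gene_union(res_abs)))
  expect_equal(ov["abs", "sum"],
               length(intersect(gene_union(res_abs), gene_union(res_sum))))
  expect_equal(ov, t(ov))
  # identical results -> full overlap; mismatched universes -> error
  expect_equal(overlap_matrix(list(a = res_abs, b = res_abs))[1, 2],
               length(gene_union(res_abs)))
  other <- scan_pairs(make_expr(m = 8, n = 20, seed = 20), "abs", top_n = 3)
  expect_error(overlap_matrix(list(res_abs, other)), "universes")
})

test_that("infinite-t sentinels rank above all finite scores", {
  v <- withr::with_seed(4, matrix(rnorm(5 * 12), nrow = 5))
  v[2, ] <- rep(c(1, 2), each = 6)  # rank-separated from v[3,] below
  v[3, ] <- rep(c(2, 1), each = 6)
  ds <- expression_dataset(v, labels = rep(c(0, 1), each = 6))
  res <- scan_pairs(ds, "sign", top_n = 10)
  expect_true(is.infinite(res$t_score[1]))
  expect_equal(sort(c(res$gene_p[1], res$gene_q[1])), c("gene2", "gene3"))
})
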