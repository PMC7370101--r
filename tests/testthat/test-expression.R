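make_expr <- function(values, conditions = colnames(values), replicates = 1L) {
  # values: genes x conditions matrix of the value given to every replicate
  samples <- as.vector(t(outer(conditions, seq_len(replicates),
                               function(c, r) sprintf("%s_r%d", c, r))))
  fpkm <- tibble::tibble(gene_id = rownames(values))
  for (ci in seq_along(conditions)) {
    for (r in seq_len(replicates)) {
      fpkm[[sprintf("%s_r%d", conditions[ci], r)]] <- values[, ci]
    }
  }
  design <- tibble::tibble(
    sample = samples,
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), times = length(conditions))
  )
  new_aqp_expression(fpkm, design)
}

test_that("the threshold is strict: mean FPKM 1 is not expressed, 10 is", {
  vals <- matrix(c(1, 10, 0), ncol = 1,
                 dimnames = list(c("at_one", "ten", "zero"), "c1"))
  calls <- call_expression(make_expr(vals, "c1"))
  expect_equal(calls$expressed[calls$gene_id == "at_one"], FALSE)
  expect_equal(calls$expressed[calls$gene_id == "ten"], TRUE)
  expect_equal(calls$log10_fpkm[calls$gene_id == "ten"], 1)
  # zero aggregate: sentinel NA, not expressed
  expect_true(is.na(calls$log10_fpkm[calls$gene_id == "zero"]))
  expect_false(calls$expressed[calls$gene_id == "zero"])
})

test_that("equal replicates aggregate exactly and counts ignore column order", {
  sim <- simulate_fpkm(n_genes = 30, seed = 14)
  x <- sim$expression
  const <- x
  const$fpkm[-1] <- 5
  cc <- call_expression(const)
  expect_true(all(cc$mean_fpkm == 5))

  shuffled <- x
  perm <- c(1, 1 + sample(ncol(x$fpkm) - 1))
  shuffled$fpkm <- x$fpkm[, perm]
  a <- expressed_counts(call_expression(x))
  b <- expressed_counts(call_expression(shuffled))
  expect_equal(dplyr::arrange(a, condition), dplyr::arrange(b, condition))
})

test_that("raising the threshold never increases expressed counts", {
  sim <- simulate_fpkm(n_genes = 60, seed = 15)
  thresholds <- c(-1, 0, 0.5, 1, 2)
  counts <- vapply(thresholds, function(th) {
    sum(call_expression(sim$expression, threshold_log10 = th)$expressed)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ubiquitous and silent sets match a per-gene brute-force oracle", {
  sim <- simulate_fpkm(n_genes = 40, seed = 16, expressed_fraction = 0.6)
  calls <- call_expression(sim$expression)
  ub <- ubiquitous_genes(calls)
  sil <- silent_genes(calls)
  for (g in unique(calls$gene_id)) {
    e <- calls$expressed[calls$gene_id == g]
    expect_equal(g %in% ub, all(e))
    expect_equal(g %in% sil, !any(e))
  }
  expect_error(ubiquitous_genes(calls, conditions = c("root", "mars")),
               class = "aqpkit_input_error")
  expect_error(ubiquitous_genes(calls, conditions = "root"),
               class = "aqpkit_input_error")
})

test_that("a gene expressed in two of three conditions is not ubiquitous", {
  vals <- matrix(c(10, 10, 0.5), nrow = 1,
                 dimnames = list("g1", c("a", "b", "c")))
  calls <- call_expression(make_expr(vals, c("a", "b", "c")))
  expect_length(ubiquitous_genes(calls), 0)
})

test_that("the heatmap matrix has genes by conditions with NA sentinels", {
  vals <- matrix(c(10, 0, 1, 100), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
  calls <- call_expression(make_expr(vals, c("a", "b")))
  hm <- heatmap_matrix(calls)
  expect_equal(dim(hm), c(2L, 3L))
  expect_true(is.na(hm$a[hm$gene_id == "g2"]))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  heatmap_matrix(calls, path = tsv)
  txt <- readLines(tsv)
  expect_true(any(grepl("\tNA", txt)))

  sim <- simulate_fpkm(n_genes = 88, seed = 18)
  hm88 <- heatmap_matrix(call_expression(sim$expression))
  expect_equal(dim(hm88), c(88L, 4L))
})

test_that("heatmap plotting returns a ggplot object", {
  sim <- simulate_fpkm(n_genes = 10, seed = 19)
  p <- ggplot2::autoplot(call_expression(sim$expression))
  expect_s3_class(p, "ggplot")
})
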