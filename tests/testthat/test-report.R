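test_that("the exact sign test reproduces printed two-sided P values", {
  expect_equal(sign_test(18, 2), 0.0004, tolerance = 1e-2)
  expect_equal(signif(sign_test(18, 2), 1), 4e-4)
  expect_equal(sign_test(22, 0), 4.77e-7, tolerance = 1e-2)
  expect_equal(sign_test(1, 1), 1)
  expect_equal(sign_test(10, 10), 1)
})

test_that("the sign test agrees with binomial-coefficient enumeration", {
  for (n in c(1, 2, 5, 9, 14, 20)) {
    for (w in 0:n) {
      expect_equal(sign_test(w, n - w), enum_sign_test(w, n - w),
                   tolerance = 1e-12, info = paste(w, n - w))
    }
  }
})

test_that("strand bias tests forward against reverse occurrence counts", {
  occ <- data.frame(strand = c(rep("+", 10), rep("-", 10)))
  sb <- strand_bias(occ)
  expect_equal(sb$p_value, 1)
  expect_identical(sb$direction, "none")
  occ2 <- data.frame(strand = rep("+", 20))
  sb2 <- strand_bias(occ2)
  expect_equal(sb2$p_value, 2 * 2^-20)
  expect_identical(sb2$direction, "+")
  expect_error(strand_bias(occ2[0, , drop = FALSE]), "undefined")
})

test_that("positional histograms anchor at the codon-proximal end", {
  seqs <- sequence_records(c(g1 = strrep("C", 100)), region = "upstream")
  # occurrence flush against the 3' end (start codon) of an upstream region
  occ <- data.frame(gene_id = "g1", start = 94L, end = 100L, strand = "+")
  h <- position_histogram(occ, seqs, bin_width = 50)
  expect_identical(h$count[h$bin_start == 0], 1L)
  # same occurrence in a downstream region anchors at the 5' end
  seqs_d <- sequence_records(c(g1 = strrep("C", 100)), region = "downstream")
  hd <- position_histogram(occ, seqs_d, bin_width = 50)
  expect_identical(hd$count[hd$bin_start == 50], 1L)
  # histogram mass equals the occurrence count
  set.seed(71)
  occ_many <- data.frame(gene_id = "g1",
                         start = sample(0:94, 40, replace = TRUE),
                         strand = "+")
  occ_many$end <- occ_many$start + 6L
  hm <- position_histogram(occ_many, seqs, bin_width = 10)
  expect_identical(sum(hm$count), 40L)
  # per-gene counting collapses same-bin duplicates
  hg <- position_histogram(occ_many, seqs, bin_width = 100, per_gene = TRUE)
  expect_identical(sum(hg$count), 1L)
})

test_that("expression heatmap cells standardize against the hypergeometric law", {
  set.seed(72)
  n <- 400
  X <- cbind(cond1 = runif(n), cond2 = runif(n))
  rownames(X) <- paste0("g", 1:n)
  # positives concentrated in the top bin of condition 1
  pres <- setNames(as.integer(X[, 1] > quantile(X[, 1], 0.96)), rownames(X))
  Z <- expression_heatmap(pres, X, n_bins = 5)
  expect_identical(dim(Z), c(5L, 2L))
  expect_identical(which.max(Z[, 1]), 5L)
  expect_equal(max(Z[, 1], na.rm = TRUE), max(Z, na.rm = TRUE))
  # direct z-score recomputation for one cell
  brk <- seq(min(X[, 1]), max(X[, 1]), length.out = 6)
  cell <- which(cut(X[, 1], brk, include.lowest = TRUE, labels = FALSE) == 5)
  expect_equal(unname(Z[5, 1]),
               density_zscore(sum(pres[cell]), length(cell), sum(pres), n))
  # cell sample sizes per condition sum to n (uniform data: no empty cells)
  counts_per_bin <- table(cut(X[, 2], seq(min(X[, 2]), max(X[, 2]),
                                          length.out = 6),
                              include.lowest = TRUE))
  expect_identical(sum(as.integer(counts_per_bin)), as.integer(n))
  # a cell holding exactly the expected share sits at z = 0
  expect_equal(density_zscore(10, 100, 40, 400), 0)
})

test_that("ranked gene lists are the z-sorted motif-positive genes", {
  g <- structure(list(k = 2L, stage = "balanced",
                      gene_ids = paste0("g", 1:6),
                      nbrs = list(c(2L, 3L), c(3L, 4L), c(1L, 2L), c(5L, 6L),
                                  c(4L, 6L), c(4L, 5L))),
                 class = "neighbor_graph")
  pres <- setNames(c(1L, 1L, 1L, 0L, 0L, 0L), paste0("g", 1:6))
  dp <- density_profile(pres, g)
  rl <- ranked_gene_list(dp, pres)
  expect_identical(nrow(rl), 3L)                      # length = n_m
  expect_true(all(diff(rl$zscore) <= 0))
  # oracle equivalence: elementwise density_zscore
  expect_equal(rl$zscore,
               density_zscore(rl$count, 2, 3, 6))
  # all densities equal -> all z equal
  pres_u <- setNames(rep(1L, 6), paste0("g", 1:6))
  expect_error(ranked_gene_list(density_profile(pres_u, g), pres_u),
               "undefined")
})
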