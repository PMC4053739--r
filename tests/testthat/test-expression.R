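test_that("pairwise distances match their definitions", {
  X <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  D <- pairwise_distance(X, "euclidean")
  expect_equal(D["a", "b"], 5)
  expect_equal(D["a", "c"], 0)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # pearson distance of a profile vs its affine positive rescaling is 0
  Y <- rbind(a = c(1, 2, 5, 3), b = 2 * c(1, 2, 5, 3) + 7, c = c(4, 1, 0, 2))
  Dp <- pairwise_distance(Y, "pearson")
  expect_equal(Dp["a", "b"], 0, tolerance = 1e-12)
  expect_equal(Dp["a", "c"], 1 - cor(Y["a", ], Y["c", ]))
  # zero-variance profile is flagged by name
  Z <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  err <- tryCatch(pairwise_distance(Z, "pearson"), error = identity)
  expect_identical(attr(err, "genes"), "a")
})

test_that("kNN graph agrees with the full-sort oracle and breaks ties by order", {
  X <- cbind(c(0, 1, 2))            # collinear points
  rownames(X) <- c("a", "b", "c")
  g <- knn_graph(X, 1)
  expect_identical(g$nbrs, list(2L, 1L, 2L))  # middle is neighbor of both ends;
                                              # b's tie (a vs c) resolved to a
  set.seed(11)
  Xr <- matrix(rnorm(80 * 5), 80)
  rownames(Xr) <- paste0("g", 1:80)
  g8 <- knn_graph(Xr, 8)
  expect_identical(g8$nbrs, oracle_knn(pairwise_distance(Xr), 8))
  expect_true(all(lengths(g8$nbrs) == 8))
  expect_error(knn_graph(Xr, 80), "k must satisfy")
})

test_that("symmetrization closes arcs under reversal and lifts in-degrees to >= k", {
  set.seed(12)
  X <- matrix(rnorm(60 * 4), 60)
  g <- knn_graph(X, 5)
  gs <- symmetrize(g)
  n <- 60
  arc <- function(gr) {
    cbind(rep(seq_len(n), lengths(gr$nbrs)), unlist(gr$nbrs))
  }
  a <- arc(gs)
  have <- paste(a[, 1], a[, 2])
  expect_true(all(paste(a[, 2], a[, 1]) %in% have))    # closed under reversal
  a0 <- arc(g)
  expect_true(all(paste(a0[, 1], a0[, 2]) %in% have))  # superset of the kNN arcs
  expect_true(all(in_degrees(gs) >= 5))
  # an already-symmetric graph is unchanged
  gs2 <- symmetrize(structure(list(k = gs$k, stage = "knn",
                                   gene_ids = gs$gene_ids, nbrs = gs$nbrs),
                              class = "neighbor_graph"))
  expect_identical(gs2$nbrs, gs$nbrs)
})

test_that("balanced sampling favors low in-degree candidates at the stated rate", {
  # neighborhood {b, c} with Gamma* in-degrees d(b) = 1, d(c) = 3:
  # one draw should pick b with probability (1/1) / (1/1 + 1/3) = 3/4
  gstar <- structure(list(k = 1L, stage = "symmetrized", gene_ids = letters[1:6],
                          nbrs = list(c(2L, 3L), 3L, 3L, 1L, 4L, 5L)),
                     class = "neighbor_graph")
  expect_identical(in_degrees(gstar)[2:3], c(1L, 3L))
  picks <- vapply(1:4000, function(s)
    balanced_neighbor_sample(gstar, 1L, seed = s)$nbrs[[1]], 1L)
  expect_equal(mean(picks == 2L), 0.75, tolerance = 0.025)
})

test_that("balanced graph is a k-regular subgraph of the symmetrized graph", {
  set.seed(13)
  X <- matrix(rnorm(80 * 6), 80)
  k <- 10
  gs <- symmetrize(knn_graph(X, k))
  gb <- balanced_neighbor_sample(gs, k, seed = 5)
  expect_true(all(lengths(gb$nbrs) == k))             # out-degree exactly k
  for (i in seq_len(80)) {
    expect_true(all(gb$nbrs[[i]] %in% gs$nbrs[[i]]))  # arc subset of Gamma*
    expect_false(i %in% gb$nbrs[[i]])
    expect_false(anyDuplicated(gb$nbrs[[i]]) > 0)
  }
  expect_identical(sum(in_degrees(gb)), 80L * 10L)    # conservation
  # reproducibility under a fixed seed
  gb2 <- balanced_neighbor_sample(gs, k, seed = 5)
  expect_identical(gb$nbrs, gb2$nbrs)
})

test_that("with equal in-degrees balanced sampling is uniform without replacement", {
  # star-free toy: every gene's neighborhood is everyone else, all degrees equal
  n <- 6
  gstar <- structure(list(k = 2L, stage = "symmetrized",
                          gene_ids = as.character(1:n),
                          nbrs = lapply(1:n, function(i) setdiff(1:n, i))),
                     class = "neighbor_graph")
  draws <- table(unlist(lapply(1:3000, function(s)
    balanced_neighbor_sample(gstar, 2L, seed = s)$nbrs[[1]])))
  freq <- as.numeric(draws) / sum(draws)
  expect_true(max(abs(freq - 1 / (n - 1))) < 0.02)
})

test_that("k-means baseline recovers separated blobs and improves with restarts", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40 * 3, mean = 0), 40),
             matrix(rnorm(40 * 3, mean = 8), 40))
  rownames(X) <- paste0("g", 1:80)
  part <- kmeans_partition(X, 2, restarts = 5, seed = 3)
  expect_identical(length(unique(part$labels[1:40])), 1L)
  expect_identical(length(unique(part$labels[41:80])), 1L)
  expect_true(part$labels[1] != part$labels[41])
  # best-of-restarts is no worse than a single restart
  single <- kmeans_partition(X, 5, restarts = 1, seed = 9)
  multi <- kmeans_partition(X, 5, restarts = 20, seed = 9)
  expect_lte(multi$tot_withinss, single$tot_withinss)
})
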