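test_that("hypergeometric upper tail is exact against enumeration", {
  expect_equal(hypergeom_upper_tail(0, 10, 4, 3), 1)
  expect_equal(hypergeom_upper_tail(4, 10, 4, 3), 0)   # x > min(draw, n_m)
  expect_equal(hypergeom_upper_tail(2, 10, 4, 3), 1 / 3)
  for (n in c(5, 9, 14)) {
    for (n_m in 0:n) {
      for (draw in 0:n) {
        x <- 0:(min(draw, n_m) + 1L)
        expect_equal(hypergeom_upper_tail(x, n, n_m, draw),
                     vapply(x, enum_hyper_tail, 0, n = n, n_m = n_m,
                            draw = draw),
                     tolerance = 1e-12,
                     info = paste(n, n_m, draw))
      }
    }
  }
})

test_that("density profiles count positive neighbors", {
  g <- structure(list(k = 2L, stage = "balanced",
                      gene_ids = paste0("g", 1:4),
                      nbrs = list(c(2L, 3L), c(1L, 4L), c(1L, 2L), c(2L, 3L))),
                 class = "neighbor_graph")
  pres <- setNames(c(1L, 1L, 0L, 0L), paste0("g", 1:4))
  dp <- density_profile(pres, g)
  expect_identical(dp$counts, c(1L, 1L, 2L, 1L))   # direct neighbor count
  expect_equal(dp$densities, c(0.5, 0.5, 1, 0.5))
  expect_equal(density_profile(setNames(rep(1L, 4), paste0("g", 1:4)), g)$densities,
               rep(1, 4))
  expect_equal(density_profile(setNames(rep(0L, 4), paste0("g", 1:4)), g)$densities,
               rep(0, 4))
  expect_error(density_profile(pres[1:3], g), "universes")
})

test_that("density z-score standardizes against the hypergeometric law", {
  expect_equal(density_zscore(2, 20, 10, 100), 0)    # observed = expected
  expect_equal(density_zscore(6, 20, 10, 100), 3.3166, tolerance = 1e-4)
  # sign flips around the expectation k n_m / n
  expect_lt(density_zscore(1, 20, 10, 100), 0)
  expect_gt(density_zscore(3, 20, 10, 100), 0)
  # agrees with the mean/sd of the actual hypergeometric distribution
  xs <- 0:20
  pr <- dhyper(xs, 10, 90, 20)
  mu <- sum(xs * pr)
  sdv <- sqrt(sum((xs - mu)^2 * pr))
  expect_equal(density_zscore(6, 20, 10, 100), (6 - mu) / sdv, tolerance = 1e-12)
  expect_error(density_zscore(5, 20, 0, 100), "undefined")
})

test_that("discrete scores reproduce worked cluster examples", {
  pres <- c(1, 1, 1, 0, 0, 0)
  labs <- c(1, 1, 1, 2, 2, 2)
  expect_equal(score_discrete(pres, labs, "hypergeometric"), -log(1 / 20))
  expect_equal(score_discrete(pres, labs, "mutual_information"), 1)  # 1 bit
  expect_equal(score_discrete(rep(1, 6), labs, "mutual_information"), 0)
  expect_error(score_discrete(pres, factor(labs, levels = 1:3), "hypergeometric"),
               "empty cluster")
})

test_that("continuous scores reproduce worked neighborhood examples", {
  # n = 6, k = 2, one gene with both neighbors positive, n_m = 2
  counts <- c(2, 0, 0, 0, 0, 0)
  expect_equal(score_continuous(counts, 2, 6, "hypergeometric", k = 2),
               -log(1 / 15), tolerance = 1e-12)
  # n = 2, k = 1, densities (1, 0), n_m = 1: 1 bit
  expect_equal(score_continuous(c(1, 0), 1, 2, "mutual_information", k = 1), 1)
  # densities all equal to n_m / n: MI estimate 0
  expect_equal(score_continuous(rep(5, 10), 5, 10, "mutual_information", k = 10),
               0)
  expect_message(
    expect_equal(score_continuous(rep(0, 4), 0, 4, "mutual_information", k = 2), 0),
    "degenerate")
})

test_that("MI estimate is a non-negative average of KL divergences", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    k <- sample(1:(n - 1), 1)
    counts <- sample(0:k, n, replace = TRUE)
    n_m <- sample(1:(n - 1), 1)
    expect_gte(score_continuous(counts, n_m, n, "mutual_information", k = k), 0)
  }
})

test_that("hypergeometric neighborhood score is monotone in any single count", {
  set.seed(22)
  counts <- sample(0:10, 20, replace = TRUE)
  base <- score_continuous(counts, 7, 20, "hypergeometric", k = 10)
  for (i in c(1, 5, 12)) {
    bumped <- counts
    bumped[i] <- min(10, bumped[i] + 1)
    expect_gte(score_continuous(bumped, 7, 20, "hypergeometric", k = 10), base)
  }
})

test_that("scores are invariant under a joint gene permutation", {
  set.seed(23)
  n <- 30
  X <- matrix(rnorm(n * 5), n, dimnames = list(paste0("g", 1:n), NULL))
  seqs <- sequence_records(setNames(vapply(1:n, function(i) random_seq(60), ""),
                                    rownames(X)))
  g <- knn_graph(X, 6)    # deterministic stage: exact invariance expected
  pres <- presence_matrix("ACG", seqs)
  sc <- score_continuous(density_profile(pres, g), sum(pres), n)
  perm <- sample.int(n)
  Xp <- X[perm, , drop = FALSE]
  gp <- knn_graph(Xp, 6)
  # permuting genes jointly in sequences and expression relabels the graph
  presp <- pres[perm]
  scp <- score_continuous(density_profile(presp, gp), sum(presp), n)
  expect_equal(scp, sc, tolerance = 1e-9)
})
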