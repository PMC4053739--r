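test_that("q-mer enumeration counts and canonical pairing are correct", {
  expect_length(enumerate_qmers(1, "forward"), 4)
  expect_length(enumerate_qmers(2, "both"), 10)   # (16 + 4 palindromes) / 2
  expect_length(enumerate_qmers(3, "forward"), 64)
  q7 <- enumerate_qmers(7, "both")
  expect_length(q7, 8192)                         # odd length: no palindromes
  # every canonical representative is <= its reverse complement
  expect_true(all(q7 <= redens:::revcomp_words(q7)))
})

test_that("bulk q-mer presence equals per-motif scanning", {
  set.seed(31)
  seqs <- sequence_records(setNames(vapply(1:25, function(i) random_seq(80), ""),
                                    paste0("g", 1:25)))
  for (strands in c("forward", "both")) {
    P <- qmer_presence(seqs, 3, strands)
    expect_true(all(P@x == 1))
    for (m in sample(colnames(P), 12)) {
      expect_identical(as.integer(P[, m]),
                       unname(presence_matrix(m, seqs, strands)),
                       info = paste(m, strands))
    }
  }
  # windows containing N mark nothing
  Pn <- qmer_presence(sequence_records(c(g = "AANTT")), 3, "forward")
  expect_identical(sum(Pn), 0)
})

test_that("fast q-mer scoring equals the per-motif reference path", {
  fx <- small_planted_fixture(n = 80, p = 8, k = 12, seq_len = 120, seed = 33)
  P <- qmer_presence(fx$seqs, 4, "both")
  for (crit in c("mutual_information", "hypergeometric")) {
    fast <- qmer_scores(P, fx$graph, crit)
    ref <- vapply(sample(colnames(P), 25), function(m) {
      pres <- presence_matrix(m, fx$seqs, "both")
      suppressMessages(score_continuous(density_profile(pres, fx$graph),
                                        sum(pres), nrow(fx$X), crit))
    }, 0)
    expect_equal(fast[names(ref)], ref, tolerance = 1e-10)
  }
})

test_that("shuffle null: identity permutation reproduces observed scores", {
  fx <- small_planted_fixture(n = 60, p = 6, k = 10, seq_len = 100, seed = 34)
  P <- qmer_presence(fx$seqs, 4, "both")
  obs <- qmer_scores(P, fx$graph)
  expect_equal(qmer_scores(P, fx$graph, perm = seq_len(nrow(P))), obs)
  # a motif present in all genes scores 0 under any permutation
  Pall <- P
  Pall[, 1] <- 1
  perm <- sample.int(nrow(P))
  expect_equal(unname(qmer_scores(Pall, fx$graph, perm = perm)[1]), 0)
  nl <- null_scores(P, fx$graph, n_shuffles = 3, seed = 7)
  expect_identical(dim(nl), c(3L, ncol(P)))
  expect_identical(nl, null_scores(P, fx$graph, n_shuffles = 3, seed = 7))
})

test_that("FDR curve follows the expected/observed ratio with a cap at 1", {
  observed <- c(a = 5, b = 4, c = 3, d = 1)
  # one shuffle round with nulls below every observed score: FDR 0 everywhere
  expect_equal(fdr_curve(observed, matrix(rep(0.5, 4), 1)), rep(0, 4))
  # mean null count 5 at s, observed count 50 at s -> 0.1
  obs2 <- seq(10, 0.2, length.out = 50)
  nulls2 <- matrix(rep(c(rep(obs2[50] + 0.01, 5), rep(-1, 45)), 2),
                   nrow = 2, byrow = TRUE)
  expect_equal(fdr_curve(obs2, nulls2)[50], 5 / 50)
  # expected > observed caps at 1
  expect_equal(fdr_curve(c(x = 1), matrix(rep(2, 10), 1)), 1)
})

test_that("seed selection ranks by score with the FDR gate", {
  tab <- structure(list(qmers = c("AA", "CC", "GG", "TT"),
                        observed = c(AA = 2, CC = 5, GG = 5, TT = 0.1),
                        nulls = matrix(0, 1, 4),
                        fdr = c(0.0005, 0, 0, 0.5),
                        n_m = c(3, 4, 5, 6)),
                   class = "seed_table")
  sel <- select_seeds(tab, 0.001)
  expect_identical(sel$qmer, c("CC", "GG", "AA"))  # score desc, tie by string
  expect_identical(nrow(select_seeds(tab, 0)), 0L)
  expect_identical(nrow(select_seeds(tab, 1.0000001)), 4L)
})

test_that("a planted q-mer dominates the seed table on synthetic data", {
  fx <- small_planted_fixture(n = 200, p = 12, k = 40, q = 6,
                              motif = "WAGACA", seed = 35)
  P <- qmer_presence(fx$seqs, 6, "both")
  tab <- seed_table(P, fx$graph, "mutual_information", n_shuffles = 5,
                    seed = 36)
  sel <- select_seeds(tab, 0.001)
  planted <- expand_motif("WAGACA")
  expect_gt(nrow(sel), 0)
  expect_true(sel$qmer[1] %in% planted)
  # observed MI of the planted words clears the whole shuffle null
  for (w in planted) {
    expect_gt(tab$observed[w], max(tab$nulls[, w]))
    expect_gt(tab$observed[w], quantile(tab$nulls, 0.99))
    expect_gt(tab$observed[w], 3 * mean(tab$nulls[, w]))
  }
})
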