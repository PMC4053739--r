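# Shared oracles and fixture builders. Oracles are deliberately naive and
# independent of the implementation paths they check.

# brute-force IUPAC window scan: double loop, no regex
naive_scan <- function(motif, seq) {
  sets <- lapply(strsplit(motif, "")[[1]],
                 function(s) redens:::IUPAC_SET[[s]])
  chars <- strsplit(seq, "")[[1]]
  w <- length(sets)
  hits <- integer(0)
  if (length(chars) >= w) {
    for (i in seq_len(length(chars) - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!chars[i + j - 1L] %in% sets[[j]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i - 1L)  # 0-based
    }
  }
  hits
}

# hypergeometric upper tail by direct binomial-coefficient summation
enum_hyper_tail <- function(x, n, n_m, draw) {
  js <- x:min(draw, n_m)
  js <- js[js >= max(0, draw - (n - n_m))]
  if (x > min(draw, n_m)) return(0)
  if (x <= 0) return(1)
  sum(choose(n_m, js) * choose(n - n_m, draw - js)) / choose(n, draw)
}

# exact two-sided sign test from binomial-coefficient enumeration
enum_sign_test <- function(wins, losses) {
  n <- wins + losses
  probs <- choose(n, 0:n) / 2^n
  up <- sum(probs[(wins:n) + 1L])
  down <- sum(probs[(0:wins) + 1L])
  min(1, 2 * min(up, down))
}

# exhaustive-sort kNN oracle with index tie-break
oracle_knn <- function(D, k) {
  n <- nrow(D)
  lapply(seq_len(n), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  })
}

random_motif <- function(len, alphabet = names(redens:::IUPAC_MASK)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_seq <- function(len, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

# small planted fixture shared by the refinement/seed tests
small_planted_fixture <- function(n = 200, p = 12, k = 40, q = 6,
                                  motif = "WAGACA", seq_len = 150,
                                  p_inside = 0.9, p_outside = 0.02,
                                  seed = 101) {
  X <- simulate_expression(n, p, "periodic", noise_sd = 0.25, seed = seed)
  sim <- simulate_sequences(X, length = seq_len, at_fraction = 0.5,
                            motifs = list(list(motif = motif,
                                               p_inside = p_inside,
                                               p_outside = p_outside,
                                               inside_fraction = 0.2)),
                            seed = seed + 1)
  g <- balanced_neighbor_sample(symmetrize(knn_graph(X, k)), k,
                                seed = seed + 2)
  list(X = X, seqs = sim$records, truth = sim$truth, graph = g, q = q, k = k)
}
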