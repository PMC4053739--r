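# Seed discovery: exhaustive q-mer scoring, shuffle null, empirical FDR.

#' Enumerate all non-degenerate q-mers
#'
#' All 4^q words over A/C/G/T. With `strands = "both"`, each
#' reverse-complement pair is represented once by its lexicographically
#' smaller member (palindromic words represent themselves), so scanning a
#' canonical q-mer on both strands covers the pair.
#'
#' @param q Word length, 1..15.
#' @param strands "both" (canonical representatives) or "forward" (all
#'   4^q words).
#' @return Character vector of q-mers, sorted.
#' @export
enumerate_qmers <- function(q, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  q <- as.integer(q)
  if (q < 1L || q > 15L) stop("q must be in 1..15")
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), q),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  words <- do.call(paste0, grid)
  if (strands == "both") {
    rc <- revcomp_words(words)
    words <- unique(pmin(words, rc))
  }
  sort(words)
}

canonical_qmer <- function(words) pmin(words, revcomp_words(words))

#' Presence of every q-mer in every sequence
#'
#' Single suffix-scan over each sequence marking all contained q-mers
#' (windows containing N mark nothing). With `strands = "both"`, windows
#' are mapped to their canonical representative.
#'
#' @param seqs Named character vector of sequences.
#' @param q Word length.
#' @param strands "both" or "forward".
#' @return Sparse 0/1 Matrix (genes x q-mers) with dimnames; q-mer columns
#'   follow [enumerate_qmers()] order.
#' @export
qmer_presence <- function(seqs, q, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  qmers <- enumerate_qmers(q, strands)
  n <- length(seqs)
  lens <- nchar(seqs)
  nwin <- pmax(lens - q + 1L, 0L)
  gene_idx <- rep.int(seq_len(n), nwin)
  starts <- unlist(lapply(nwin, function(w) seq_len(w)), use.names = FALSE)
  windows <- substring(rep.int(unname(seqs), nwin), starts, starts + q - 1L)
  if (strands == "both") windows <- canonical_qmer(windows)
  col_idx <- match(windows, qmers)          # NA for windows containing N
  keep <- !is.na(col_idx)
  M <- Matrix::sparseMatrix(i = gene_idx[keep], j = col_idx[keep], x = 1,
                            dims = c(n, length(qmers)),
                            dimnames = list(names(seqs), qmers))
  M@x[] <- 1                                # occurrence counts -> presence
  M
}

# in-neighbor lists of a fixed-out-degree graph in 0-based CSC layout
in_csc <- function(graph) {
  n <- length(graph$gene_ids)
  from <- rep.int(seq_len(n), lengths(graph$nbrs))
  to <- unlist(graph$nbrs, use.names = FALSE)
  o <- order(to, from, method = "radix")
  list(nb = from[o] - 1L,
       ptr = c(0L, cumsum(tabulate(to, nbins = n))))
}

# entropy-like per-gene lookup a[c] = d log d + (1-d) log(1-d), d = c/k,
# in the requested base; a[0] = a[k] = 0
a_lookup <- function(k, base) {
  d <- (0:k) / k
  t1 <- ifelse(d > 0, d * log(d), 0)
  t2 <- ifelse(d < 1, (1 - d) * log(1 - d), 0)
  (t1 + t2) / log(base)
}

#' Score every q-mer against a neighbor graph
#'
#' Computes the continuous hypergeometric or mutual-information score of
#' every presence-matrix column in one pass over the graph (C++ inner
#' loop). Identical, q-mer by q-mer, to [score_continuous()] applied to
#' [density_profile()].
#'
#' @param P Sparse presence matrix from [qmer_presence()].
#' @param graph Fixed-out-degree neighbor graph (stage "balanced" or
#'   "knn") over the same genes.
#' @param criterion "mutual_information" or "hypergeometric".
#' @param base Log base (default: 2 for MI, natural for hypergeometric).
#' @param perm Optional gene relabelling (integer permutation of 1..n)
#'   applied to the presence rows; used for the shuffle null.
#' @return Named numeric vector of scores, one per q-mer.
#' @export
qmer_scores <- function(P, graph,
                        criterion = c("mutual_information", "hypergeometric"),
                        base = NULL, perm = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(graph, "neighbor_graph"))
  n <- length(graph$gene_ids)
  if (nrow(P) != n) stop("presence and graph cover different gene universes")
  k <- graph$k
  P <- methods::as(P, "CsparseMatrix")
  csc <- in_csc(graph)
  if (is.null(perm)) perm <- seq_len(n)
  base <- base %||% if (criterion == "mutual_information") 2 else exp(1)
  alut <- if (criterion == "mutual_information") a_lookup(k, base)
          else numeric(k + 1L)
  st <- qmer_count_stats(P@i, P@p, csc$nb, csc$ptr, n, alut,
                         as.integer(perm) - 1L)
  n_m <- Matrix::colSums(P)
  if (criterion == "mutual_information") {
    p <- n_m / n
    lp <- ifelse(p > 0, log(p), 0) / log(base)
    l1p <- ifelse(p < 1, log(1 - p), 0) / log(base)
    dbar <- st$sum_c / k            # sum of densities over genes
    sc <- (st$sum_a - dbar * lp - (n - dbar) * l1p) / n
    sc[p <= 0 | p >= 1] <- 0
  } else {
    sc <- vapply(seq_along(n_m), function(j)
      neg_log_hyper_tail(st$max_c[j], n, n_m[j], k, base = base), 0)
  }
  stats::setNames(sc, colnames(P))
}

#' Shuffle-null score distribution for all q-mers
#'
#' Estimates the score distribution under the null hypothesis of no
#' dependency between sequences and expression by randomly permuting the
#' mapping between the two (one shared permutation per shuffle round,
#' applied to the presence rows while the graph is fixed) and rescoring
#' every q-mer.
#'
#' @inheritParams qmer_scores
#' @param n_shuffles Number of shuffle rounds (default 10).
#' @param seed Integer seed.
#' @return Matrix n_shuffles x q-mers of null scores.
#' @export
null_scores <- function(P, graph,
                        criterion = c("mutual_information", "hypergeometric"),
                        n_shuffles = 10L, seed = 1L, base = NULL) {
  criterion <- match.arg(criterion)
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  n <- length(graph$gene_ids)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perms <- replicate(n_shuffles, sample.int(n), simplify = FALSE)
  out <- t(vapply(perms, function(pp)
    qmer_scores(P, graph, criterion, base = base, perm = pp),
    numeric(ncol(P))))
  colnames(out) <- colnames(P)
  out
}

#' Empirical FDR at each observed score
#'
#' FDR(s) = (mean over shuffles of the number of null scores >= s) /
#' (number of observed scores >= s), evaluated at every observed score and
#' capped at 1.
#'
#' @param observed Named numeric vector of observed q-mer scores.
#' @param nulls Null score matrix from [null_scores()] (rows = shuffles).
#' @return Numeric vector of FDR values in [0, 1], aligned with
#'   `observed`.
#' @export
fdr_curve <- function(observed, nulls) {
  n_shuffles <- nrow(nulls)
  nullv <- sort(as.numeric(nulls))
  obsv <- sort(as.numeric(observed))
  n_null_ge <- length(nullv) - findInterval(observed, nullv, left.open = TRUE)
  n_obs_ge <- length(obsv) - findInterval(observed, obsv, left.open = TRUE)
  pmin(1, (n_null_ge / n_shuffles) / n_obs_ge)
}

#' Assemble the seed table
#'
#' Scores all q-mers, builds the shuffle null and attaches the FDR curve.
#'
#' @inheritParams null_scores
#' @return List of class `seed_table` with fields `qmers`, `observed`,
#'   `nulls`, `fdr`, `n_m`, `criterion`, `k`.
#' @export
seed_table <- function(P, graph,
                       criterion = c("mutual_information", "hypergeometric"),
                       n_shuffles = 10L, seed = 1L, base = NULL) {
  criterion <- match.arg(criterion)
  observed <- qmer_scores(P, graph, criterion, base = base)
  nulls <- null_scores(P, graph, criterion, n_shuffles, seed, base = base)
  structure(list(qmers = colnames(P), observed = observed, nulls = nulls,
                 fdr = fdr_curve(observed, nulls),
                 n_m = Matrix::colSums(P), criterion = criterion,
                 k = graph$k),
            class = "seed_table")
}

#' @export
#' @method print seed_table
print.seed_table <- function(x, ...) {
  cat("seed table: ", length(x$qmers), " q-mers, ", nrow(x$nulls),
      " shuffle rounds, criterion = ", x$criterion, "\n", sep = "")
  invisible(x)
}

#' Select seeds below an FDR threshold
#'
#' @param table A `seed_table`.
#' @param fdr_threshold Seeds must have FDR strictly below this value
#'   (default 0.001).
#' @return data.frame (qmer, score, fdr, n_m) ranked by score descending,
#'   ties by q-mer string.
#' @export
select_seeds <- function(table, fdr_threshold = 0.001) {
  keep <- which(table$fdr < fdr_threshold)
  d <- data.frame(qmer = table$qmers[keep],
                  score = unname(table$observed[keep]),
                  fdr = unname(table$fdr[keep]),
                  n_m = unname(table$n_m[keep]),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$score, d$qmer), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Export a seed table as TSV
#' @param table A `seed_table`.
#' @param path Output file.
#' @export
write_seed_table <- function(table, path) {
  d <- data.frame(qmer = table$qmers, score = unname(table$observed),
                  fdr = unname(table$fdr), n_m = unname(table$n_m))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
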