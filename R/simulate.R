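# Synthetic data: expression matrices with smooth low-dimensional
# structure and sequence sets with planted, expression-localized motifs.
# Ground truth is recorded for every plant, so every pipeline stage can
# be checked against a known answer.

#' Simulate an expression matrix
#'
#' `structure = "periodic"` emulates time-course data in which every gene
#' follows one common oscillation with a gene-specific phase (the
#' expression space is essentially a noisy circle); `"blobs"` draws genes
#' from a mixture of Gaussian clusters.
#'
#' @param n Number of genes (>= 10).
#' @param p Number of conditions / time points (>= 2).
#' @param structure "periodic" or "blobs".
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @param amplitude Sinusoid amplitude (periodic only).
#' @param n_clusters Number of blobs (blobs only, default 4).
#' @return Numeric matrix (genes x conditions) with gene IDs g0001, ...
#'   For the periodic design, the gene phases are attached as attribute
#'   "phase".
#' @export
simulate_expression <- function(n, p, structure = c("periodic", "blobs"),
                                noise_sd = 0.3, seed = 1L, amplitude = 1,
                                n_clusters = 4L) {
  structure_ <- match.arg(structure)
  if (n < 10L) stop("n must be >= 10")
  if (p < 2L) stop("p must be >= 2")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ids <- sprintf("g%04d", seq_len(n))
  tp <- 2 * pi * (seq_len(p) - 1L) / p
  if (structure_ == "periodic") {
    phase <- stats::runif(n, 0, 2 * pi)
    X <- amplitude * sin(outer(phase, tp, "+")) +
      matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
    attr(X, "phase") <- phase
  } else {
    centers <- matrix(stats::rnorm(n_clusters * p, sd = 3), n_clusters, p)
    lab <- sample.int(n_clusters, n, replace = TRUE)
    X <- centers[lab, , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
    attr(X, "cluster") <- lab
  }
  dimnames(X) <- list(ids, sprintf("c%02d", seq_len(p)))
  X
}

#' Simulate gene sequences with expression-localized planted motifs
#'
#' Background bases are drawn i.i.d. with P(A) = P(T) = at_fraction / 2
#' and P(C) = P(G) = (1 - at_fraction) / 2. For each plant specification,
#' a focal region of the expression space is defined as the genes whose
#' profile lies within a radius of a focal gene's profile (the radius is
#' the `inside_fraction` quantile of all distances); genes inside receive
#' one occurrence of the motif with probability `p_inside`, genes outside
#' with probability `p_outside`. A planted occurrence overwrites the
#' background with a uniformly chosen word of the motif's expansion, at a
#' uniform position, on a random strand (when `strand = "both"`). At most
#' one plant per gene per motif. Background sequence may contain chance
#' occurrences; the truth record distinguishes planted from background
#' hits.
#'
#' @param X Expression matrix from [simulate_expression()].
#' @param length Sequence length in bp (>= longest motif).
#' @param at_fraction Background A+T fraction (default 0.6; near 0.9
#'   mimics extremely AT-rich intergenic regions).
#' @param motifs List of plant specifications, each a list with fields
#'   `motif` (IUPAC string), `p_inside`, `p_outside`,
#'   `inside_fraction` (default 0.2), `focal_gene` (default: seeded
#'   random choice) and `strand` ("both" or "forward").
#' @param seed Integer seed.
#' @param region Region kind of the emitted records.
#' @return List with `records` (sequence collection) and `truth`: a list
#'   with `plants` (data.frame gene_id, motif, word, start, strand),
#'   `inside` (list of inside-gene ID vectors per motif), and the
#'   generator parameters.
#' @export
simulate_sequences <- function(X, length = 600L, at_fraction = 0.6,
                               motifs = list(), seed = 1L,
                               region = c("upstream", "downstream")) {
  region <- match.arg(region)
  n <- nrow(X)
  ids <- rownames(X)
  for (sp in motifs)
    if (nchar(sp$motif) > length)
      stop("motif ", sp$motif, " longer than the sequences")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pr <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
          G = (1 - at_fraction) / 2, T = at_fraction / 2)
  mat <- matrix(sample(names(pr), n * length, replace = TRUE, prob = pr),
                nrow = n)
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- ids
  plants <- list()
  inside_sets <- list()
  occupied <- vector("list", n)       # planted intervals, kept plant-disjoint
  for (sp in motifs) {
    motif <- as_motif(sp$motif)
    words <- expand_motif(motif)
    inside_fraction <- sp$inside_fraction %||% 0.2
    strand_mode <- sp$strand %||% "both"
    focal <- sp$focal_gene %||% sample(ids, 1L)
    d <- sqrt(colSums((t(X) - X[focal, ])^2))
    radius <- stats::quantile(d, inside_fraction)
    inside <- ids[d <= radius]
    inside_sets[[motif]] <- inside
    p_gene <- ifelse(ids %in% inside, sp$p_inside, sp$p_outside)
    plant <- stats::runif(n) < p_gene
    w <- nchar(motif)
    for (g in which(plant)) {
      word <- sample(words, 1L)
      pos <- sample.int(length - w + 1L, 1L)           # 1-based start
      for (try in seq_len(100L)) {
        clash <- any(vapply(occupied[[g]], function(iv)
          pos <= iv[2L] && pos + w - 1L >= iv[1L], TRUE))
        if (!clash) break
        pos <- sample.int(length - w + 1L, 1L)
      }
      occupied[[g]] <- c(occupied[[g]], list(c(pos, pos + w - 1L)))
      strand <- if (strand_mode == "both") sample(c("+", "-"), 1L) else "+"
      ins <- if (strand == "+") word else revcomp_words(word)
      substr(seqs[g], pos, pos + w - 1L) <- ins
      plants[[length(plants) + 1L]] <-
        data.frame(gene_id = ids[g], motif = motif, word = word,
                   start = pos - 1L, strand = strand,
                   stringsAsFactors = FALSE)
    }
  }
  plants <- if (length(plants)) do.call(rbind, plants) else
    data.frame(gene_id = character(0), motif = character(0),
               word = character(0), start = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  list(records = sequence_records(seqs, region),
       truth = list(plants = plants, inside = inside_sets,
                    params = list(length = length,
                                  at_fraction = at_fraction,
                                  motifs = motifs, seed = seed)))
}

#' Write a synthetic truth record as JSON
#' @param truth Truth list from [simulate_sequences()].
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
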