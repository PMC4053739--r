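# Greedy seed refinement: IUPAC generalization constrained by
# density-profile correlation with the original seed, then elongation.

#' Build a scoring context for motif refinement
#'
#' Bundles the sequences, neighbor graph and scoring settings so that any
#' IUPAC motif can be scored consistently with the q-mer seeding stage
#' (same graph, same criterion, same log base).
#'
#' @param seqs Named character vector of sequences, in graph gene order.
#' @param graph Fixed-out-degree neighbor graph.
#' @param criterion "mutual_information" or "hypergeometric".
#' @param strands "both" or "forward".
#' @param base Log base (default as in [score_continuous()]).
#' @return List of class `score_context`.
#' @export
score_context <- function(seqs, graph,
                          criterion = c("mutual_information", "hypergeometric"),
                          strands = c("both", "forward"), base = NULL) {
  criterion <- match.arg(criterion)
  strands <- match.arg(strands)
  stopifnot(inherits(graph, "neighbor_graph"))
  if (!identical(names(seqs), graph$gene_ids))
    stop("sequence gene IDs do not match the graph's")
  structure(list(seqs = seqs, graph = graph, adj = adj_matrix(graph),
                 n = length(seqs), k = graph$k, criterion = criterion,
                 strands = strands,
                 base = base %||%
                   if (criterion == "mutual_information") 2 else exp(1)),
            class = "score_context")
}

#' Score a motif in a context
#'
#' @param motif IUPAC motif string.
#' @param ctx A `score_context`.
#' @return List with `score`, `n_m`, `presence` (0/1 vector) and `counts`
#'   (neighborhood counts, the motif's density profile numerator).
#' @export
motif_score <- function(motif, ctx) {
  pres <- presence_matrix(motif, ctx$seqs, ctx$strands)
  counts <- as.integer(rowSums(matrix(pres[ctx$adj], nrow = ctx$n)))
  n_m <- sum(pres)
  sc <- suppressMessages(
    score_continuous(counts, n_m, ctx$n, ctx$criterion,
                     base = ctx$base, k = ctx$k))
  list(score = sc, n_m = n_m, presence = pres, counts = counts)
}

# Pearson correlation of two density profiles; NA (excluded) if either
# has zero variance.
profile_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' One generalization move
#'
#' Evaluates all one-position generalizations of `current`, discards
#' candidates whose density profile has Pearson correlation below `alpha`
#' with the ORIGINAL seed's profile (or zero variance), and returns the
#' best-scoring candidate if it strictly improves on `current_score`
#' (ties broken by motif string order).
#'
#' @param current IUPAC motif string.
#' @param current_score Its score.
#' @param seed_counts Density-profile counts of the original seed.
#' @param alpha Correlation threshold in [0, 1] (default 0.75).
#' @param ctx A `score_context`.
#' @return List (motif, score, n_m, presence, counts) or NULL if no
#'   candidate qualifies and improves.
#' @export
generalize_step <- function(current, current_score, seed_counts, alpha, ctx) {
  cands <- generalizations_of(current)
  best <- NULL
  for (m in cands) {
    sc <- motif_score(m, ctx)
    r <- profile_cor(sc$counts, seed_counts)
    if (is.na(r) || r < alpha) next
    if (sc$score > current_score &&
        (is.null(best) || sc$score > best$score ||
         (sc$score == best$score && m < best$motif))) {
      best <- c(list(motif = m), sc)
    }
  }
  best
}

#' One elongation move
#'
#' Evaluates `current` with each of the 15 IUPAC symbols prepended or
#' appended (no correlation gate: elongation can only shrink the word
#' set); returns the best strict improvement, or NULL. Motifs at
#' `max_len` are not elongated.
#'
#' @param current IUPAC motif string.
#' @param current_score Its score.
#' @param max_len Maximum motif length (default 9, at most 15).
#' @param ctx A `score_context`.
#' @return List (motif, score, n_m, presence, counts) or NULL.
#' @export
elongate_step <- function(current, current_score, max_len, ctx) {
  if (nchar(current) >= max_len) return(NULL)
  syms <- names(IUPAC_MASK)
  cands <- sort(c(paste0(syms, current), paste0(current, syms)))
  best <- NULL
  for (m in cands) {
    sc <- motif_score(m, ctx)
    if (sc$score > current_score &&
        (is.null(best) || sc$score > best$score ||
         (sc$score == best$score && m < best$motif))) {
      best <- c(list(motif = m), sc)
    }
  }
  best
}

#' Greedy optimization of a seed
#'
#' Repeats [generalize_step()] until no generalization passes the alpha
#' gate and strictly improves the score, then repeats [elongate_step()]
#' likewise. The score sequence is strictly increasing, so the procedure
#' terminates at a local maximum. Each seed is optimized independently of
#' all other seeds.
#'
#' @param seed Non-degenerate q-mer (a selected seed).
#' @param ctx A `score_context`.
#' @param alpha Density-correlation threshold for generalization
#'   (default 0.75).
#' @param max_len Maximum motif length (default 9, at most 15).
#' @return List of class `optimized_motif`: `motif`, `score`, `seed`,
#'   `seed_score`, `n_m`, `presence`, `counts`, and `trace`, a data.frame
#'   of accepted moves (iteration, motif, score, move).
#' @export
optimize_seed <- function(seed, ctx, alpha = 0.75, max_len = 9L) {
  if (max_len > 15L) stop("max_len cannot exceed 15")
  cur <- c(list(motif = as_motif(seed)), motif_score(seed, ctx))
  seed_counts <- cur$counts
  trace <- data.frame(iteration = 0L, motif = cur$motif, score = cur$score,
                      move = "seed", stringsAsFactors = FALSE)
  it <- 0L
  repeat {
    nxt <- generalize_step(cur$motif, cur$score, seed_counts, alpha, ctx)
    if (is.null(nxt)) break
    it <- it + 1L
    cur <- nxt
    trace <- rbind(trace, data.frame(iteration = it, motif = cur$motif,
                                     score = cur$score, move = "generalize",
                                     stringsAsFactors = FALSE))
  }
  repeat {
    nxt <- elongate_step(cur$motif, cur$score, max_len, ctx)
    if (is.null(nxt)) break
    it <- it + 1L
    cur <- nxt
    trace <- rbind(trace, data.frame(iteration = it, motif = cur$motif,
                                     score = cur$score, move = "elongate",
                                     stringsAsFactors = FALSE))
  }
  structure(list(motif = cur$motif, score = cur$score, seed = seed,
                 seed_score = trace$score[1L], n_m = cur$n_m,
                 presence = cur$presence, counts = cur$counts,
                 trace = trace),
            class = "optimized_motif")
}

#' @export
#' @method print optimized_motif
print.optimized_motif <- function(x, ...) {
  cat("optimized motif: ", x$motif, " (seed ", x$seed, "), score ",
      format(x$score, digits = 4), ", n_m = ", x$n_m, "\n", sep = "")
  invisible(x)
}
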