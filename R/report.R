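# Per-motif reports: sign tests, positional histograms, expression
# heatmaps and gene lists ranked by density z-score.

#' Exact two-sided sign test
#'
#' Binomial test with success probability 1/2 on `wins` out of
#' `wins + losses` (ties must be excluded before the call); the two-sided
#' P value doubles the smaller exact tail and is capped at 1.
#'
#' @param wins,losses Non-negative integers, wins + losses >= 1.
#' @return Two-sided P value.
#' @examples
#' sign_test(18, 2)  # 0.0004
#' @export
sign_test <- function(wins, losses) {
  stopifnot(wins >= 0, losses >= 0)
  n <- wins + losses
  if (n < 1) stop("wins + losses must be >= 1")
  up <- stats::pbinom(wins - 1, n, 0.5, lower.tail = FALSE)  # P(X >= wins)
  down <- stats::pbinom(wins, n, 0.5)                        # P(X <= wins)
  min(1, 2 * min(up, down))
}

#' Strand bias of a motif's occurrences
#'
#' Sign test on the forward vs reverse occurrence counts.
#'
#' @param occ Occurrence table from [scan_occurrences()].
#' @return List with `p_value`, `direction` ("+", "-" or "none"),
#'   `n_forward`, `n_reverse`.
#' @export
strand_bias <- function(occ) {
  if (!nrow(occ)) stop("no occurrences: strand bias undefined")
  nf <- sum(occ$strand == "+")
  nr <- sum(occ$strand == "-")
  list(p_value = sign_test(nf, nr),
       direction = if (nf > nr) "+" else if (nr > nf) "-" else "none",
       n_forward = nf, n_reverse = nr)
}

#' Positional histogram of motif occurrences
#'
#' Distances are measured from the codon-proximal end of the stored
#' sequence: for upstream regions, from the 3' end (the start codon); for
#' downstream regions, from the 5' end (the stop codon). An occurrence
#' flush against the codon falls in bin 0.
#'
#' @param occ Occurrence table from [scan_occurrences()].
#' @param seqs Sequence collection the occurrences were found in (its
#'   `region` attribute selects the anchor).
#' @param bin_width Bin width in bp (default 50).
#' @param per_gene Count genes-with-occurrence instead of occurrences in
#'   each bin (default FALSE: occurrences are counted).
#' @return data.frame (bin_start, bin_end, count); total count equals the
#'   number of occurrences (or of gene-bin pairs when `per_gene`).
#' @export
position_histogram <- function(occ, seqs, bin_width = 50L, per_gene = FALSE) {
  if (bin_width < 1L) stop("bin_width must be >= 1")
  region <- attr(seqs, "region") %||% "upstream"
  lens <- nchar(seqs)[occ$gene_id]
  dist <- if (region == "upstream") lens - occ$end else occ$start
  if (per_gene) {
    keep <- !duplicated(paste(occ$gene_id, dist %/% bin_width))
    dist <- dist[keep]
  }
  if (!length(dist))
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  bins <- dist %/% bin_width
  tab <- tabulate(bins + 1L, nbins = max(bins) + 1L)
  data.frame(bin_start = (seq_along(tab) - 1L) * bin_width,
             bin_end = seq_along(tab) * bin_width,
             count = tab)
}

#' Motif density heatmap over the expression space
#'
#' For each condition, genes are assigned to `n_bins` equal-width bins
#' over that condition's expression range (equal-frequency bins with
#' `binning = "frequency"`); each cell's value is the density z-score of
#' the motif-positive count among the genes in the cell. Empty cells are
#' NA.
#'
#' @param presence Named 0/1 vector per gene.
#' @param X Expression matrix (same genes, same order).
#' @param n_bins Number of expression-level bins (default 25).
#' @param binning "width" (equal-width, default) or "frequency".
#' @return n_bins x conditions matrix of z-scores (rows = bins from low
#'   to high expression).
#' @export
expression_heatmap <- function(presence, X, n_bins = 25L,
                               binning = c("width", "frequency")) {
  binning <- match.arg(binning)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (length(presence) != nrow(X))
    stop("presence and expression cover different gene universes")
  n <- nrow(X)
  n_m <- sum(presence)
  Z <- matrix(NA_real_, nrow = n_bins, ncol = ncol(X),
              dimnames = list(NULL, colnames(X)))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    brk <- if (binning == "width") {
      if (diff(range(x)) == 0) next            # constant condition: flagged NA
      seq(min(x), max(x), length.out = n_bins + 1L)
    } else {
      unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
    }
    cell <- cut(x, breaks = brk, include.lowest = TRUE, labels = FALSE)
    for (b in seq_len(n_bins)) {
      in_cell <- which(cell == b)
      if (!length(in_cell)) next
      Z[b, j] <- density_zscore(sum(presence[in_cell]), length(in_cell),
                                n_m, n)
    }
  }
  Z
}

#' Genes possessing a motif, ranked by density z-score
#'
#' Each gene's neighborhood count is standardized with [density_zscore()];
#' genes that possess the motif are listed in decreasing z-score order. A
#' positive z-score means the neighborhood's motif proportion exceeds the
#' genome-wide expectation, flagging occurrences that are more likely
#' functional.
#'
#' @param profile A `density_profile` for the motif.
#' @param presence Named 0/1 vector per gene (same universe).
#' @return data.frame (gene_id, count, density, zscore) with
#'   sum(presence) rows.
#' @export
ranked_gene_list <- function(profile, presence) {
  stopifnot(inherits(profile, "density_profile"))
  if (length(presence) != length(profile$gene_ids))
    stop("presence and profile cover different gene universes")
  n <- length(presence)
  n_m <- sum(presence)
  z <- density_zscore(profile$counts, profile$k, n_m, n)
  keep <- which(presence == 1L)
  d <- data.frame(gene_id = profile$gene_ids[keep],
                  count = profile$counts[keep],
                  density = profile$densities[keep],
                  zscore = z[keep], stringsAsFactors = FALSE)
  d <- d[order(-d$zscore, d$gene_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}
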