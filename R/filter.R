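# Redundancy filtering: ungapped IUPAC overlap plus density-profile
# correlation, greedy retention by score.

#' Ungapped overlap between two IUPAC motifs
#'
#' The maximum number of positions that can be aligned without internal
#' gaps such that every aligned symbol pair has a non-empty IUPAC
#' intersection (degenerate matches such as N-N count); 0 if no offset
#' aligns fully. In `strands = "both"` mode the reverse complement of the
#' second motif is also tried.
#'
#' @param a,b IUPAC motif strings.
#' @param strands "forward" or "both".
#' @return Integer overlap, bounded by min(nchar(a), nchar(b)).
#' @examples
#' overlap("WAGACA", "TATAGA") # 4
#' @export
overlap <- function(a, b, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  best <- overlap_one(as_motif(a), as_motif(b))
  if (strands == "both")
    best <- max(best, overlap_one(a, reverse_complement_motif(b)))
  best
}

overlap_one <- function(a, b) {
  ma <- motif_masks(a)
  mb <- motif_masks(b)
  la <- length(ma)
  lb <- length(mb)
  best <- 0L
  for (off in (-(lb - 1L)):(la - 1L)) {   # position of b[1] relative to a[1]
    ia <- max(1L, off + 1L):min(la, off + lb)
    ib <- ia - off
    if (all(bitwAnd(ma[ia], mb[ib]) > 0L)) best <- max(best, length(ia))
  }
  best
}

#' Are two motifs redundant?
#'
#' True iff their ungapped overlap is at least `min_overlap` AND the
#' Pearson correlation between their density profiles is at least
#' `gamma`. A zero-variance profile makes the correlation undefined and
#' is treated as 0 (never redundant on the correlation side), with a
#' message.
#'
#' @param a,b IUPAC motif strings.
#' @param profile_a,profile_b Density-profile count vectors.
#' @param gamma Correlation threshold (default 0.75).
#' @param min_overlap Overlap threshold (default 4).
#' @param strands "forward" or "both" for the overlap computation.
#' @return Logical.
#' @export
is_redundant <- function(a, b, profile_a, profile_b, gamma = 0.75,
                         min_overlap = 4L, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (overlap(a, b, strands) < min_overlap) return(FALSE)
  r <- profile_cor(profile_a, profile_b)
  if (is.na(r)) {
    message("zero-variance density profile; correlation treated as 0")
    r <- 0
  }
  r >= gamma
}

#' Greedy redundancy filtering of optimized motifs
#'
#' Sorts motifs by score descending (ties by motif string) and accepts
#' each in turn iff it is not redundant with any already-accepted motif.
#'
#' @param motifs Character vector of IUPAC motifs.
#' @param scores Numeric scores, same length.
#' @param profiles Matrix of density-profile counts, one column per
#'   motif (genes in rows).
#' @param gamma,min_overlap,strands See [is_redundant()].
#' @return Integer vector of accepted indices into `motifs`, in
#'   acceptance (score) order.
#' @export
filter_motifs <- function(motifs, scores, profiles, gamma = 0.75,
                          min_overlap = 4L, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  stopifnot(length(motifs) == length(scores),
            ncol(profiles) == length(motifs))
  ord <- order(-scores, motifs)
  kept <- integer(0)
  for (i in ord) {
    red <- FALSE
    for (j in kept) {
      if (is_redundant(motifs[i], motifs[j], profiles[, i], profiles[, j],
                       gamma, min_overlap, strands)) {
        red <- TRUE
        break
      }
    }
    if (!red) kept <- c(kept, i)
  }
  kept
}
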