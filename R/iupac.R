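# IUPAC degenerate DNA alphabet: each code denotes a non-empty subset of
# {A,C,G,T}, encoded here as a 4-bit mask (A=1, C=2, G=4, T=8).

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

# reverse lookup: symbol for each mask 1..15
IUPAC_SYMBOL <- character(15L)
IUPAC_SYMBOL[IUPAC_MASK] <- names(IUPAC_MASK)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# nucleotides denoted by each symbol
IUPAC_SET <- lapply(IUPAC_MASK, function(m) {
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
})

#' Validate an IUPAC motif string
#'
#' A motif is a non-empty string over the 15-letter IUPAC DNA alphabet
#' (A, C, G, T, R, Y, S, W, K, M, B, D, H, V, N). It denotes the finite set
#' of exact words obtained by choosing, at every position, one nucleotide
#' from the set the symbol stands for.
#'
#' @param motif Character scalar, the candidate motif.
#' @return The motif, upper-cased, invisibly usable as a valid motif.
#' @examples
#' as_motif("wagaca")
#' @export
as_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif))
    stop("motif must be a single character string")
  m <- toupper(motif)
  if (nchar(m) < 1L) stop("motif must have length >= 1")
  syms <- motif_symbols(m)
  bad <- setdiff(unique(syms), names(IUPAC_MASK))
  if (length(bad))
    stop("invalid IUPAC symbol(s) in motif: ", paste(bad, collapse = ", "))
  m
}

motif_symbols <- function(motif) strsplit(motif, "", fixed = TRUE)[[1L]]

motif_masks <- function(motif) unname(IUPAC_MASK[motif_symbols(motif)])

#' Number of exact words a motif denotes
#'
#' Product over positions of the cardinality of each symbol's nucleotide set.
#'
#' @param motif IUPAC motif string.
#' @return Integer-valued numeric, the size of the denoted word set.
#' @export
motif_cardinality <- function(motif) {
  motif <- as_motif(motif)
  prod(vapply(IUPAC_SET[motif_symbols(motif)], length, 1L))
}

#' Expand an IUPAC motif into its exact words
#'
#' Returns every word in the Cartesian product of the per-symbol nucleotide
#' sets; e.g. WAGACA expands to AAGACA and TAGACA.
#'
#' @param motif IUPAC motif string.
#' @return Character vector of exact DNA words, sorted.
#' @examples
#' expand_motif("WAGACA")
#' @export
expand_motif <- function(motif) {
  motif <- as_motif(motif)
  sets <- IUPAC_SET[motif_symbols(motif)]
  if (prod(vapply(sets, length, 1L)) > 4^15)
    stop("motif expansion too large")
  grid <- do.call(expand.grid, c(rev(unname(sets)),
                                 list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  sort(do.call(paste0, rev(grid)))
}

#' Reverse complement of an IUPAC motif
#'
#' Symbol-wise IUPAC complement with the order of positions reversed; an
#' involution on motifs.
#'
#' @param motif IUPAC motif string.
#' @return The reverse-complement motif string.
#' @examples
#' reverse_complement_motif("WAGACA") # TGTCTW
#' @export
reverse_complement_motif <- function(motif) {
  motif <- as_motif(motif)
  paste(rev(unname(IUPAC_COMPLEMENT[motif_symbols(motif)])), collapse = "")
}

# fast reverse complement for vectors of plain ACGT(N) words
revcomp_words <- function(words) {
  if (!length(words)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
}

#' One-step generalizations of a motif
#'
#' For every position holding a single nucleotide, emit one candidate motif
#' per IUPAC symbol that strictly contains that nucleotide (7 symbols per
#' base, N included). Positions that are already degenerate are never
#' modified, so the candidate set for WAGACA has 5 x 7 = 35 members and
#' contains WWGACA, WHGACA and WARACA.
#'
#' @param motif IUPAC motif string.
#' @return Character vector of candidate motifs (possibly empty), sorted.
#' @export
generalizations_of <- function(motif) {
  motif <- as_motif(motif)
  syms <- motif_symbols(motif)
  masks <- unname(IUPAC_MASK[syms])
  out <- character(0)
  for (i in seq_along(syms)) {
    if (bitwAnd(masks[i], masks[i] - 1L) != 0L) next  # degenerate: >1 bit set
    sup <- IUPAC_SYMBOL[which(bitwAnd(1:15, masks[i]) == masks[i])]
    sup <- setdiff(sup, syms[i])
    for (s in sup) {
      cand <- syms
      cand[i] <- s
      out <- c(out, paste(cand, collapse = ""))
    }
  }
  sort(out)
}

# PCRE for a motif: character classes per position; masked N in the input
# sequence matches nothing because N is absent from every class.
motif_regex <- function(motif, lookahead = TRUE) {
  sets <- IUPAC_SET[motif_symbols(as_motif(motif))]
  body <- paste(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
  if (lookahead) paste0("(?=", body, ")") else body
}
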