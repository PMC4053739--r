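# Sequence records and IUPAC occurrence scanning.
#
# A sequence collection is a named character vector (names = gene IDs,
# values = DNA strings over A/C/G/T/N) carrying a "region" attribute,
# either "upstream" or "downstream". Masked bases (N) never match any
# motif symbol.

#' Build a sequence record collection
#'
#' @param seqs Named character vector of DNA sequences; names are gene IDs
#'   and must be unique.
#' @param region Either "upstream" or "downstream"; controls how positional
#'   distances are anchored (start vs stop codon).
#' @return The validated, upper-cased named vector with a `region` attribute.
#' @export
sequence_records <- function(seqs, region = c("upstream", "downstream")) {
  region <- match.arg(region)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique gene IDs as names")
  if (any(!nzchar(seqs))) stop("empty sequence(s): ",
                               paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  s <- toupper(seqs)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  attr(s, "region") <- region
  s
}

#' Read gene sequences from a FASTA file
#'
#' @param path FASTA file, one record per gene; record names are gene IDs
#'   (first whitespace-delimited token).
#' @param region Region kind, "upstream" (default) or "downstream".
#' @return A sequence record collection (see [sequence_records()]).
#' @export
read_sequences <- function(path, region = c("upstream", "downstream")) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  sequence_records(stats::setNames(as.character(x), ids), match.arg(region))
}

#' Write gene sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
}

#' Scan a sequence collection for occurrences of an IUPAC motif
#'
#' Every maximal window whose bases all lie in the IUPAC set of the aligned
#' motif symbol is reported; overlapping occurrences are allowed. With
#' `strands = "both"` the reverse-complement motif is additionally scanned
#' on the stored (forward) sequence and reported with strand "-"; a motif
#' that equals its own reverse complement is scanned once per window.
#'
#' @param motif IUPAC motif string.
#' @param seqs Named character vector of sequences (or a single unnamed
#'   sequence).
#' @param strands "forward" or "both".
#' @param context Number of flanking bases reported on each side of a match
#'   (truncated at sequence ends). Default 10.
#' @return A data.frame with columns gene_id, start (0-based), end
#'   (half-open), strand, word (forward-strand text of the match), context.
#' @examples
#' scan_occurrences("WAGACA", c(g1 = "TTAGACAT"))
#' @export
scan_occurrences <- function(motif, seqs, strands = c("both", "forward"),
                             context = 10L) {
  strands <- match.arg(strands)
  motif <- as_motif(motif)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  pats <- list(`+` = motif_regex(motif))
  rc <- reverse_complement_motif(motif)
  if (strands == "both" && rc != motif) pats$`-` <- motif_regex(rc)
  w <- nchar(motif)
  out <- vector("list", length(seqs) * length(pats))
  idx <- 0L
  for (g in seq_along(seqs)) {
    s <- seqs[[g]]
    L <- nchar(s)
    if (L < w) next
    for (st in names(pats)) {
      m <- gregexpr(pats[[st]], s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      start1 <- as.integer(m)            # 1-based start of each window
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        gene_id = names(seqs)[g],
        start = start1 - 1L,
        end = start1 - 1L + w,
        strand = st,
        word = substring(s, start1, start1 + w - 1L),
        context = substring(s, pmax(1L, start1 - context),
                            pmin(L, start1 + w - 1L + context)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (idx == 0L)
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      word = character(0), context = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(idx)])
  res <- res[order(match(res$gene_id, names(seqs)), res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Binary presence of a motif across a sequence collection
#'
#' A gene is marked 1 if the motif occurs at least once in its sequence
#' (on the requested strands), regardless of the occurrence count.
#'
#' @inheritParams scan_occurrences
#' @return Named integer vector of 0/1 per gene, in input order.
#' @export
presence_matrix <- function(motif, seqs, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  motif <- as_motif(motif)
  hit <- grepl(motif_regex(motif, lookahead = FALSE), seqs, perl = TRUE)
  if (strands == "both") {
    rc <- reverse_complement_motif(motif)
    if (rc != motif)
      hit <- hit | grepl(motif_regex(rc, lookahead = FALSE), seqs, perl = TRUE)
  }
  stats::setNames(as.integer(hit), names(seqs))
}

#' Export occurrences as a BED-like TSV
#'
#' @param occ Occurrence table from [scan_occurrences()].
#' @param path Output file.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.table(occ, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
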