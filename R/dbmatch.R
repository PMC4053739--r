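# Evaluation against a motif database: PWM conversion, column-correlation
# alignment scoring, column-shuffle null P values, BH selection and
# redundancy-aware best-match counting.
#
# A PWM is a 4 x w numeric matrix (rows A, C, G, T; columns sum to 1).

#' Convert an IUPAC motif to a PWM
#'
#' Each symbol maps to the uniform distribution over its nucleotide set:
#' 'A' becomes (1,0,0,0), 'W' becomes (0.5,0.5,0,0), etc.
#'
#' @param motif IUPAC motif string.
#' @return 4 x w matrix with rownames A,C,G,T.
#' @export
iupac_to_pwm <- function(motif) {
  motif <- as_motif(motif)
  masks <- motif_masks(motif)
  cols <- vapply(masks, function(m) {
    v <- as.numeric(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
    v / sum(v)
  }, numeric(4))
  rownames(cols) <- c("A", "C", "G", "T")
  cols
}

pwm_revcomp <- function(pwm) pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]

# columns standardized to zero mean / unit norm; all-equal columns map to
# the zero vector so their correlation contribution is 0
standardize_cols <- function(pwm) {
  x <- sweep(pwm, 2L, colMeans(pwm))
  nrm <- sqrt(colSums(x^2))
  nz <- nrm > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2L, nrm[nz], "/")
  x
}

#' Ungapped alignment score between two PWMs
#'
#' Maximum, over all ungapped offsets with at least `min_cols` aligned
#' columns (and over both orientations of the target when
#' `strands = "both"`), of the sum over aligned positions of the Pearson
#' correlation between the two 4-entry probability columns. Columns with
#' zero variance contribute 0.
#'
#' @param q Query PWM (4 x wq).
#' @param t Target PWM (4 x wt).
#' @param min_cols Minimum aligned columns (default 4; capped at the
#'   shorter motif's width).
#' @param strands "both" or "forward".
#' @return List with `score`, `offset` (position of target column 1
#'   relative to query column 1) and `orientation` ("+" or "-").
#' @export
align_score <- function(q, t, min_cols = 4L, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  min_cols <- min(min_cols, ncol(q), ncol(t))
  qs <- standardize_cols(q)
  best <- list(score = -Inf, offset = 0L, orientation = "+")
  for (ori in if (strands == "both") c("+", "-") else "+") {
    ts <- standardize_cols(if (ori == "+") t else pwm_revcomp(t))
    R <- crossprod(qs, ts)                    # column-correlation matrix
    wq <- ncol(qs); wt <- ncol(ts)
    for (off in (-(wt - min_cols)):(wq - min_cols)) {
      iq <- max(1L, off + 1L):min(wq, off + wt)
      sc <- sum(R[cbind(iq, iq - off)])
      if (sc > best$score)
        best <- list(score = sc, offset = off, orientation = ori)
    }
  }
  best
}

#' Column-shuffle null P values against a motif database
#'
#' The query is aligned to every database motif; the best observed score
#' per target is compared with a null built by shuffling all PWM columns
#' across the whole database (target lengths preserved;
#' `scope = "within"` restricts the shuffle to each motif's own columns).
#' For each target, P = (1 + #{null best score >= observed}) /
#' (1 + n_shuffles), where the null best score is taken over the entire
#' shuffled database.
#'
#' @param q Query PWM.
#' @param db Named list of target PWMs.
#' @param n_shuffles Shuffle rounds (>= 100; default 1000).
#' @param seed Integer seed.
#' @param min_cols,strands Passed to [align_score()].
#' @param scope "pool" (default) or "within".
#' @return data.frame (target, score, offset, orientation, p_value),
#'   one row per database motif.
#' @export
match_pvalue <- function(q, db, n_shuffles = 1000L, seed = 1L,
                         min_cols = 4L, strands = c("both", "forward"),
                         scope = c("pool", "within")) {
  strands <- match.arg(strands)
  scope <- match.arg(scope)
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  obs <- lapply(db, align_score, q = q, min_cols = min_cols, strands = strands)
  widths <- vapply(db, ncol, 0L)
  pool <- do.call(cbind, unname(db))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  null_best <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    if (scope == "pool") {
      perm <- sample.int(ncol(pool))
      shuffled <- pool[, perm, drop = FALSE]
      ends <- cumsum(widths)
      starts <- ends - widths + 1L
      sdb <- lapply(seq_along(db), function(j)
        shuffled[, starts[j]:ends[j], drop = FALSE])
    } else {
      sdb <- lapply(db, function(p)
        p[, sample.int(ncol(p)), drop = FALSE])
    }
    null_best[s] <- max(vapply(sdb, function(t)
      align_score(q, t, min_cols, strands)$score, 0))
  }
  data.frame(target = names(db),
             score = vapply(obs, `[[`, 0, "score"),
             offset = vapply(obs, `[[`, 0L, "offset"),
             orientation = vapply(obs, `[[`, "", "orientation"),
             p_value = vapply(obs, function(o)
               (1 + sum(null_best >= o$score)) / (1 + n_shuffles), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count significant, non-redundant database matches for a set of queries
#'
#' Each query's best match is its minimum-P database motif (ties by score
#' descending, then target name). Benjamini-Hochberg step-up is applied
#' over the queries' best P values at level `fdr`; when several
#' significant queries share the same best target, only the query with
#' the lowest P counts and the others are treated as having no match.
#'
#' @param queries Named list of query PWMs (or IUPAC strings, converted
#'   via [iupac_to_pwm()]).
#' @param db Named list of target PWMs.
#' @param fdr BH level (default 0.15).
#' @param ... Passed to [match_pvalue()].
#' @return List with `count` (number of counted matches) and `table`, a
#'   per-query data.frame (query, target, score, p_value, bh_significant,
#'   counted).
#' @export
benchmark_matches <- function(queries, db, fdr = 0.15, ...) {
  if (!length(queries))
    return(list(count = 0L,
                table = data.frame(query = character(0), target = character(0),
                                   score = numeric(0), p_value = numeric(0),
                                   bh_significant = logical(0),
                                   counted = logical(0))))
  if (is.character(queries))
    queries <- stats::setNames(lapply(queries, iupac_to_pwm),
                               names(queries) %||% queries)
  best <- lapply(queries, function(q) {
    m <- match_pvalue(q, db, ...)
    m <- m[order(m$p_value, -m$score, m$target), , drop = FALSE]
    m[1L, ]
  })
  tab <- do.call(rbind, best)
  tab <- data.frame(query = names(queries), tab[, c("target", "score", "p_value")],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$bh_significant <- stats::p.adjust(tab$p_value, method = "BH") <= fdr
  tab$counted <- FALSE
  sig <- which(tab$bh_significant)
  if (length(sig)) {
    sig <- sig[order(tab$p_value[sig], sig)]
    seen <- character(0)
    for (i in sig) {
      if (!tab$target[i] %in% seen) {
        tab$counted[i] <- TRUE
        seen <- c(seen, tab$target[i])
      }
    }
  }
  list(count = sum(tab$counted), table = tab)
}

#' Read a MEME minimal-format motif file
#'
#' Parses the letter-probability matrices of a minimal MEME text file
#' into a named list of 4 x w PWMs (rows A, C, G, T).
#'
#' @param path Input file.
#' @return Named list of PWMs.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  midx <- grep("^MOTIF\\s+", lines)
  if (!length(midx)) stop("no MOTIF entries in ", path)
  out <- list()
  for (i in seq_along(midx)) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[midx[i]])), "\\s+")[[1L]][1L]
    hdr <- grep("letter-probability matrix", lines)
    hdr <- hdr[hdr > midx[i]][1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    pwm <- t(do.call(rbind, vals))
    rownames(pwm) <- c("A", "C", "G", "T")
    out[[name]] <- pwm
  }
  out
}

#' Write motifs as a MEME minimal-format file
#'
#' @param pwms Named list of PWMs (or IUPAC strings, converted first).
#' @param path Output file.
#' @param bg Background letter frequencies (A, C, G, T).
#' @export
write_meme <- function(pwms, path, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (is.character(pwms))
    pwms <- stats::setNames(lapply(pwms, iupac_to_pwm), names(pwms) %||% pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(p)), con)
    writeLines(apply(p, 2L, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
}
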