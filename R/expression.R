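# Expression matrix handling, kNN graphs and the hubness-corrected
# balanced neighbor graph.
#
# A neighbor graph is a list with fields
#   k        neighbors per gene (requested size)
#   stage    "knn", "symmetrized" or "balanced"
#   gene_ids character vector (n)
#   nbrs     list of integer vectors, out-neighbors per gene
# In the "knn" and "balanced" stages every gene has exactly k out-neighbors,
# never itself and no duplicates; the "symmetrized" stage has variable
# out-degree (>= k) and in-degree >= k for every gene.

#' Read an expression matrix from TSV
#'
#' Expects a header row of condition names and gene IDs in the first
#' column. Rows with missing values are dropped (with a message).
#'
#' @param path Tab-separated text file.
#' @return Numeric matrix, rownames = gene IDs, colnames = conditions.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  X <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  if (anyDuplicated(ids)) stop("duplicate gene IDs in expression matrix")
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    message(sum(!keep), " gene(s) dropped for missing expression values")
    X <- X[keep, , drop = FALSE]
  }
  X
}

#' Write an expression matrix as TSV
#' @param X Numeric matrix with gene IDs as rownames.
#' @param path Output file.
#' @export
write_expression <- function(X, path) {
  d <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Pairwise distances between expression profiles
#'
#' @param X Numeric matrix, genes in rows.
#' @param metric "euclidean" (L2 between rows) or "pearson"
#'   (1 - Pearson correlation between rows).
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distance <- function(X, metric = c("euclidean", "pearson")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(X, method = "euclidean"))
  } else {
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0)) {
      bad <- rownames(X)[sds == 0]
      cond <- simpleError(paste0("zero-variance profile(s) with pearson metric: ",
                                 paste(bad, collapse = ", ")))
      attr(cond, "genes") <- bad
      stop(cond)
    }
    D <- 1 - stats::cor(t(X))
    diag(D) <- 0
  }
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' k-nearest-neighbor graph over genes
#'
#' Arc g -> g' whenever g' is among the k nearest other genes of g;
#' distance ties are broken by gene input order, and a gene is never its
#' own neighbor.
#'
#' @param X Expression matrix (genes x conditions), or a precomputed
#'   distance matrix if `is_distance = TRUE`.
#' @param k Neighborhood size; must satisfy k < n.
#' @param metric Distance metric, see [pairwise_distance()].
#' @param is_distance Interpret `X` as a distance matrix.
#' @return A neighbor graph at stage "knn".
#' @export
knn_graph <- function(X, k = 200L, metric = c("euclidean", "pearson"),
                      is_distance = FALSE) {
  D <- if (is_distance) X else pairwise_distance(X, metric)
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n (n = ", n, ")")
  nbrs <- vector("list", n)
  seq_n <- seq_len(n)
  for (i in seq_n) {
    d <- D[i, ]
    d[i] <- Inf                       # never a self-neighbor
    nbrs[[i]] <- order(d, seq_n, method = "radix")[seq_len(k)]
  }
  structure(list(k = k, stage = "knn",
                 gene_ids = rownames(D) %||% as.character(seq_n),
                 nbrs = nbrs),
            class = "neighbor_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print neighbor_graph
print.neighbor_graph <- function(x, ...) {
  cat("neighbor graph (", x$stage, "): ", length(x$gene_ids),
      " genes, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Symmetrize a kNN graph
#'
#' Adds the reverse of every arc, so that each gene lies in the
#' neighborhood of at least k other genes (in-degree >= k).
#'
#' @param g Neighbor graph at stage "knn".
#' @return Neighbor graph at stage "symmetrized".
#' @export
symmetrize <- function(g) {
  stopifnot(inherits(g, "neighbor_graph"))
  if (g$stage != "knn") stop("symmetrize expects a graph at stage 'knn'")
  n <- length(g$gene_ids)
  from <- rep.int(seq_len(n), lengths(g$nbrs))
  to <- unlist(g$nbrs, use.names = FALSE)
  rev_lists <- split(from, factor(to, levels = seq_len(n)))
  nbrs <- lapply(seq_len(n), function(i)
    sort(unique(c(g$nbrs[[i]], rev_lists[[i]]))))
  structure(list(k = g$k, stage = "symmetrized", gene_ids = g$gene_ids,
                 nbrs = nbrs),
            class = "neighbor_graph")
}

#' In-degree of every gene in a neighbor graph
#' @param g Neighbor graph.
#' @return Integer vector of in-degrees, one per gene.
#' @export
in_degrees <- function(g) {
  tabulate(unlist(g$nbrs, use.names = FALSE), nbins = length(g$gene_ids))
}

#' Balanced neighbor sampling (hubness correction)
#'
#' From the symmetrized graph, draws exactly k neighbors per gene,
#' sequentially without replacement, with probability inversely
#' proportional to each candidate's in-degree in the symmetrized graph
#' (renormalized over the not-yet-chosen candidates of that gene). Genes
#' that sit in many neighborhoods are therefore chosen less often, which
#' flattens the in-degree distribution of the resulting graph.
#'
#' @param gstar Neighbor graph at stage "symmetrized".
#' @param k Neighbors to draw per gene (default: the graph's k).
#' @param seed Integer seed; all draws are reproducible given it.
#' @return Neighbor graph at stage "balanced" with out-degree exactly k.
#' @export
balanced_neighbor_sample <- function(gstar, k = gstar$k, seed = 1L) {
  stopifnot(inherits(gstar, "neighbor_graph"))
  if (gstar$stage != "symmetrized")
    stop("balanced_neighbor_sample expects a graph at stage 'symmetrized'")
  k <- as.integer(k)
  deg <- in_degrees(gstar)          # static: never recomputed during draws
  n <- length(gstar$gene_ids)
  nbrs <- vector("list", n)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (i in seq_len(n)) {
    cand <- gstar$nbrs[[i]]
    if (length(cand) <= k) {
      if (length(cand) < k)
        warning("gene ", gstar$gene_ids[i], " has fewer than k = ", k,
                " candidates; taking all")
      nbrs[[i]] <- cand
    } else {
      nbrs[[i]] <- sort(cand[sample.int(length(cand), k,
                                        prob = 1 / deg[cand])])
    }
  }
  structure(list(k = k, stage = "balanced", gene_ids = gstar$gene_ids,
                 nbrs = nbrs),
            class = "neighbor_graph")
}

# seed handling: set the RNG locally, restore the caller's state after
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# out-adjacency as an n x k index matrix (fixed out-degree stages only)
adj_matrix <- function(g) {
  stopifnot(all(lengths(g$nbrs) == g$k))
  matrix(unlist(g$nbrs, use.names = FALSE), nrow = length(g$nbrs),
         ncol = g$k, byrow = TRUE)
}

#' Export a neighbor graph as an edge list TSV
#' @param g Neighbor graph.
#' @param path Output file.
#' @export
write_graph <- function(g, path) {
  from <- rep.int(g$gene_ids, lengths(g$nbrs))
  to <- g$gene_ids[unlist(g$nbrs, use.names = FALSE)]
  utils::write.table(data.frame(from = from, to = to),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' k-means partition of the expression space (cluster-based baseline)
#'
#' Runs Hartigan-Wong k-means `restarts` times with random initializations
#' and keeps the partition with the lowest within-cluster sum of squares;
#' restarts that end with an empty cluster (or otherwise fail) are redrawn.
#'
#' @param X Expression matrix (genes x conditions).
#' @param k_clusters Number of clusters; must be < n.
#' @param restarts Random restarts (default 100).
#' @param seed Integer seed.
#' @return List with `labels` (integer cluster index per gene, named),
#'   `k_clusters` and `tot_withinss`.
#' @export
kmeans_partition <- function(X, k_clusters, restarts = 100L, seed = 1L) {
  n <- nrow(X)
  if (k_clusters >= n + 1L || k_clusters < 1L) stop("k_clusters must be in [1, n]")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- NULL
    attempts <- 0L
    while (is.null(km) && attempts < 50L) {
      attempts <- attempts + 1L
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = k_clusters, nstart = 1L)),
        error = function(e) NULL)
      if (!is.null(km) && any(km$size == 0L)) km <- NULL
    }
    if (is.null(km)) stop("k-means failed repeatedly (empty clusters)")
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(labels = stats::setNames(as.integer(best$cluster), rownames(X)),
       k_clusters = as.integer(k_clusters),
       tot_withinss = best$tot.withinss)
}
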