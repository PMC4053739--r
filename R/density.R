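# Motif density profiles and the four dependency scores between motif
# presence and expression: discrete (cluster-based) and continuous
# (neighborhood-based) variants of the hypergeometric enrichment and
# mutual-information criteria, plus the density z-score used for ranking
# genes and drawing heatmaps.

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= x) when drawing `draw` genes without replacement from `n` genes
#' of which `n_m` are positive. Evaluated in log space via
#' [stats::phyper()] for numerical stability; `-log` scores are derived
#' from the log-space tail, never from the linear value.
#'
#' @param x Observed count (vectorized).
#' @param n Population size.
#' @param n_m Number of positive genes in the population.
#' @param draw Sample size.
#' @param log.p Return log of the tail probability.
#' @return Tail probability (or its log), same length as `x`.
#' @export
hypergeom_upper_tail <- function(x, n, n_m, draw, log.p = FALSE) {
  stopifnot(n_m >= 0, n_m <= n, draw >= 0, draw <= n)
  lp <- stats::phyper(x - 1, m = n_m, n = n - n_m, k = draw,
                      lower.tail = FALSE, log.p = TRUE)
  lp[x <= 0] <- 0                      # P(X >= 0) = 1
  lp[x > pmin(draw, n_m)] <- -Inf      # impossible counts
  if (log.p) lp else exp(lp)
}

# -log tail in the requested base, from the log-space tail
neg_log_hyper_tail <- function(x, n, n_m, draw, base = exp(1)) {
  -hypergeom_upper_tail(x, n, n_m, draw, log.p = TRUE) / log(base)
}

#' Motif density profile over a neighbor graph
#'
#' For each gene, the number (and fraction) of its k graph neighbors whose
#' sequence contains the motif.
#'
#' @param presence Named 0/1 integer vector (see [presence_matrix()]), in
#'   the graph's gene order.
#' @param graph Neighbor graph at stage "balanced" (or "knn" for
#'   ablation), with fixed out-degree k.
#' @return List of class `density_profile` with fields `gene_ids`,
#'   `counts` (per-gene positive neighbors, 0..k), `k` and `densities`
#'   (= counts / k).
#' @export
density_profile <- function(presence, graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (!graph$stage %in% c("balanced", "knn"))
    stop("density_profile needs a fixed-out-degree graph (stage 'balanced' or 'knn')")
  if (length(presence) != length(graph$gene_ids))
    stop("presence and graph cover different gene universes")
  if (!is.null(names(presence)) &&
      !identical(names(presence), graph$gene_ids))
    stop("presence gene IDs do not match the graph's")
  A <- adj_matrix(graph)
  counts <- as.integer(rowSums(matrix(presence[A], nrow = nrow(A))))
  structure(list(gene_ids = graph$gene_ids, counts = counts, k = graph$k,
                 densities = counts / graph$k),
            class = "density_profile")
}

#' Density z-score
#'
#' Standardized deviation of an observed neighborhood count from its
#' expectation under a random motif distribution, where the count among k
#' sampled genes follows a hypergeometric(n, n_m, k) law:
#' z = (n_mk - k n_m / n) / sqrt(k n_m (n - k)(n - n_m) / (n^2 (n - 1))).
#' Positive values flag neighborhoods with more motif-positive genes than
#' expected.
#'
#' @param n_mk Observed positive count among the k sampled genes
#'   (vectorized).
#' @param k Sample (neighborhood) size, 0 < k < n.
#' @param n_m Total positive genes, 0 < n_m < n.
#' @param n Total genes.
#' @return Numeric z-score(s).
#' @export
density_zscore <- function(n_mk, k, n_m, n) {
  if (k <= 0 || k >= n) stop("k must satisfy 0 < k < n")
  if (n_m <= 0 || n_m >= n)
    stop("density z-score undefined for n_m = ", n_m, " (must be 0 < n_m < n)")
  mu <- k * n_m / n
  v <- k * n_m * (n - k) * (n - n_m) / (n^2 * (n - 1))
  (n_mk - mu) / sqrt(v)
}

#' Discrete (cluster-based) dependency scores
#'
#' Baseline scores computed on a hard partition of the genes: the
#' hypergeometric criterion is the largest cluster-wise enrichment,
#' max over clusters of -log P(X >= n_mc) with draw = n_c; the
#' mutual-information criterion is the plug-in mutual information between
#' motif presence and cluster membership.
#'
#' @param presence Named 0/1 vector per gene.
#' @param labels Integer cluster label per gene (same order), e.g. from
#'   [kmeans_partition()].
#' @param criterion "hypergeometric" or "mutual_information".
#' @param base Logarithm base: natural log for the hypergeometric score,
#'   2 (bits) for mutual information, by default.
#' @return Scalar score (>= 0).
#' @export
score_discrete <- function(presence, labels,
                           criterion = c("mutual_information", "hypergeometric"),
                           base = NULL) {
  criterion <- match.arg(criterion)
  if (length(presence) != length(labels))
    stop("presence and partition cover different gene universes")
  n <- length(presence)
  n_m <- sum(presence)
  labels <- as.factor(labels)       # keeps declared-but-empty clusters
  tab <- table(labels, factor(presence, levels = c(0, 1)))
  n_c <- rowSums(tab)
  if (any(n_c == 0L)) stop("empty cluster in partition")
  n_mc <- tab[, "1"]
  if (criterion == "hypergeometric") {
    base <- base %||% exp(1)
    max(neg_log_hyper_tail(n_mc, n, n_m, n_c, base = base))
  } else {
    base <- base %||% 2
    p_m <- n_m / n
    xlogx <- function(p, q) ifelse(p > 0, p * (log(p) - log(q)), 0)
    joint1 <- n_mc / n
    joint0 <- (n_c - n_mc) / n
    p_c <- n_c / n
    mi <- sum(xlogx(joint1, p_m * p_c) + xlogx(joint0, (1 - p_m) * p_c))
    mi / log(base)
  }
}

#' Continuous (neighborhood-based) dependency scores
#'
#' Clustering-free analogues of the discrete scores, computed from a
#' motif's density profile. The hypergeometric criterion takes, over all
#' genes g, the largest -log P(X >= n_mkg) with draw = k; because the tail
#' shrinks monotonically in the count, this is evaluated at the maximal
#' neighborhood count. The mutual-information criterion estimates
#' I(presence; expression position) by averaging, over genes, the
#' Kullback-Leibler divergence between the local presence distribution
#' (P(M=1|X_g) = n_mkg / k) and the global one (P(M=1) = n_m / n), with
#' 0 log 0 = 0.
#'
#' @param profile A `density_profile` (or a bare integer vector of counts,
#'   in which case `k` must be supplied).
#' @param n_m Total number of motif-positive genes.
#' @param n Total number of genes.
#' @param criterion "hypergeometric" or "mutual_information".
#' @param base Log base; defaults as in [score_discrete()].
#' @param k Neighborhood size when `profile` is a bare count vector.
#' @return Scalar score (>= 0). A degenerate global presence
#'   (n_m = 0 or n_m = n) yields a mutual information of 0, with a message.
#' @export
score_continuous <- function(profile, n_m, n,
                             criterion = c("mutual_information", "hypergeometric"),
                             base = NULL, k = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(profile, "density_profile")) {
    counts <- profile$counts
    k <- profile$k
  } else {
    counts <- profile
    if (is.null(k)) stop("k required when profile is a bare count vector")
  }
  if (length(counts) != n) stop("profile length differs from n")
  if (criterion == "hypergeometric") {
    base <- base %||% exp(1)
    neg_log_hyper_tail(max(counts), n, n_m, k, base = base)
  } else {
    base <- base %||% 2
    p <- n_m / n
    if (p <= 0 || p >= 1) {
      message("degenerate global presence (P(M) = ", p, "); MI set to 0")
      return(0)
    }
    d <- counts / k
    xlogx <- function(a, b) ifelse(a > 0, a * (log(a) - log(b)), 0)
    mean(xlogx(d, p) + xlogx(1 - d, 1 - p)) / log(base)
  }
}
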