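# Full discovery run: graph construction, seed identification, greedy
# refinement, redundancy filtering and per-motif statistics, wrapped in a
# single fitting-style function returning a classed result object.

CONFIG_DEFAULTS <- list(
  q = 7L, k = 200L, n_shuffles = 10L, seed_fdr = 0.001,
  alpha = 0.75, gamma = 0.75, max_len = 9L, min_overlap = 4L,
  criterion = "mutual_information", metric = "euclidean",
  strands = "both", heatmap_bins = 25L
)

#' Validated discovery configuration
#'
#' Fills in defaults (q = 7, k = 200, n_shuffles = 10, seed_fdr = 0.001,
#' alpha = 0.75, gamma = 0.75, max_len = 9, min_overlap = 4,
#' criterion = "mutual_information", metric = "euclidean",
#' strands = "both", heatmap_bins = 25), rejects unknown keys and
#' out-of-range values.
#'
#' @param config Named list of overrides, or a YAML/JSON file path.
#' @return Complete, validated configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  unknown <- setdiff(names(config), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, config)
  chk <- function(ok, key, legal)
    if (!ok) stop("configuration value out of range: ", key,
                  " (legal: ", legal, ")")
  cfg$q <- as.integer(cfg$q); cfg$k <- as.integer(cfg$k)
  cfg$n_shuffles <- as.integer(cfg$n_shuffles)
  cfg$max_len <- as.integer(cfg$max_len)
  cfg$min_overlap <- as.integer(cfg$min_overlap)
  cfg$heatmap_bins <- as.integer(cfg$heatmap_bins)
  chk(cfg$q >= 1 && cfg$q <= 15, "q", "1..15")
  chk(cfg$k >= 1, "k", ">= 1")
  chk(cfg$n_shuffles >= 1, "n_shuffles", ">= 1")
  chk(cfg$seed_fdr > 0 && cfg$seed_fdr <= 1, "seed_fdr", "(0, 1]")
  chk(cfg$alpha >= 0 && cfg$alpha <= 1, "alpha", "[0, 1]")
  chk(cfg$gamma >= 0 && cfg$gamma <= 1, "gamma", "[0, 1]")
  chk(cfg$max_len >= cfg$q && cfg$max_len <= 15, "max_len", "q..15")
  chk(cfg$min_overlap >= 1, "min_overlap", ">= 1")
  chk(cfg$criterion %in% c("mutual_information", "hypergeometric"),
      "criterion", "mutual_information | hypergeometric")
  chk(cfg$metric %in% c("euclidean", "pearson"), "metric",
      "euclidean | pearson")
  chk(cfg$strands %in% c("both", "forward"), "strands", "both | forward")
  chk(cfg$heatmap_bins >= 2, "heatmap_bins", ">= 2")
  cfg
}

#' Clustering-free motif discovery
#'
#' Runs the full discovery pipeline: pairwise distances in expression
#' space, kNN graph, symmetrization, balanced (hubness-corrected)
#' neighbor sampling, exhaustive q-mer scoring, shuffle-FDR seed
#' selection, greedy generalization/elongation of each seed, and
#' redundancy filtering. All randomness derives from `seed` (graph
#' sampling uses seed + 1, the shuffle null seed + 2), so two runs with
#' identical inputs, configuration and seed are identical.
#'
#' @param expression Numeric matrix (genes x conditions, gene IDs as
#'   rownames) or path to a TSV (see [read_expression()]).
#' @param sequences Named character vector of DNA sequences or path to a
#'   FASTA file.
#' @param config Named list of configuration overrides or a YAML file
#'   path; see [load_config()].
#' @param seed Master integer seed.
#' @param region Region kind when `sequences` is a file path.
#' @param verbose Print progress messages.
#' @return Object of class `motif_discovery` with components `motifs`
#'   (data.frame motif, score, seed, seed_score, n_m), `optimized` (all
#'   optimized seeds with traces), `kept` (indices retained by the
#'   filter), `seed_table`, `seeds`, `graph`, `X`, `seqs`, `config`,
#'   `manifest`.
#' @export
discover_motifs <- function(expression, sequences, config = list(),
                            seed = 1L, region = "upstream", verbose = TRUE) {
  cfg <- load_config(config)
  say <- if (verbose) message else function(...) invisible(NULL)
  X <- if (is.character(expression)) read_expression(expression) else expression
  seqs <- if (is.character(sequences) && length(sequences) == 1L &&
              file.exists(sequences)) read_sequences(sequences, region)
          else sequence_records(sequences,
                                attr(sequences, "region") %||% region)
  common <- intersect(rownames(X), names(seqs))
  dropped <- (nrow(X) - length(common)) + (length(seqs) - length(common))
  if (dropped > 0)
    say(dropped, " record(s) without both expression and sequence dropped")
  if (length(common) < cfg$k + 1L)
    stop("fewer than k + 1 = ", cfg$k + 1L, " usable genes (", length(common),
         "); lower k or provide more data")
  region_kind <- attr(seqs, "region")
  X <- X[common, , drop = FALSE]
  seqs <- sequence_records(stats::setNames(seqs[common], common), region_kind)
  n <- length(common)

  say("building neighbor graph (n = ", n, ", k = ", cfg$k, ", ",
      cfg$metric, ")")
  gk <- knn_graph(X, cfg$k, cfg$metric)
  gs <- symmetrize(gk)
  gb <- balanced_neighbor_sample(gs, cfg$k, seed = seed + 1L)

  say("scoring all ", cfg$q, "-mers (", cfg$criterion, ", ",
      cfg$n_shuffles, " shuffles)")
  P <- qmer_presence(seqs, cfg$q, cfg$strands)
  tab <- seed_table(P, gb, cfg$criterion, cfg$n_shuffles, seed = seed + 2L)
  seeds <- select_seeds(tab, cfg$seed_fdr)
  say(nrow(seeds), " seed(s) at FDR < ", cfg$seed_fdr)

  ctx <- score_context(seqs, gb, cfg$criterion, cfg$strands)
  optimized <- lapply(seeds$qmer, optimize_seed, ctx = ctx,
                      alpha = cfg$alpha, max_len = cfg$max_len)
  kept <- integer(0)
  if (length(optimized)) {
    motifs <- vapply(optimized, `[[`, "", "motif")
    scores <- vapply(optimized, `[[`, 0, "score")
    profiles <- vapply(optimized, `[[`, numeric(n), "counts")
    kept <- filter_motifs(motifs, scores, profiles, cfg$gamma,
                          cfg$min_overlap, cfg$strands)
  }
  say(length(kept), " motif(s) after redundancy filtering")

  motif_df <- if (length(kept)) {
    data.frame(motif = vapply(optimized[kept], `[[`, "", "motif"),
               score = vapply(optimized[kept], `[[`, 0, "score"),
               seed = vapply(optimized[kept], `[[`, "", "seed"),
               seed_score = vapply(optimized[kept], `[[`, 0, "seed_score"),
               n_m = vapply(optimized[kept], `[[`, 0L, "n_m"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(motif = character(0), score = numeric(0), seed = character(0),
               seed_score = numeric(0), n_m = integer(0))
  }

  manifest <- list(
    package = "redens",
    version = as.character(utils::packageVersion("redens")),
    config = cfg, seed = seed,
    stage_seeds = list(graph = seed + 1L, shuffles = seed + 2L),
    n_genes = n, n_dropped = dropped, region = region_kind,
    log_base = list(mutual_information = 2, hypergeometric = "e"),
    notes = paste("continuous MI uses P(M=1|Xg) = n_mkg / k (the density",
                  "definition); the printed M=1 numerator n is a known",
                  "erratum")
  )
  structure(list(motifs = motif_df, optimized = optimized, kept = kept,
                 seed_table = tab, seeds = seeds, graph = gb, X = X,
                 seqs = seqs, config = cfg, manifest = manifest),
            class = "motif_discovery")
}

#' @export
#' @method print motif_discovery
print.motif_discovery <- function(x, ...) {
  cat("motif discovery (", x$config$criterion, ", q = ", x$config$q,
      ", k = ", x$config$k, ")\n", sep = "")
  cat("  genes: ", nrow(x$X), "   seeds at FDR < ", x$config$seed_fdr, ": ",
      nrow(x$seeds), "   motifs: ", nrow(x$motifs), "\n", sep = "")
  if (nrow(x$motifs)) {
    cat("  top motifs:\n")
    top <- utils::head(x$motifs, 5L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-15s score %.4f  n_m %d  (seed %s)\n",
                  top$motif[i], top$score[i], top$n_m[i], top$seed[i]))
  }
  invisible(x)
}

#' @export
#' @method summary motif_discovery
summary.motif_discovery <- function(object, ...) {
  out <- list(n_genes = nrow(object$X),
              n_qmers = length(object$seed_table$qmers),
              n_seeds = nrow(object$seeds),
              motifs = object$motifs,
              config = object$config)
  class(out) <- "summary.motif_discovery"
  out
}

#' @export
#' @method print summary.motif_discovery
print.summary.motif_discovery <- function(x, ...) {
  cat("Clustering-free motif discovery\n")
  cat("  genes:", x$n_genes, "  q-mers scored:", x$n_qmers,
      "  seeds:", x$n_seeds, "  motifs:", nrow(x$motifs), "\n\n")
  if (nrow(x$motifs)) print(x$motifs)
  invisible(x)
}

#' Plot a discovered motif's expression-space density heatmap
#'
#' @param x A `motif_discovery` object.
#' @param motif Index or motif string among the filtered motifs
#'   (default 1, the best scoring).
#' @param ... Passed to [graphics::image()].
#' @export
#' @method plot motif_discovery
plot.motif_discovery <- function(x, motif = 1L, ...) {
  if (!nrow(x$motifs)) stop("no motifs to plot")
  if (is.character(motif)) motif <- match(motif, x$motifs$motif)
  m <- x$motifs$motif[motif]
  opt <- x$optimized[[x$kept[motif]]]
  Z <- expression_heatmap(opt$presence, x$X, x$config$heatmap_bins)
  cols <- grDevices::colorRampPalette(c("darkgreen", "white", "darkred"))(51)
  lim <- max(abs(Z), na.rm = TRUE)
  graphics::image(x = seq_len(ncol(Z)), y = seq_len(nrow(Z)), z = t(Z),
                  zlim = c(-lim, lim), col = cols,
                  xlab = "condition", ylab = "expression bin",
                  main = paste("density z-score:", m), ...)
  invisible(Z)
}

#' Write a full per-motif report directory
#'
#' Emits, per filtered motif, a BED-like occurrence TSV, positional
#' histogram TSV, expression heatmap TSV, ranked gene list TSV and a
#' summary JSON; plus the run manifest, the motif table and the seed
#' table at the top level. Output is deterministic given the fitted
#' object.
#'
#' @param fit A `motif_discovery` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(fit, dir) {
  stopifnot(inherits(fit, "motif_discovery"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(fit$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(fit$motifs, file.path(dir, "motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_seed_table(fit$seed_table, file.path(dir, "seed_table.tsv"))
  cfg <- fit$config
  for (i in seq_len(nrow(fit$motifs))) {
    m <- fit$motifs$motif[i]
    opt <- fit$optimized[[fit$kept[i]]]
    mdir <- file.path(dir, sprintf("motif_%02d_%s", i, m))
    dir.create(mdir, showWarnings = FALSE)
    occ <- scan_occurrences(m, fit$seqs, cfg$strands)
    write_occurrences(occ, file.path(mdir, "occurrences.tsv"))
    utils::write.table(position_histogram(occ, fit$seqs),
                       file.path(mdir, "histogram.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    Z <- expression_heatmap(opt$presence, fit$X, cfg$heatmap_bins)
    utils::write.table(Z, file.path(mdir, "heatmap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prof <- structure(list(gene_ids = fit$graph$gene_ids, counts = opt$counts,
                           k = fit$graph$k,
                           densities = opt$counts / fit$graph$k),
                      class = "density_profile")
    utils::write.table(ranked_gene_list(prof, opt$presence),
                       file.path(mdir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sb <- if (nrow(occ)) strand_bias(occ) else
      list(p_value = NA, direction = "none", n_forward = 0L, n_reverse = 0L)
    jsonlite::write_json(
      list(motif = m, score = fit$motifs$score[i], seed = fit$motifs$seed[i],
           seed_score = fit$motifs$seed_score[i], n_m = fit$motifs$n_m[i],
           strand_bias = sb, trace = opt$trace, parameters = cfg),
      file.path(mdir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(dir)
}

#' Cluster-based baseline scores for every q-mer
#'
#' Scores all q-mers with the discrete (partition-based) criteria on
#' k-means clusterings of the expression matrix, the clustering-based
#' procedure that the continuous scores replace.
#'
#' @param X Expression matrix.
#' @param seqs Sequence collection.
#' @param q Word length (default 7).
#' @param k_clusters Vector of cluster numbers (default
#'   c(5, 10, 20, 40, 80)).
#' @param restarts k-means restarts (default 100).
#' @param criterion "mutual_information" or "hypergeometric".
#' @param strands "both" or "forward".
#' @param seed Integer seed.
#' @return List per cluster number: the partition and the named score
#'   vector over q-mers.
#' @export
baseline_scores <- function(X, seqs, q = 7L,
                            k_clusters = c(5L, 10L, 20L, 40L, 80L),
                            restarts = 100L,
                            criterion = c("mutual_information", "hypergeometric"),
                            strands = c("both", "forward"), seed = 1L) {
  criterion <- match.arg(criterion)
  strands <- match.arg(strands)
  P <- qmer_presence(seqs, q, strands)
  out <- list()
  for (kc in k_clusters) {
    part <- kmeans_partition(X, kc, restarts, seed = seed + kc)
    scores <- apply(as.matrix(P), 2L, score_discrete,
                    labels = part$labels, criterion = criterion)
    out[[as.character(kc)]] <- list(partition = part, scores = scores)
  }
  out
}
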