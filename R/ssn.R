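# Sequence similarity network: all-vs-all local alignment, edges kept
# above an alignment-score threshold, clusters as connected components.
# The alignment score follows the EFI-EST convention, -log10(E-value),
# so the canonical threshold 70 corresponds to roughly 90% amino-acid
# identity for proteins of BaiE scale.

#' Alignment score of an alignment result
#'
#' `-log10(E-value)`, clamped at 300 against underflow.
#'
#' @param aln an alignment-result data frame (rows from [local_align()]).
#' @return numeric vector of scores.
#' @export
alignment_score <- function(aln) {
  if (any(aln$e_value <= 0)) stop("E-values must be positive")
  pmin(-log10(aln$e_value), 300)
}

#' Build a sequence similarity network
#'
#' All-vs-all Smith-Waterman over the input proteins; an undirected edge
#' is kept between two sequences iff their alignment score reaches
#' `threshold`. E-values here use the pairwise product of lengths as the
#' search space (self-contained and order-independent).
#'
#' @param seqs protein [seq_records] (>= 2 rows).
#' @param params a [search_params] supplying the scoring constants
#'   (identity/coverage cutoffs are not applied here).
#' @param threshold minimum alignment score for an edge; 70 by default.
#' @return an `ssn_graph`: list with `nodes`, `edges` (data frame
#'   `a`, `b`, `score` with `a < b`), `alignments` (full pair table) and
#'   `threshold`.
#' @export
build_ssn <- function(seqs, params = search_params(), threshold = 70) {
  if (nrow(seqs) < 2L) stop("need at least 2 sequences")
  params$db_size <- NULL # pairwise product-of-lengths search space
  n <- nrow(seqs)
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs$seq[(i + 1L):n]),
      Biostrings::AAString(seqs$seq[i]), type = "local",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    pairs[[i]] <- aln_stats(pa, seqs$id[(i + 1L):n], seqs$id[i],
                            nchar(seqs$seq[(i + 1L):n]), nchar(seqs$seq[i]),
                            params)
  }
  aln <- do.call(rbind, pairs)
  # store undirected with a < b
  a <- pmin(aln$query_id, aln$subject_id)
  b <- pmax(aln$query_id, aln$subject_id)
  aln$a <- a; aln$b <- b
  aln$score <- alignment_score(aln)
  edges <- aln[aln$score >= threshold, c("a", "b", "score"), drop = FALSE]
  rownames(edges) <- NULL
  log_msg("SSN: %d nodes, %d/%d pairs above score %s",
          n, nrow(edges), nrow(aln), format(threshold))
  structure(list(nodes = seqs$id, edges = edges,
                 alignments = aln[, c("a", "b", "score", "pct_identity",
                                      "bit_score", "e_value")],
                 threshold = threshold),
            class = "ssn_graph")
}

#' Connected-component clusters of an SSN
#'
#' Singleton nodes form singleton clusters. Cluster ids are assigned
#' 1..k by descending member count, ties broken by the lexicographically
#' smallest member id, making the otherwise arbitrary cluster naming
#' deterministic.
#'
#' @param graph an `ssn_graph`.
#' @param query_ids ids considered "query" sequences; used to flag
#'   clusters containing at least one query.
#' @return a data frame with columns `cluster_id`, `member`,
#'   `contains_query`.
#' @export
ssn_components <- function(graph, query_ids = character(0)) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  ord <- order(-lengths(groups),
               vapply(groups, function(m) sort(m)[1], character(1)))
  groups <- groups[ord]
  out <- do.call(rbind, lapply(seq_along(groups), function(k)
    data.frame(cluster_id = k, member = sort(groups[[k]]),
               stringsAsFactors = FALSE)))
  out$contains_query <- out$cluster_id %in%
    unique(out$cluster_id[out$member %in% query_ids])
  rownames(out) <- NULL
  out
}

#' Per-cluster summary table
#'
#' One row per cluster with the member count and the minimum pairwise
#' percent identity among members (100 for singletons) - the statistic
#' behind the ">92.4% within-cluster identity" style headline. Sorted by
#' size descending.
#'
#' @param clusters output of [ssn_components()].
#' @param graph the `ssn_graph` the clusters came from (supplies the
#'   pairwise identities).
#' @return data frame `cluster_id`, `size`, `min_within_identity`,
#'   `contains_query`.
#' @export
cluster_report <- function(clusters, graph) {
  aln <- graph$alignments
  ids <- sort(unique(clusters$cluster_id))
  rows <- lapply(ids, function(cid) {
    members <- clusters$member[clusters$cluster_id == cid]
    if (length(members) == 1L) mwi <- 100
    else {
      sel <- aln$a %in% members & aln$b %in% members
      mwi <- min(aln$pct_identity[sel])
    }
    data.frame(cluster_id = cid, size = length(members),
               min_within_identity = mwi,
               contains_query = any(clusters$contains_query[
                 clusters$cluster_id == cid]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$size, out$cluster_id), , drop = FALSE]
}

#' Export an SSN as an edge-list TSV
#' @param graph an `ssn_graph`.
#' @param path output path.
#' @export
write_ssn_edges <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export an SSN as GraphML (Cytoscape-compatible)
#' @param graph an `ssn_graph`.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="score" for="edge" attr.name="alignment_score" attr.type="double"/>',
    '  <graph id="ssn" edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', graph$nodes), con)
  if (nrow(graph$edges))
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="score">%.4f</data></edge>',
      graph$edges$a, graph$edges$b, graph$edges$score), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
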