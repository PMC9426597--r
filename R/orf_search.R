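# Six-frame ORF extraction and the iterative homology search that
# expands a set of seed BaiE queries to a fixed point over a protein
# database. An ORF is a methionine-initiated, stop-terminated stretch:
# within each maximal stop-free run of a frame, the first ATG opens the
# (single, non-nested) reported ORF, and the interval includes the stop
# codon. Coordinates are 0-based half-open on the forward strand.

#' Extract open reading frames from a contig
#'
#' @param contig a single-row dna [seq_records] table (or one row of one).
#' @param min_protein_len minimum protein length to report (residues,
#'   stop excluded). Default 100, sized for bai-operon-scale genes
#'   (BaiE itself is 177 aa).
#' @return a data frame with columns `orf_id`, `contig_id`, `start`,
#'   `end` (0-based half-open, stop codon included), `strand`, `frame`
#'   (0-2 on its strand) and `protein`, sorted by `(start, strand)`.
#' @export
extract_orfs <- function(contig, min_protein_len = 100L) {
  if (inherits(contig, "data.frame")) {
    stopifnot(nrow(contig) == 1L)
    cid <- contig$id; s <- contig$seq
    if (contig$alphabet != "dna") stop("contig must be dna")
  } else stop("contig must be a seq_records row")
  if (grepl("[^ACGTN]", s)) stop("non-ACGTN characters in contig ", cid)
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      sub_len <- ((L - frame) %/% 3L) * 3L
      if (sub_len < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(ss, frame + 1L, frame + sub_len)),
        if.fuzzy.codon = "X"))
      res <- strsplit(aa, "")[[1]]
      stops <- c(0L, which(res == "*"))
      for (k in seq_len(length(stops) - 1L)) {
        seg_start <- stops[k] + 1L   # aa index after previous stop
        seg_stop <- stops[k + 1L]    # aa index of terminating stop
        if (seg_stop - 1L < seg_start) next
        ms <- which(res[seg_start:(seg_stop - 1L)] == "M")
        if (!length(ms)) next
        m_idx <- seg_start + ms[1L] - 1L
        plen <- seg_stop - m_idx
        if (plen < min_protein_len) next
        nt_start <- frame + (m_idx - 1L) * 3L       # on strand ss, 0-based
        nt_end <- frame + seg_stop * 3L             # includes stop codon
        if (strand == "+") {
          fs <- nt_start; fe <- nt_end
        } else {
          fs <- L - nt_end; fe <- L - nt_start
        }
        out[[length(out) + 1L]] <- data.frame(
          contig_id = cid, start = fs, end = fe, strand = strand,
          frame = frame,
          protein = paste(res[m_idx:(seg_stop - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(orf_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, out)
  orfs <- orfs[order(orfs$start, orfs$strand), , drop = FALSE]
  orfs <- cbind(orf_id = sprintf("%s_orf%03d", cid, seq_len(nrow(orfs))),
                orfs, stringsAsFactors = FALSE)
  rownames(orfs) <- NULL
  orfs
}

#' Search parameters for protein homology search
#'
#' Houses the filter thresholds and the scoring constants. Defaults are
#' the conventional gapped-BLASTP settings: BLOSUM62, gap open 11 /
#' extend 1, Karlin-Altschul lambda = 0.267 and K = 0.041. The two
#' discovery stages use `min_identity`/`min_coverage` of 50/90
#' (reference database) and 30/90 (metagenome ORFs).
#'
#' @param min_identity percent identity cutoff over alignment columns.
#' @param min_coverage percent of the query length that must be aligned.
#' @param substitution_matrix matrix name understood by Biostrings.
#' @param gap_open,gap_extend positive gap penalties (open >= extend).
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters (> 0).
#' @param db_size total database residues for E-value scaling, or `NULL`
#'   to use the subject length (self-contained pairwise mode).
#' @return a `search_params` list.
#' @export
search_params <- function(min_identity = 50, min_coverage = 90,
                          substitution_matrix = "BLOSUM62",
                          gap_open = 11L, gap_extend = 1L,
                          karlin_lambda = 0.267, karlin_k = 0.041,
                          db_size = NULL) {
  if (gap_open < gap_extend) stop("gap_open must be >= gap_extend")
  if (karlin_lambda <= 0 || karlin_k <= 0)
    stop("Karlin parameters must be positive")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k,
                 db_size = db_size), class = "search_params")
}

# shared alignment-statistics assembly used by local_align and search
aln_stats <- function(pa, query_ids, subject_id, qlens, slen, params) {
  raw <- BiocGenerics::score(pa)
  ap <- as.character(Biostrings::alignedPattern(pa))
  ncols <- nchar(ap)
  nmatch <- Biostrings::nmatch(pa)
  q_aligned <- nchar(gsub("-", "", ap, fixed = TRUE)) # span on the query
  bit <- (params$karlin_lambda * raw - log(params$karlin_k)) / log(2)
  mn <- qlens * (params$db_size %||% slen)
  e <- mn * 2^(-bit)
  data.frame(query_id = query_ids, subject_id = subject_id,
             raw_score = raw, bit_score = bit,
             e_value = pmax(e, .Machine$double.xmin),
             pct_identity = ifelse(ncols > 0, 100 * nmatch / ncols, 0),
             query_coverage = 100 * q_aligned / qlens,
             aln_len = ncols, stringsAsFactors = FALSE)
}

#' Optimal local protein alignment with BLAST-style statistics
#'
#' Smith-Waterman affine-gap optimal local alignment (via
#' [Biostrings::pairwiseAlignment()]) with Karlin-Altschul bit score and
#' E-value: `bit = (lambda * raw - ln K) / ln 2`,
#' `E = m * n * 2^(-bit)` where `n` is `db_size` (or the subject length
#' when unset). Percent identity is computed over alignment columns
#' including gap columns; query coverage is the aligned fraction of the
#' query length.
#'
#' @param query,subject protein strings or single-row [seq_records].
#' @param params a [search_params].
#' @return a one-row alignment-result data frame (`query_id`,
#'   `subject_id`, `raw_score`, `bit_score`, `e_value`, `pct_identity`,
#'   `query_coverage`, `aln_len`).
#' @export
local_align <- function(query, subject, params = search_params()) {
  qid <- "query"; sid <- "subject"
  if (inherits(query, "data.frame")) { qid <- query$id[1]; query <- query$seq[1] }
  if (inherits(subject, "data.frame")) { sid <- subject$id[1]; subject <- subject$seq[1] }
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  aln_stats(pa, qid, sid, nchar(query), nchar(subject), params)
}

#' All-vs-all filtered homology search
#'
#' Every query x subject pair is aligned; hits passing both the identity
#' and the query-coverage cutoff are returned, ordered by `(query_id,
#' descending bit_score, subject_id)`.
#'
#' @param queries,database [seq_records] tables of proteins.
#' @param params a [search_params]; `db_size` defaults to the total
#'   residue count of `database`.
#' @return an alignment-result data frame (possibly empty).
#' @export
search <- function(queries, database, params = search_params()) {
  if (nrow(database) == 0L) {
    warning("empty database; no hits")
    return(empty_hits())
  }
  if (is.null(params$db_size)) params$db_size <- sum(nchar(database$seq))
  qset <- Biostrings::AAStringSet(setNames(queries$seq, queries$id))
  res <- lapply(seq_len(nrow(database)), function(j) {
    pa <- Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(database$seq[j]), type = "local",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    aln_stats(pa, queries$id, database$id[j], nchar(queries$seq),
              nchar(database$seq[j]), params)
  })
  hits <- do.call(rbind, res)
  hits <- hits[hits$pct_identity >= params$min_identity &
                 hits$query_coverage >= params$min_coverage, , drop = FALSE]
  hits <- hits[order(hits$query_id, -hits$bit_score, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  log_msg("search: %d queries x %d subjects -> %d passing hits",
          nrow(queries), nrow(database), nrow(hits))
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             raw_score = numeric(0), bit_score = numeric(0),
             e_value = numeric(0), pct_identity = numeric(0),
             query_coverage = numeric(0), aln_len = integer(0),
             stringsAsFactors = FALSE)
}

#' Iterative search-and-cluster expansion of a query set
#'
#' Implements the discovery loop: search the current queries against the
#' database, build an SSN over queries plus passing hits, accept the
#' clusters that contain at least one current query - or, when operon
#' verdicts from neighborhood analysis are supplied, query-less clusters
#' with at least one member whose operon is a 7a-dehydroxylation
#' candidate (the route by which distant families enter) - promote
#' accepted database members to queries, and repeat until no new
#' sequence is accepted.
#' The accepted set grows monotonically and is bounded by the database,
#' so a fixed point is guaranteed.
#'
#' @param seed_queries non-empty protein [seq_records].
#' @param database protein [seq_records] to mine.
#' @param params a [search_params] for the search stage.
#' @param ssn_threshold SSN edge threshold (alignment score, -log10 E).
#' @param verdicts optional named character vector mapping sequence ids
#'   to `"candidate"`/`"non-candidate"` operon verdicts.
#' @param max_rounds diagnostic cap on rounds.
#' @return list with `accepted` ([seq_records] subset of `database`),
#'   `pool` (queries plus every passing hit of the final round - the
#'   node set a downstream SSN should be built over, including clusters
#'   that were hit but not functionally accepted) and `rounds` (number
#'   of rounds that grew the accepted set; a final confirming round that
#'   finds nothing new is not counted).
#' @export
iterative_expand <- function(seed_queries, database,
                             params = search_params(min_identity = 30),
                             ssn_threshold = 70, verdicts = NULL,
                             max_rounds = 20L) {
  if (nrow(seed_queries) == 0L) stop("seed_queries must be non-empty")
  accepted <- character(0)
  rounds <- 0L   # rounds that grew the accepted set
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_rounds)
      stop("iterative_expand failed to converge within ", max_rounds,
           " rounds")
    query_ids <- c(seed_queries$id, accepted)
    queries <- rbind(seed_queries,
                     database[database$id %in% accepted, , drop = FALSE])
    hits <- search(queries, database, params)
    pool_ids <- unique(c(query_ids, hits$subject_id))
    pool <- rbind(seed_queries[seed_queries$id %in% pool_ids, , drop = FALSE],
                  database[database$id %in% setdiff(pool_ids, seed_queries$id),
                           , drop = FALSE])
    new_accepted <- accepted
    if (nrow(pool) >= 2L) {
      graph <- build_ssn(pool, params, threshold = ssn_threshold)
      clusters <- ssn_components(graph, query_ids = query_ids)
      rep_tab <- cluster_report(clusters, graph)
      for (cid in rep_tab$cluster_id) {
        members <- clusters$member[clusters$cluster_id == cid]
        has_query <- rep_tab$contains_query[rep_tab$cluster_id == cid]
        gnn_ok <- !is.null(verdicts) &&
          any(verdicts[members] == "candidate", na.rm = TRUE)
        if (!has_query && !gnn_ok) next
        new_accepted <- union(new_accepted, intersect(members, database$id))
      }
    } else {
      new_accepted <- union(accepted, intersect(pool_ids, database$id))
    }
    log_msg("expand round %d: %d accepted", iter, length(new_accepted))
    if (setequal(new_accepted, accepted)) break
    accepted <- new_accepted
    rounds <- rounds + 1L
  }
  list(accepted = database[database$id %in% accepted, , drop = FALSE],
       pool = pool, rounds = rounds)
}
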