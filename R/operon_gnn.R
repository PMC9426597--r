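# Genome-neighborhood annotation around a baiE hit and the completeness
# rule separating 7a-dehydroxylation candidates from non-candidates.
# Completeness is judged on the operon-local seven required genes
# (baiA, baiB, baiCD, baiE, baiF, baiG, baiH); the regulators barA/barB
# and the distally encoded baiN/baiK are reported but never affect the
# verdict.

#' Annotate ORFs in the neighborhood of a baiE anchor
#'
#' Every ORF whose interval lies within `window` bp of the anchor ORF is
#' aligned against each reference gene profile; it is assigned the gene
#' with the best bit score provided identity >= 30% and reference
#' (subject-profile) coverage >= 50%, else `"unassigned"`. The looser
#' thresholds (relative to the discovery filter) reflect the higher
#' divergence of neighborhood genes.
#'
#' @param contig single-row dna [seq_records] (currently unused beyond
#'   identification; kept for interface symmetry).
#' @param orfs ORF table from [extract_orfs()].
#' @param ref a [bai_reference_set()].
#' @param window neighborhood half-width in bp (default 15000; bai
#'   operons span roughly 12 kb).
#' @param anchor `orf_id` of the baiE hit on this contig.
#' @param min_identity,min_ref_coverage assignment thresholds (percent).
#' @return `orfs` with extra columns `assignment` and `best_identity`.
#' @export
annotate_neighborhood <- function(contig, orfs, ref, window = 15000L,
                                  anchor, min_identity = 30,
                                  min_ref_coverage = 50) {
  if (!anchor %in% orfs$orf_id) stop("anchor ORF not in orfs: ", anchor)
  a <- orfs[orfs$orf_id == anchor, ]
  gap <- pmax(0L, pmax(orfs$start, a$start) - pmin(orfs$end, a$end))
  near <- gap <= window
  params <- search_params()
  prof_gene <- rep(names(ref$profiles),
                   vapply(ref$profiles, nrow, integer(1)))
  prof_seq <- unlist(lapply(ref$profiles, function(p) p$seq),
                     use.names = FALSE)
  prof_set <- Biostrings::AAStringSet(prof_seq)
  assignment <- rep(NA_character_, nrow(orfs))
  best_identity <- rep(NA_real_, nrow(orfs))
  for (i in which(near)) {
    # profiles as queries so query_coverage is coverage of the reference
    r <- aln_stats(
      Biostrings::pairwiseAlignment(
        prof_set, Biostrings::AAString(orfs$protein[i]), type = "local",
        substitutionMatrix = params$substitution_matrix,
        gapOpening = params$gap_open, gapExtension = params$gap_extend),
      prof_gene, orfs$orf_id[i], nchar(prof_seq), nchar(orfs$protein[i]),
      params)
    ok <- r$pct_identity >= min_identity &
      r$query_coverage >= min_ref_coverage
    if (any(ok)) {
      best <- which(ok)[which.max(r$bit_score[ok])]
      assignment[i] <- r$query_id[best]
      best_identity[i] <- r$pct_identity[best]
    } else {
      assignment[i] <- "unassigned"
    }
  }
  out <- orfs
  out$assignment <- assignment
  out$best_identity <- best_identity
  out[near, , drop = FALSE]
}

#' Classify operon completeness of an annotated neighborhood
#'
#' Verdict is `"candidate"` iff every required gene is present in the
#' window; duplicated genes (e.g. two baiF copies) count once; optional
#' and distal genes are reported but never affect the verdict.
#'
#' @param contig_id contig identifier.
#' @param annotated output of [annotate_neighborhood()].
#' @param ref a [bai_reference_set()].
#' @return an `operon_call`: list with `contig_id`, `annotated`,
#'   `present`, `missing_required`, `verdict` and `resolvable` (whether
#'   the neighborhood held more than the anchor ORF).
#' @export
classify_operon <- function(contig_id, annotated, ref) {
  assigned <- annotated$assignment[!is.na(annotated$assignment) &
                                     annotated$assignment != "unassigned"]
  present <- unique(assigned)
  missing_required <- setdiff(ref$required, present)
  structure(list(contig_id = contig_id,
                 annotated = annotated,
                 present = present,
                 missing_required = missing_required,
                 verdict = if (length(missing_required) == 0)
                   "candidate" else "non-candidate",
                 resolvable = nrow(annotated) > 1L),
            class = "operon_call")
}

#' Aggregate operon verdicts over an SSN cluster
#'
#' A cluster is a 7a-dehydroxylation candidate if any member contig
#' carries a complete operon (existential rule); `"indeterminate"` when
#' no member has a resolvable neighborhood (e.g. all hits sit on short
#' contigs carrying only the anchor gene).
#'
#' @param calls list of `operon_call` objects for the cluster's members.
#' @return `"candidate"`, `"non-candidate"` or `"indeterminate"`.
#' @export
cluster_verdict <- function(calls) {
  if (!length(calls)) stop("need at least one operon call")
  verdicts <- vapply(calls, `[[`, character(1), "verdict")
  resolvable <- vapply(calls, `[[`, logical(1), "resolvable")
  if (any(verdicts == "candidate")) return("candidate")
  if (!any(resolvable)) return("indeterminate")
  "non-candidate"
}

#' Write gene-arrow and verdict tables for operon diagrams
#' @param call an `operon_call`.
#' @param path output TSV path.
#' @export
write_operon_table <- function(call, path) {
  tab <- call$annotated[, c("contig_id", "assignment", "start", "end",
                            "strand")]
  names(tab)[2] <- "gene"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
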