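# Average nucleotide identity between genomes/MAGs (OrthoANI-style
# reciprocal best-hit fragments) and distance-based phylogenetics
# (p-distance on aligned marker proteins, Saitou-Nei neighbor joining).

#' OrthoANI-style average nucleotide identity
#'
#' Both genomes are cut into non-overlapping fragments (1020 bp, the
#' published OrthoANI default; trailing remainders dropped). Fragment
#' pairs are aligned by nucleotide local alignment on both strands;
#' alignments with >= 35% identity over >= 35% of the fragment are
#' admitted, reciprocal best-hit pairs found, and ANI is the mean
#' identity over reciprocal pairs (symmetric by construction).
#'
#' @param genome_a,genome_b dna [seq_records] tables (one or more
#'   contigs each).
#' @param fragment_len fragment length in bp.
#' @param min_identity,min_coverage admission thresholds (percent).
#' @param species_cutoff ANI threshold for the same-species call
#'   (default 95, the midpoint of the conventional 94-96% band).
#' @return an `ani_result` list: `genome_a`, `genome_b`, `ani` (percent,
#'   `NA` if no reciprocal pairs), `n_fragments_used`, `same_species`.
#' @export
orthoani <- function(genome_a, genome_b, fragment_len = 1020L,
                     min_identity = 35, min_coverage = 35,
                     species_cutoff = 95) {
  fa <- chop_fragments(genome_a, fragment_len)
  fb <- chop_fragments(genome_b, fragment_len)
  if (length(fa) < 2L || length(fb) < 2L)
    stop("each genome must yield at least 2 fragments")
  fb_rc <- revcomp(fb)
  na <- length(fa); nb <- length(fb)
  ident <- matrix(NA_real_, na, nb)
  score <- matrix(-Inf, na, nb)
  min_cols <- ceiling(min_coverage / 100 * fragment_len)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      r1 <- .sw_nt_pair_cpp(fa[i], fb[j], 1L, -1L, -2L)
      r2 <- .sw_nt_pair_cpp(fa[i], fb_rc[j], 1L, -1L, -2L)
      r <- if (r1[["score"]] >= r2[["score"]]) r1 else r2
      if (r[["ncols"]] >= min_cols) {
        id <- 100 * r[["nmatch"]] / r[["ncols"]]
        if (id >= min_identity) {
          ident[i, j] <- id
          score[i, j] <- r[["score"]]
        }
      }
    }
  }
  best_a <- apply(score, 1L, function(s) if (all(!is.finite(s))) NA_integer_
                  else which.max(s))
  best_b <- apply(score, 2L, function(s) if (all(!is.finite(s))) NA_integer_
                  else which.max(s))
  recip <- which(!is.na(best_a) &
                   vapply(seq_len(na), function(i)
                     !is.na(best_a[i]) && !is.na(best_b[best_a[i]]) &&
                       best_b[best_a[i]] == i, logical(1)))
  ani <- if (length(recip))
    mean(ident[cbind(recip, best_a[recip])]) else NA_real_
  if (!length(recip)) log_msg("orthoani: no reciprocal fragment pairs")
  structure(list(genome_a = genome_label(genome_a),
                 genome_b = genome_label(genome_b),
                 ani = ani, n_fragments_used = length(recip),
                 same_species = !is.na(ani) && ani >= species_cutoff),
            class = "ani_result")
}

genome_label <- function(g) {
  if (inherits(g, "data.frame")) paste(g$id, collapse = "|") else "genome"
}

chop_fragments <- function(genome, fragment_len) {
  seqs <- if (inherits(genome, "data.frame")) genome$seq else
    as.character(genome)
  unlist(lapply(seqs, function(s) {
    n <- nchar(s) %/% fragment_len
    if (n == 0L) return(character(0))
    substring(s, (seq_len(n) - 1L) * fragment_len + 1L,
              seq_len(n) * fragment_len)
  }), use.names = FALSE)
}

#' p-distance matrix from aligned protein sequences
#'
#' Pairwise proportion of differing columns among columns where both
#' sequences are non-gap (pairwise deletion).
#'
#' @param aligned a protein [seq_records] of equal-length aligned
#'   sequences (gaps as `-`), or a named character vector.
#' @return a symmetric `dist`-free base matrix with zero diagonal.
#' @export
p_distance <- function(aligned) {
  seqs <- if (inherits(aligned, "data.frame"))
    setNames(aligned$seq, aligned$id) else aligned
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) { d[i, j] <- d[j, i] <- NA_real_; next }
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classical NJ with the standard Q criterion. Ties in Q break to the
#' lowest index pair (determinism); negative branch lengths are clamped
#' to zero with the remainder transferred to the sibling branch, which
#' preserves the path length between the joined taxa. Recovers any
#' additive distance matrix exactly.
#'
#' @param d symmetric non-negative matrix with zero diagonal; row/col
#'   names are the taxon labels. Triangle-inequality violations are
#'   tolerated (logged), as NJ handles them.
#' @return an unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(as.matrix(d)), tol = 1e-8))
    stop("distance matrix must be symmetric")
  d <- as.matrix(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("need at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n0))
  tri_viol <- FALSE
  for (i in seq_len(n0)) for (j in seq_len(n0)) for (k in seq_len(n0))
    if (d[i, j] > d[i, k] + d[k, j] + 1e-9) tri_viol <- TRUE
  if (tri_viol) log_msg("nj_tree: triangle-inequality violations present")
  # working set: newick fragments for each live node
  node <- labels
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest-index pair among minima
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    cl <- clamp_pair(li, lj)
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", node[i], cl[1], node[j], cl[2])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    node <- c(node[keep], merged)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l <- pmax(c(la, lb, lc), 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    node[1], l[1], node[2], l[2], node[3], l[3])
  read_newick(newick)
}

# clamp a sibling branch pair: negatives go to 0, remainder moved to the
# sibling so the inter-taxon path length is preserved
clamp_pair <- function(li, lj) {
  if (li < 0) { lj <- lj + li; li <- 0 }
  if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
  c(li, lj)
}

#' Seeded column-resampling bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance NJ tree per replicate, and reports for each internal
#' clade of the full-data tree the proportion of replicates containing
#' it. Optional diagnostics only; not part of the validated surface.
#'
#' @param aligned equal-length aligned protein [seq_records] or named
#'   character vector.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @return list with `tree` (the full-data NJ tree) and `support`
#'   (per-internal-node proportion in \[0, 1\]).
#' @export
nj_bootstrap <- function(aligned, n_boot = 100L, seed = 1L) {
  seqs <- if (inherits(aligned, "data.frame"))
    setNames(aligned$seq, aligned$id) else aligned
  base <- nj_tree(p_distance(seqs))
  m <- do.call(rbind, strsplit(seqs, ""))
  boots <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
    idx <- sample.int(ncol(m), replace = TRUE)
    res <- apply(m[, idx, drop = FALSE], 1L, paste, collapse = "")
    nj_tree(p_distance(setNames(res, names(seqs))))
  }))
  counts <- ape::prop.clades(base, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = base, support = counts / n_boot)
}
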