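# Seeded generators that emulate the statistical structure of the real
# inputs: protein families with controlled within/between identity
# (the SSN cluster structure), contigs carrying complete or incomplete
# bai operons, read sets drawn at planted cluster abundances, and sample
# metadata with planted group effects and bile-acid-ratio correlations.
# Every generator is a pure function of (spec, seed) and emits its
# planted truth alongside the data.

#' Canonical bai operon gene roster
#'
#' Gene names, protein lengths (aa) and coding strands of the ten-gene
#' bai operon layout used as the synthetic ground truth: baiE (bile-acid
#' 7a-dehydratase, the pathway marker), baiCD/baiH (NADH:flavin
#' oxidoreductases), barA/barB (regulators), baiA (3a-hydroxysteroid
#' dehydrogenase), baiB (bile acid-CoA ligase), baiG (transporter) and
#' two baiF copies (bile acid-CoA transferase).
#'
#' @return a data frame with columns `gene`, `length_aa`, `strand`.
#' @export
bai_operon_layout <- function() {
  data.frame(
    gene = c("baiE", "baiCD", "baiH", "barA", "barB",
             "baiA", "baiB", "baiG", "baiF", "baiF"),
    length_aa = c(177L, 644L, 663L, 514L, 195L,
                  255L, 506L, 473L, 452L, 478L),
    strand = c("-", "-", "+", "+", "+", "+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE)
}

#' Random protein / DNA sequence generators
#'
#' Proteins always start with methionine so their reverse translation
#' yields an ATG-initiated ORF.
#'
#' @param len sequence length (residues / bases).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a single character string.
#' @export
random_protein <- function(len, seed = NULL) {
  gen <- function() paste0("M", paste(sample(AA20, len - 1L, replace = TRUE),
                                      collapse = ""))
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @rdname random_protein
#' @export
random_dna <- function(len, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Family specification for the protein-family generator
#'
#' @param ancestor a protein string or single-row [seq_records] table.
#' @param n_members number of family members to derive.
#' @param target_identity intended fraction identity of each member to the
#'   ancestor, in (0, 1]. 0.98 by default: two members at 98% to the
#'   ancestor sit near 96% pairwise identity, placing whole families
#'   inside the >92.4% within-cluster regime observed for natural BaiE
#'   clusters.
#' @param seed integer seed.
#' @return a `family_spec` list.
#' @export
family_spec <- function(ancestor, n_members, target_identity = 0.98, seed = 1L) {
  if (inherits(ancestor, "data.frame")) ancestor <- ancestor$seq[1]
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1)
    stop("target_identity must be in (0, 1]")
  if (n_members < 1) stop("n_members must be >= 1")
  structure(list(ancestor = toupper(ancestor), n_members = as.integer(n_members),
                 target_identity = target_identity, seed = as.integer(seed)),
            class = "family_spec")
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Derive a protein family by seeded point substitution
#'
#' Each member is derived from the ancestor by i.i.d. residue
#' substitutions at rate `1 - target_identity`; replacement residues are
#' drawn with BLOSUM62-weighted probabilities (weight `2^score`,
#' excluding the original residue) so alignments of the family remain
#' realistic for score calibration. The initial methionine is never
#' mutated, keeping reverse-translated genes ATG-initiated.
#'
#' @param spec a [family_spec].
#' @param prefix member id prefix.
#' @return a [seq_records] table of `n_members` proteins.
#' @export
mutate_family <- function(spec, prefix = "fam") {
  stopifnot(inherits(spec, "family_spec"))
  if (nchar(spec$ancestor) < 50) stop("ancestor protein must be >= 50 residues")
  rate <- 1 - spec$target_identity
  bl <- blosum62_matrix()
  with_seed(spec$seed, {
    members <- vapply(seq_len(spec$n_members), function(i) {
      res <- strsplit(spec$ancestor, "")[[1]]
      # position 1 (M) held fixed
      idx <- which(runif(length(res) - 1L) < rate) + 1L
      for (p in idx) {
        orig <- res[p]
        alts <- setdiff(AA20, orig)
        w <- 2^bl[orig, alts]
        res[p] <- sample(alts, 1L, prob = w / sum(w))
      }
      paste(res, collapse = "")
    }, character(1))
    seq_records(sprintf("%s_%02d", prefix, seq_len(spec$n_members)),
                members, "protein", source = "synthetic")
  })
}

#' Operon specification for the contig builder
#'
#' @param genes character vector of gene names drawn from
#'   [bai_operon_layout()] (plus optionally `baiN`/`baiK`); `baiF` may
#'   occur twice, all other names at most once.
#' @param strands `"+"`/`"-"` per gene; defaults to the canonical layout
#'   strand where the gene matches it.
#' @param intergenic_len spacer length between genes (bp).
#' @param complete declared intent flag: `TRUE` means the spec is meant
#'   to carry the full required gene set.
#' @return an `operon_spec` list.
#' @export
operon_spec <- function(genes, strands = NULL, intergenic_len = 100L,
                        complete = TRUE) {
  if (is.null(strands)) {
    lay <- bai_operon_layout()
    strands <- lay$strand[match(genes, lay$gene)]
    strands[is.na(strands)] <- "+"
  }
  stopifnot(length(genes) == length(strands),
            all(strands %in% c("+", "-")), intergenic_len >= 0)
  tab <- table(genes)
  over <- names(tab)[tab > ifelse(names(tab) == "baiF", 2L, 1L)]
  if (length(over)) stop("gene(s) repeated beyond allowance: ",
                         paste(over, collapse = ", "))
  structure(list(genes = genes, strands = strands,
                 intergenic_len = as.integer(intergenic_len),
                 complete = isTRUE(complete)),
            class = "operon_spec")
}

#' @rdname operon_spec
#' @export
table1_operon_spec <- function(intergenic_len = 100L) {
  lay <- bai_operon_layout()
  operon_spec(lay$gene, lay$strand, intergenic_len, complete = TRUE)
}

#' Reference bai proteins for the synthetic ground truth
#'
#' Generates one protein per bai/bar gene at the canonical length,
#' deterministically from `seed`. The second `baiF` copy is an
#' independent protein of length 478. `baiN` and `baiK` (encoded
#' distantly from the operon in real genomes) are included for the
#' reference set but not placed on operon contigs by default.
#'
#' @param seed integer seed.
#' @return named list mapping gene name to a character vector of protein
#'   sequences (length 2 for `baiF`).
#' @export
bai_reference_proteins <- function(seed = 101L) {
  lay <- bai_operon_layout()
  with_seed(seed, {
    prots <- lapply(seq_len(nrow(lay)), function(i)
      random_protein(lay$length_aa[i]))
    names(prots) <- make.unique(lay$gene)
    out <- list()
    for (g in unique(lay$gene))
      out[[g]] <- unlist(prots[make.unique(lay$gene) %in%
                                 c(g, paste0(g, ".1"))], use.names = FALSE)
    out$baiN <- random_protein(360L)
    out$baiK <- random_protein(450L)
    out
  })
}

#' Reference set used by neighborhood annotation
#'
#' @param seed passed to [bai_reference_proteins()].
#' @param proteins optional pre-built gene-to-protein map.
#' @return a `bai_reference_set`: list with `profiles` (gene ->
#'   [seq_records]), and the `required`, `optional` and `distal` gene
#'   name sets. Completeness of an operon is judged on `required` only.
#' @export
bai_reference_set <- function(seed = 101L, proteins = NULL) {
  proteins <- proteins %||% bai_reference_proteins(seed)
  profiles <- lapply(names(proteins), function(g)
    seq_records(paste0(g, "_ref", seq_along(proteins[[g]])),
                proteins[[g]], "protein", source = "bai_reference"))
  names(profiles) <- names(proteins)
  structure(list(
    profiles = profiles,
    required = c("baiA", "baiB", "baiCD", "baiE", "baiF", "baiG", "baiH"),
    optional = c("barA", "barB"),
    distal = c("baiN", "baiK")), class = "bai_reference_set")
}

# genetic code helpers ------------------------------------------------------

codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

# stop codons in all six frames; palindromic under reverse complement
STOP_WALL <- "TTAATTAATTAA"

reverse_translate <- function(protein, add_stop = TRUE) {
  ct <- codon_table()
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res, function(a) {
    opts <- ct[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  if (add_stop) codons <- c(codons, sample(ct[["*"]], 1L))
  paste(codons, collapse = "")
}

#' Build a contig carrying a synthetic bai operon
#'
#' Reverse-translates each gene's protein (uniform random synonymous
#' codons, standard bacterial code) and lays the ORFs out on the contig
#' on their stated strands, separated by random intergenic spacers.
#' Every gene is flanked by a short six-frame stop wall so the planted
#' ORF boundaries are exactly what [extract_orfs()] recovers. Intervals
#' are 0-based half-open and include the stop codon.
#'
#' @param spec an [operon_spec].
#' @param proteins gene-to-protein map, e.g. [bai_reference_proteins()];
#'   a gene listed twice consumes successive entries of its vector.
#' @param codon_seed integer seed for codon choice and spacers.
#' @param contig_id id of the returned record.
#' @return list with `contig` (single-row dna [seq_records]) and `truth`
#'   (data frame `gene`, `start`, `end`, `strand`, `protein`).
#' @export
build_contig <- function(spec, proteins = bai_reference_proteins(),
                         codon_seed = 1L, contig_id = "contig1") {
  stopifnot(inherits(spec, "operon_spec"))
  with_seed(codon_seed, {
    seen <- integer(0)
    parts <- character(0)
    truth <- data.frame(gene = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        protein = character(0), stringsAsFactors = FALSE)
    pos <- 0L
    push <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
    push(random_dna(spec$intergenic_len))
    for (i in seq_along(spec$genes)) {
      g <- spec$genes[i]
      k <- sum(seen == match(g, unique(spec$genes))) # occurrence count
      seen <- c(seen, match(g, unique(spec$genes)))
      prot_opts <- proteins[[g]]
      if (is.null(prot_opts)) stop("no protein available for gene ", g)
      occ <- sum(spec$genes[seq_len(i)] == g)
      prot <- prot_opts[min(occ, length(prot_opts))]
      orf <- reverse_translate(prot, add_stop = TRUE)
      push(STOP_WALL)
      start <- pos
      placed <- if (spec$strands[i] == "-") revcomp(orf) else orf
      push(placed)
      truth <- rbind(truth, data.frame(
        gene = g, start = start, end = pos, strand = spec$strands[i],
        protein = prot, stringsAsFactors = FALSE))
      push(STOP_WALL)
      push(random_dna(spec$intergenic_len))
    }
    contig <- seq_records(contig_id, paste(parts, collapse = ""), "dna",
                          source = "synthetic_operon")
    list(contig = contig, truth = truth)
  })
}

#' Community specification for the read simulator
#'
#' @param contigs a dna [seq_records] table with an extra `cluster`
#'   column naming the planted cluster of each contig.
#' @param relative_abundances named numeric vector over clusters, summing
#'   to 1 (tolerance 1e-9).
#' @param depth total read count.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution probability, in \[0, 0.1\].
#' @param seed integer seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(contigs, relative_abundances, depth,
                           read_len = 100L, error_rate = 0.01, seed = 1L) {
  if (abs(sum(relative_abundances) - 1) > 1e-9)
    stop("relative_abundances must sum to 1")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  if (depth < 1) stop("depth must be >= 1")
  if (!"cluster" %in% names(contigs)) stop("contigs need a cluster column")
  if (read_len > min(nchar(contigs$seq)))
    stop("read_len exceeds the shortest contig")
  structure(list(contigs = contigs,
                 relative_abundances = relative_abundances,
                 depth = as.integer(depth), read_len = as.integer(read_len),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

#' Simulate a shotgun read set from a planted community
#'
#' Reads are drawn from contigs with probability proportional to
#' `relative_abundance x contig length`, positions uniform, strands
#' random; substitution errors at `error_rate` (no indels, matching the
#' identity/length-based mapping criterion); constant Q40 qualities.
#' Deterministic given the spec seed.
#'
#' @param spec a [community_spec].
#' @param sample_id sample label of the returned read set.
#' @param modality read-set modality tag.
#' @return list with `reads` (a `read_set`) and `truth` (per-read contig,
#'   cluster, position and strand).
#' @export
simulate_reads <- function(spec, sample_id = "synthetic_sample",
                           modality = "metagenome") {
  stopifnot(inherits(spec, "community_spec"))
  ctg <- spec$contigs
  lens <- nchar(ctg$seq)
  w <- spec$relative_abundances[ctg$cluster] * lens
  if (any(is.na(w))) stop("contig cluster missing from relative_abundances")
  with_seed(spec$seed, {
    idx <- sample.int(nrow(ctg), spec$depth, replace = TRUE, prob = w)
    pos <- floor(runif(spec$depth) * (lens[idx] - spec$read_len + 1L))
    strand <- sample(c("+", "-"), spec$depth, replace = TRUE)
    seqs <- substring(ctg$seq[idx], pos + 1L, pos + spec$read_len)
    flip <- strand == "-"
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    if (spec$error_rate > 0) {
      nerr <- rbinom(spec$depth, spec$read_len, spec$error_rate)
      for (i in which(nerr > 0L)) {
        s <- strsplit(seqs[i], "")[[1]]
        at <- sample.int(spec$read_len, nerr[i])
        for (p in at)
          s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
      }
    }
    reads <- data.frame(
      id = sprintf("read%07d", seq_len(spec$depth)),
      seq = seqs,
      qual = strrep(rawToChar(as.raw(40L + 33L)), spec$read_len),
      stringsAsFactors = FALSE)
    list(reads = read_set(sample_id, reads, modality),
         truth = data.frame(id = reads$id, contig = ctg$id[idx],
                            cluster = ctg$cluster[idx], start = pos,
                            strand = strand, stringsAsFactors = FALSE))
  })
}

#' Simulate sample metadata with planted associations
#'
#' Generates bile-acid concentrations whose secondary/primary ratio is a
#' monotone function of the supplied cluster abundance plus Gaussian
#' noise on a latent scale, calibrated via the bivariate-normal rank
#' correlation identity (latent r of `2 * sin(pi * rho_s / 6)`) so the
#' realized Spearman correlation is approximately `rho_target`. Samples
#' are split between a healthy and a disease group; the disease group's
#' abundance is shifted by `-group_effect` on the log scale and the
#' shifted vector is returned alongside the metadata (the planted group
#' difference).
#'
#' @param abundance named numeric vector of per-sample cluster abundance
#'   (e.g. CPM); at least 10 samples.
#' @param rho_target target Spearman correlation in \[-1, 1\].
#' @param group_effect location shift (log scale) between healthy and
#'   disease abundance.
#' @param seed integer seed.
#' @param disease disease label for the non-healthy group.
#' @return list with `metadata` (sample_id, group, CA, CDCA, DCA, LCA),
#'   `abundance` (group-shifted copy of the input) and `planted`.
#' @export
simulate_metadata <- function(abundance, rho_target, group_effect = 0,
                              seed = 1L, disease = "CD") {
  n <- length(abundance)
  if (n < 10) stop("need at least 10 samples")
  if (abs(rho_target) > 1) stop("rho_target must be in [-1, 1]")
  ids <- names(abundance) %||% sprintf("s%03d", seq_len(n))
  with_seed(seed, {
    r <- 2 * sin(pi * rho_target / 6)
    u <- qnorm((rank(abundance, ties.method = "average") - 0.5) / n)
    noise <- if (abs(r) < 1) rnorm(n) else numeric(n)
    y <- r * u + sqrt(max(0, 1 - r^2)) * noise
    ratio <- exp(y) # monotone transform; Spearman depends on ranks only
    ca <- runif(n, 0.5, 2); cdca <- runif(n, 0.5, 2)
    frac <- runif(n, 0.2, 0.8)
    dca <- ratio * (ca + cdca) * frac
    lca <- ratio * (ca + cdca) * (1 - frac)
    group <- rep(c("healthy", disease), length.out = n)[sample.int(n)]
    shifted <- abundance
    shifted[group == disease] <- shifted[group == disease] * exp(-group_effect)
    meta <- data.frame(sample_id = ids, group = group,
                       CA = ca, CDCA = cdca, DCA = dca, LCA = lca,
                       stringsAsFactors = FALSE)
    list(metadata = meta, abundance = setNames(shifted, ids),
         planted = list(rho_target = rho_target, group_effect = group_effect))
  })
}
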