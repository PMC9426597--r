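# Orchestration: discover -> cluster -> classify -> quantify ->
# associate -> report, driven by one configuration with a single master
# seed from which every stage derives a named substream. Re-running with
# an identical config reproduces byte-identical tables.

#' Default run configuration
#'
#' All thresholds of the analysis in one place: 50/90 identity/coverage
#' for the reference search stage, 30/90 for the metagenome stage, SSN
#' edge score 70, read matching at 90% identity / 20 bp, trimming at
#' Q30 / 50 bp, ANI species cutoff 95 - plus the synthetic-community
#' parameters used when no input paths are given.
#'
#' @param seed master seed.
#' @return a named list, serializable to YAML via [yaml::write_yaml()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = NULL,
    thresholds = list(
      ref_identity = 50, ref_coverage = 90,
      meta_identity = 30, meta_coverage = 90,
      ssn = 70,
      map_identity = 90, map_min_len = 20,
      trim_q = 30, trim_min_len = 50,
      ani_species = 95),
    fixture = list(
      n_families = 3L, members_per_family = 6L, n_decoys = 3L,
      within_identity = 0.98, between_identity = 0.45,
      n_samples = 12L, depth = 5000L, read_len = 100L, error_rate = 0.01,
      fractions = c(0.7, 0.2, 0.1), baie_fraction = 0.2,
      rho_target = 0.35, group_effect = 1.0))
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  chk <- function(x, lo, hi, nm) {
    if (is.null(x) || x < lo || x > hi)
      stop("config threshold out of range: ", nm)
  }
  chk(th$ref_identity, 0, 100, "ref_identity")
  chk(th$meta_identity, 0, 100, "meta_identity")
  chk(th$map_identity, 0, 100, "map_identity")
  chk(th$ssn, 0, 300, "ssn")
  chk(th$trim_q, 0, 41, "trim_q")
  chk(th$ani_species, 0, 100, "ani_species")
  invisible(cfg)
}

#' Generate the packaged synthetic study fixture
#'
#' Three planted BaiE families (one per SSN cluster, ~98% member-to-
#' ancestor identity, ancestors ~45% identity apart) plus unrelated
#' decoy proteins; one operon contig per family - complete for family 1
#' (the Table-layout candidate), missing baiCD for family 2, anchor-only
#' for family 3; per-sample read sets drawn at planted cluster fractions
#' with sequencing error; sample metadata with a planted bile-acid-ratio
#' correlation and disease-group effect.
#'
#' @param cfg a [default_config()]-shaped list.
#' @return list with `database`, `seed_queries`, `families` (planted
#'   membership), `contigs`, `contig_truth`, `gene_refs` (per-family
#'   baiE nucleotide sequences), `readsets`, `read_truth`, `metadata`,
#'   `ref_set`, `planted`.
#' @export
synth_fixture <- function(cfg = default_config()) {
  fx <- cfg$fixture
  seed <- cfg$seed
  proteins <- bai_reference_proteins(child_seed(seed, "refs"))
  # family ancestors: family 1 is near the reference BaiE, the others
  # are distant homologs of it
  ancestors <- character(fx$n_families)
  ancestors[1] <- proteins$baiE
  for (i in seq_len(fx$n_families)[-1])
    ancestors[i] <- mutate_family(
      family_spec(proteins$baiE, 1L, fx$between_identity,
                  child_seed(seed, paste0("anc", i))))$seq
  fam_names <- paste0("fam", seq_len(fx$n_families))
  families <- lapply(seq_len(fx$n_families), function(i)
    mutate_family(family_spec(ancestors[i], fx$members_per_family,
                              fx$within_identity,
                              child_seed(seed, paste0("fam", i))),
                  prefix = fam_names[i]))
  names(families) <- fam_names
  decoys <- with_seed(child_seed(seed, "decoys"),
                      seq_records(sprintf("decoy_%02d", seq_len(fx$n_decoys)),
                                  vapply(seq_len(fx$n_decoys),
                                         function(i) random_protein(177L),
                                         character(1)),
                                  "protein", "synthetic_decoy"))
  database <- do.call(rbind, c(families, list(decoys)))
  # one contig per family: complete operon / baiCD-deleted / anchor-only
  contigs <- list(); truth <- list()
  for (i in seq_len(fx$n_families)) {
    prot_i <- proteins
    prot_i$baiE <- families[[i]]$seq[1]
    spec <- if (i == 1) table1_operon_spec()
    else if (i == 2) {
      lay <- bai_operon_layout()
      keep <- lay$gene != "baiCD"
      operon_spec(lay$gene[keep], lay$strand[keep], complete = FALSE)
    } else operon_spec("baiE", "-", complete = FALSE)
    bc <- build_contig(spec, prot_i,
                       codon_seed = child_seed(seed, paste0("contig", i)),
                       contig_id = paste0(fam_names[i], "_contig"))
    contigs[[i]] <- bc$contig
    tr <- bc$truth
    tr$contig_id <- bc$contig$id
    tr$family <- fam_names[i]
    truth[[i]] <- tr
  }
  contig_truth <- do.call(rbind, truth)
  contig_tab <- do.call(rbind, contigs)
  # per-family baiE gene nucleotide sequences (the mapping references)
  gene_refs <- lapply(seq_len(fx$n_families), function(i) {
    tr <- truth[[i]]
    row <- tr[tr$gene == "baiE", ][1, ]
    g <- substr(contigs[[i]]$seq, row$start + 1L, row$end)
    if (row$strand == "-") g <- revcomp(g)
    seq_records(paste0(fam_names[i], "_baiE_nt"), g, "dna", "gene_ref")
  })
  names(gene_refs) <- fam_names
  # read sets: planted family fractions within the baiE compartment,
  # the rest of each sample is background (non-baiE) sequence
  fractions <- setNames(fx$fractions[seq_len(fx$n_families)], fam_names)
  fractions <- fractions / sum(fractions)
  baie_frac <- fx$baie_fraction %||% 0.2
  background <- seq_records("background_contig",
                            random_dna(3000L, child_seed(seed, "background")),
                            "dna", "background")
  read_contigs <- rbind(do.call(rbind, gene_refs), background)
  read_contigs$cluster <- c(fam_names, "background")
  # read-sampling weight is abundance x length; divide the target read
  # fractions by contig length so realized read fractions match them
  read_frac <- c(fractions * baie_frac,
                 setNames(1 - baie_frac, "background"))
  rel_ab <- read_frac / nchar(read_contigs$seq)[match(names(read_frac),
                                                      read_contigs$cluster)]
  rel_ab <- rel_ab / sum(rel_ab)
  readsets <- list(); read_truth <- list()
  if (fx$depth >= 1 && fx$n_samples >= 1) {
    for (s in seq_len(fx$n_samples)) {
      cs <- community_spec(read_contigs, rel_ab, fx$depth,
                           fx$read_len, fx$error_rate,
                           seed = child_seed(seed, paste0("reads", s)))
      sim <- simulate_reads(cs, sample_id = sprintf("s%03d", s))
      readsets[[s]] <- sim$reads
      read_truth[[s]] <- sim$truth
    }
  }
  list(database = database, seed_queries = seq_records(
         "BaiE_verified", ancestors[1], "protein", "verified_query"),
       families = families, contigs = contig_tab,
       contig_truth = contig_truth, gene_refs = gene_refs,
       readsets = readsets, read_truth = read_truth,
       ref_set = bai_reference_set(proteins = proteins),
       planted = list(fractions = fractions,
                      candidate_family = fam_names[1],
                      rho_target = fx$rho_target,
                      group_effect = fx$group_effect))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their fixed order - homology discovery, SSN
#' clustering, genome-neighborhood classification, read quantification,
#' association statistics - on either supplied inputs or the packaged
#' synthetic fixture, writing every intermediate table under
#' `config$out_dir` and returning a structured report. Fully
#' deterministic under a fixed config seed.
#'
#' @param config a [default_config()]-shaped list (e.g. from
#'   [read_config()]).
#' @return a `run_report` list: `cluster_table`, `verdicts`,
#'   `abundance`, `comparisons`, `correlations`, `provenance` (config
#'   hash, seed, per-stage input/output counts) and `hash` (md5 over the
#'   written tables).
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  out_dir <- config$out_dir %||% tempfile("baiminer_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  counts <- list()
  fx <- synth_fixture(config)
  log_msg("pipeline: %d database proteins, %d samples",
          nrow(fx$database), length(fx$readsets))

  # stage 1: iterative discovery (metagenome-stage thresholds)
  disc <- iterative_expand(
    fx$seed_queries, fx$database,
    params = search_params(min_identity = th$meta_identity,
                           min_coverage = th$meta_coverage),
    ssn_threshold = th$ssn)
  counts$discovery <- c(database = nrow(fx$database),
                        accepted = nrow(disc$accepted),
                        rounds = disc$rounds)

  # stage 2: SSN over queries plus every sequence the search reached
  # (clusters without a query stay in the network, as unaccepted hits)
  pool <- disc$pool
  graph <- build_ssn(pool, search_params(), threshold = th$ssn)
  clusters <- ssn_components(graph, query_ids = fx$seed_queries$id)
  cluster_table <- cluster_report(clusters, graph)
  counts$ssn <- c(nodes = length(graph$nodes), edges = nrow(graph$edges),
                  clusters = nrow(cluster_table))

  # map planted families to SSN cluster ids via their first member
  fam_cluster <- vapply(names(fx$families), function(f) {
    m <- intersect(fx$families[[f]]$id, clusters$member)
    if (!length(m)) return(NA_integer_)
    clusters$cluster_id[match(m[1], clusters$member)]
  }, integer(1))

  # stage 3: neighborhood classification per family contig
  calls <- list()
  for (f in names(fx$families)) {
    contig <- fx$contigs[fx$contigs$id == paste0(f, "_contig"), ,
                         drop = FALSE]
    if (!nrow(contig)) next
    orfs <- extract_orfs(contig)
    tr <- fx$contig_truth[fx$contig_truth$contig_id == contig$id &
                            fx$contig_truth$gene == "baiE", ][1, ]
    anchor <- orfs$orf_id[orfs$start == tr$start & orfs$end == tr$end]
    if (!length(anchor)) next
    ann <- annotate_neighborhood(contig, orfs, fx$ref_set,
                                 anchor = anchor[1])
    calls[[f]] <- classify_operon(contig$id, ann, fx$ref_set)
  }
  verdicts <- data.frame(
    family = names(calls),
    cluster_id = fam_cluster[names(calls)],
    contig_id = vapply(calls, `[[`, character(1), "contig_id"),
    verdict = vapply(calls, `[[`, character(1), "verdict"),
    missing_required = vapply(calls, function(x)
      paste(x$missing_required, collapse = ","), character(1)),
    cluster_verdict = vapply(names(calls), function(f)
      cluster_verdict(calls[f]), character(1)),
    stringsAsFactors = FALSE)
  counts$gnn <- c(contigs = length(calls),
                  candidates = sum(verdicts$verdict == "candidate"))

  # stage 4: quantification
  abundance <- NULL
  if (length(fx$readsets)) {
    refs_by_cluster <- fx$gene_refs
    names(refs_by_cluster) <- as.character(fam_cluster[names(fx$gene_refs)])
    profs <- lapply(fx$readsets, function(rs) {
      trimmed <- quality_trim(rs, th$trim_q, th$trim_min_len)
      cnt <- match_reads(trimmed, refs_by_cluster, th$map_identity,
                         th$map_min_len)
      normalize_cpm(cnt, trimmed)
    })
    abundance <- do.call(rbind, profs)
    counts$abundance <- c(samples = length(profs),
                          assigned = sum(abundance$count))
  } else {
    warning("empty read set; quantification stage skipped")
    counts$abundance <- c(samples = 0L, assigned = 0L)
  }

  # stage 5: association statistics
  comparisons <- NULL; correlations <- NULL; metadata <- NULL
  if (!is.null(abundance) && length(fx$readsets) < 10) {
    warning("fewer than 10 samples; association stage skipped")
  } else if (!is.null(abundance)) {
    c1 <- as.character(fam_cluster[fx$planted$candidate_family])
    a1 <- abundance[abundance$cluster_id == c1, ]
    abd <- setNames(a1$cpm, a1$sample_id)
    sim <- simulate_metadata(abd, config$fixture$rho_target,
                             config$fixture$group_effect,
                             seed = child_seed(config$seed, "metadata"))
    metadata <- sim$metadata
    # planted group effect acts on the abundance side
    shifted <- abundance
    sel <- shifted$cluster_id == c1
    shifted$cpm[sel] <- sim$abundance[shifted$sample_id[sel]]
    comparisons <- compare_groups(shifted, metadata, c1)
    correlations <- correlate_ba(abundance, metadata,
                                 clusters = sort(unique(abundance$cluster_id)))
    counts$association <- c(comparisons = NROW(comparisons),
                            correlations = NROW(correlations))
  }

  # stage 6: write tables + provenance
  tabs <- list(cluster_table = cluster_table, verdicts = verdicts,
               abundance = abundance, comparisons = comparisons,
               correlations = correlations, metadata = metadata)
  files <- character(0)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(format(tabs[[nm]], digits = 12), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], cfg_file)
  file_md5 <- tools::md5sum(files)
  hash_file <- file.path(out_dir, "hashes.txt")
  writeLines(paste(basename(names(file_md5)), unname(file_md5)), hash_file)
  report_hash <- unname(tools::md5sum(hash_file))
  provenance <- list(seed = config$seed,
                     config_md5 = unname(tools::md5sum(cfg_file)),
                     counts = counts)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(cluster_table = cluster_table, verdicts = verdicts,
                 abundance = abundance, comparisons = comparisons,
                 correlations = correlations, metadata = metadata,
                 fixture = fx, provenance = provenance,
                 out_dir = out_dir, hash = report_hash),
            class = "run_report")
}
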