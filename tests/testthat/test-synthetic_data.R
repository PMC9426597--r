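test_that("family generator hits its identity target and is deterministic", {
  anc <- random_protein(177, seed = 21)

  # zero-mutation limit
  same <- mutate_family(family_spec(anc, 4, 1.0, 1))
  expect_true(all(same$seq == anc))

  # realized member-to-ancestor identity brackets the target
  ids <- unlist(lapply(1:20, function(s) {
    fam <- mutate_family(family_spec(anc, 3, 0.95, s))
    vapply(fam$seq, hamming_identity, numeric(1), b = anc)
  }))
  expect_gte(mean(ids) / 100, 0.92)
  expect_lte(mean(ids) / 100, 0.98)

  # determinism
  f1 <- mutate_family(family_spec(anc, 5, 0.9, 77))
  f2 <- mutate_family(family_spec(anc, 5, 0.9, 77))
  expect_identical(f1, f2)

  expect_error(family_spec(anc, 3, 0), "target_identity")
  expect_error(mutate_family(family_spec(random_protein(60, seed = 1), 1,
                                         0.9, 1)), NA)
  expect_error(mutate_family(family_spec(substr(anc, 1, 40), 1, 0.9, 1)),
               ">= 50")
})

test_that("contig builder lays out the canonical ten-gene operon exactly", {
  bc <- build_contig(table1_operon_spec(), codon_seed = 9)
  lay <- bai_operon_layout()
  expect_equal(bc$truth$gene, lay$gene)
  expect_equal(bc$truth$strand, lay$strand)
  expect_equal(nrow(bc$truth), 10L)
  # intervals in order, 0-based half-open, stop codon included
  expect_true(all(diff(bc$truth$start) > 0))
  expect_equal(bc$truth$end - bc$truth$start, (lay$length_aa + 1L) * 3L)

  # translation of each interval recovers the planted protein
  orfs <- extract_orfs(bc$contig)
  hit <- merge(bc$truth, orfs, by = c("start", "end", "strand"))
  expect_equal(nrow(hit), 10L)
  expect_equal(hit$protein.x, hit$protein.y)

  # single-gene spec round-trips too
  one <- build_contig(operon_spec("baiE", "-"), codon_seed = 2)
  o1 <- extract_orfs(one$contig)
  expect_true(one$truth$protein[1] %in% o1$protein)

  # deleting a gene removes it from the truth
  lay2 <- lay[lay$gene != "baiCD", ]
  del <- build_contig(operon_spec(lay2$gene, lay2$strand, complete = FALSE),
                      codon_seed = 9)
  expect_false("baiCD" %in% del$truth$gene)
})

test_that("read simulator respects planted abundances, error model and seed", {
  g1 <- build_contig(operon_spec("baiE", "+"), codon_seed = 4)
  g2 <- build_contig(operon_spec("baiE", "+"),
                     proteins = list(baiE = random_protein(177, seed = 31)),
                     codon_seed = 5, contig_id = "contig2")
  ctg <- rbind(g1$contig, g2$contig)
  ctg$cluster <- c("A", "B")
  expect_equal(nchar(ctg$seq[1]), nchar(ctg$seq[2])) # equal lengths

  # error-free reads are exact substrings of a contig (either strand)
  spec0 <- community_spec(ctg, c(A = 0.5, B = 0.5), depth = 200,
                          read_len = 80, error_rate = 0, seed = 3)
  sim0 <- simulate_reads(spec0)
  both <- paste(c(ctg$seq, revcomp(ctg$seq)), collapse = "#")
  expect_true(all(vapply(sim0$reads$reads$seq, grepl, logical(1),
                         x = both, fixed = TRUE)))

  # planted 0.85/0.15 mixture recovered within 3 sigma at this depth
  depth <- 20000L
  spec <- community_spec(ctg, c(A = 0.85, B = 0.15), depth = depth,
                         read_len = 80, error_rate = 0.01, seed = 8)
  sim <- simulate_reads(spec)
  frac_a <- mean(sim$truth$cluster == "A")
  expect_lt(abs(frac_a - 0.85), 3 * sqrt(0.85 * 0.15 / depth))

  # determinism: byte-identical read sets
  again <- simulate_reads(spec)
  expect_identical(sim$reads$reads, again$reads$reads)

  expect_error(community_spec(ctg, c(A = 0.9, B = 0.2), 100), "sum to 1")
  expect_error(community_spec(ctg, c(A = 0.5, B = 0.5), 100,
                              error_rate = 0.5), "error_rate")
  expect_error(community_spec(ctg, c(A = 0.5, B = 0.5), 100,
                              read_len = 10000L), "shortest contig")
})

test_that("metadata simulator plants exact monotone limit and validates rho", {
  set.seed(9)
  abund <- exp(rnorm(40, 5))
  sim1 <- simulate_metadata(abund, rho_target = 1, seed = 2)
  ratio <- ba_ratio(sim1$metadata)
  expect_equal(unname(brute_spearman(abund, unname(ratio))), 1)

  expect_error(simulate_metadata(abund, 1.5), "rho_target")
  expect_error(simulate_metadata(abund[1:5], 0.5), "at least 10")

  # group shift is planted on the abundance side
  sim2 <- simulate_metadata(abund, 0.3, group_effect = 1, seed = 4)
  dis <- sim2$metadata$group != "healthy"
  expect_equal(unname(sim2$abundance[dis]), unname(abund[dis] * exp(-1)))
  expect_equal(unname(sim2$abundance[!dis]), unname(abund[!dis]))
})
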