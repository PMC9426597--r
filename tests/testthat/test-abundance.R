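mk_reads <- function(seqs, quals, sample_id = "s1") {
  read_set(sample_id,
           data.frame(id = sprintf("r%05d", seq_along(seqs)), seq = seqs,
                      qual = quals, stringsAsFactors = FALSE))
}

q40 <- function(n, len) rep(strrep("I", len), n)

test_that("quality trimming follows the sliding-window contract", {
  set.seed(15)
  seqs <- vapply(1:50, function(i) random_dna(100), character(1))
  rs <- mk_reads(seqs, q40(50, 100))
  out <- quality_trim(rs)
  expect_identical(out$reads$seq, seqs) # all-Q40 untouched
  expect_equal(out$total_reads, 50)

  # 100-bp read with a 60-bp Q2 tail trims below 50 bp and is dropped
  bad <- mk_reads(random_dna(100), paste0(strrep("I", 40), strrep("#", 60)))
  expect_equal(quality_trim(bad)$total_reads, 0)

  # idempotence on reads with block-structured quality
  mixed <- mk_reads(
    vapply(1:1000, function(i) random_dna(100), character(1)),
    vapply(1:1000, function(i) {
      lo1 <- sample(0:20, 1); lo2 <- sample(0:20, 1)
      paste0(strrep("#", lo1), strrep("I", 100 - lo1 - lo2), strrep("#", lo2))
    }, character(1)))
  t1 <- quality_trim(mixed)
  t2 <- quality_trim(t1)
  expect_identical(t1$reads, t2$reads)

  expect_error(mk_reads("ACGT", "II"), "mismatch")
})

test_that("read matching assigns by best passing hit only", {
  gene_a <- random_dna(500, seed = 23)
  gene_b <- random_dna(500, seed = 24)
  refs <- list(A = seq_records("geneA", gene_a, "dna"),
               B = seq_records("geneB", gene_b, "dna"))

  # error-free reads from A map 100% to A, on both strands
  set.seed(25)
  pos <- sample(0:400, 200, TRUE)
  seqs <- substring(gene_a, pos + 1, pos + 100)
  flip <- seq(1, 200, 2)
  seqs[flip] <- revcomp(seqs[flip])
  rs <- mk_reads(seqs, q40(200, 100))
  cnt <- match_reads(rs, refs)
  expect_equal(as.integer(cnt), c(200L, 0L))

  # a read at 85% identity to its source fails the 90% criterion
  r <- strsplit(substring(gene_a, 1, 100), "")[[1]]
  at <- seq(3, 100, length.out = 15)
  for (p in at) r[p] <- setdiff(c("A", "C", "G", "T"), r[p])[1]
  deg <- mk_reads(paste(r, collapse = ""), q40(1, 100))
  cnt85 <- match_reads(deg, refs)
  expect_equal(sum(cnt85), 0L)
  # the banded and exhaustive engines agree on it
  expect_equal(sum(match_reads(deg, refs, prefilter_k = 0L)), 0L)

  # alignment shorter than 20 bp never counts
  tiny <- mk_reads(substring(gene_a, 1, 15), strrep("I", 15))
  expect_equal(sum(match_reads(tiny, refs)), 0L)

  expect_error(match_reads(rs, list()), "empty cluster references")
})

test_that("CPM normalization and composition follow their definitions", {
  counts <- c(A = 85L, B = 15L)
  prof <- normalize_cpm(counts, 1e6, sample_id = "x")
  expect_equal(prof$cpm, c(85, 15))
  expect_equal(prof$fraction, c(0.85, 0.15))
  expect_equal(sum(prof$fraction), 1)

  # scale equivariance: composition invariant under depth rescaling
  prof2 <- normalize_cpm(counts * 10L, 1e7, sample_id = "x")
  expect_equal(prof2$fraction, prof$fraction)
  expect_equal(prof2$cpm, prof$cpm)

  zero <- normalize_cpm(c(A = 0L, B = 0L), 1000)
  expect_equal(zero$fraction, c(0, 0))
  expect_error(normalize_cpm(counts, 0), "positive")
})

test_that("recovered composition converges to the planted mixture with depth", {
  gene_a <- random_dna(500, seed = 33)
  gene_b <- random_dna(500, seed = 34)
  ctg <- rbind(seq_records("gA", gene_a, "dna"),
               seq_records("gB", gene_b, "dna"))
  ctg$cluster <- c("A", "B")
  refs <- list(A = seq_records("gA", gene_a, "dna"),
               B = seq_records("gB", gene_b, "dna"))
  err <- vapply(c(1000L, 10000L), function(depth) {
    spec <- community_spec(ctg, c(A = 0.8, B = 0.2), depth, 100, 0.01,
                           seed = depth)
    sim <- simulate_reads(spec)
    cnt <- match_reads(sim$reads, refs)
    abs(normalize_cpm(cnt, sim$reads)$fraction[1] - 0.8)
  }, numeric(1))
  expect_lt(err[2], 0.02)
  expect_lt(err[2], err[1] + 0.01) # no blow-up as depth grows
})
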