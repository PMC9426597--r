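test_that("ORF extraction finds minimal ORFs on both strands", {
  ctg <- seq_records("mini", "ATGAAATAA", "dna")
  orfs <- extract_orfs(ctg, min_protein_len = 1)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$protein, "MK")
  expect_equal(orfs$strand, "+")
  expect_equal(c(orfs$start, orfs$end), c(0L, 9L))

  rc <- seq_records("mini_rc", revcomp("ATGAAATAA"), "dna")
  orfs_rc <- extract_orfs(rc, min_protein_len = 1)
  expect_equal(orfs_rc$protein, "MK")
  expect_equal(orfs_rc$strand, "-")

  bad <- seq_records("ok", "ATGAAATAA", "dna")
  bad$seq <- "ATGRAATAA" # bypass constructor to hit the validator
  expect_error(extract_orfs(bad), "non-ACGTN")
})

test_that("local alignment matches the brute-force DP oracle", {
  p <- random_protein(177, seed = 13)
  self <- local_align(p, p)
  expect_equal(self$pct_identity, 100)
  expect_equal(self$query_coverage, 100)

  mut <- mutate_family(family_spec(p, 1, 0.8, 5))$seq
  other <- local_align(p, mut)
  expect_gte(self$raw_score, other$raw_score)

  set.seed(99)
  for (k in 1:10) {
    a <- random_protein_str(sample(10:30, 1))
    b <- random_protein_str(sample(10:30, 1))
    expect_equal(local_align(a, b)$raw_score, brute_sw_score(a, b))
  }

  # E-value decreases monotonically with raw score at fixed sizes
  params <- search_params(db_size = 1e6)
  bits <- (params$karlin_lambda * c(50, 100, 200) - log(params$karlin_k)) /
    log(2)
  expect_true(all(diff(bits) > 0))
  expect_error(local_align("", "MKL"), "empty sequence")
})

test_that("filtered search applies both cutoffs and is order-independent", {
  fams <- planted_families(31)
  q <- fams$f1[1, ]
  db <- rbind(fams$f1[-1, ], fams$f2)
  hits50 <- search(q, db, search_params(min_identity = 50))
  expect_setequal(hits50$subject_id, fams$f1$id[-1])
  expect_equal(hits50$pct_identity[1], max(hits50$pct_identity))

  # f2 sits ~45% from f1: invisible at 50%, found at 30%
  hits30 <- search(q, db, search_params(min_identity = 30))
  expect_setequal(hits30$subject_id, db$id)

  set.seed(2)
  perm <- db[sample(nrow(db)), ]
  hits_perm <- search(q, perm, search_params(min_identity = 30))
  expect_identical(hits30, hits_perm)

  expect_warning(h0 <- search(q, db[0, ], search_params()), "empty database")
  expect_equal(nrow(h0), 0L)
})

test_that("iterative expansion reaches its fixed point along planted chains", {
  fams <- planted_families(41)

  # seed already covering the whole family: one growth round
  res1 <- iterative_expand(fams$f1, fams$f1,
                           params = search_params(min_identity = 30))
  expect_equal(res1$rounds, 1L)
  expect_setequal(res1$accepted$id, fams$f1$id)

  # transitive chain seed -> A -> B -> C, each step ~45% identity, joined
  # through candidate operon verdicts (the GNN route for query-less
  # clusters); the seed only sees A at the 30% cutoff
  seed <- seq_records("seedq", random_protein(177, seed = 301), "protein")
  A <- mutate_family(family_spec(seed$seq, 1, 0.45, 311), "A")
  B <- mutate_family(family_spec(A$seq, 1, 0.45, 312), "B")
  C <- mutate_family(family_spec(B$seq, 1, 0.45, 313), "C")
  db <- rbind(A, B, C)
  verd <- setNames(rep("candidate", 3), db$id)
  res2 <- iterative_expand(seed, db,
                           params = search_params(min_identity = 30),
                           verdicts = verd)
  expect_equal(res2$rounds, 3L)
  expect_setequal(res2$accepted$id, db$id)

  # unrelated decoys below the identity floor are never accepted
  decoys <- seq_records(c("d1", "d2"),
                        c(random_protein(177, seed = 71),
                          random_protein(177, seed = 72)),
                        "protein")
  res3 <- iterative_expand(fams$f1[1, ], rbind(fams$f1[-1, ], decoys),
                           params = search_params(min_identity = 30))
  expect_length(intersect(res3$accepted$id, decoys$id), 0)

  # output independent of seed-query ordering
  two_seeds <- fams$f1[1:2, ]
  ra <- iterative_expand(two_seeds, fams$f1[-(1:2), ],
                         params = search_params(min_identity = 30))
  rb <- iterative_expand(two_seeds[2:1, ], fams$f1[-(1:2), ],
                         params = search_params(min_identity = 30))
  expect_setequal(ra$accepted$id, rb$accepted$id)
})
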