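test_that("alignment score is -log10(E), clamped and monotone", {
  mk <- function(e) data.frame(e_value = e)
  expect_equal(alignment_score(mk(1e-70)), 70)
  expect_equal(alignment_score(mk(1)), 0)
  expect_equal(alignment_score(mk(1e-310)), 300) # clamped near underflow
  expect_error(alignment_score(mk(0)), "positive")

  set.seed(4)
  e <- sort(10^runif(100, -200, 2))
  s <- alignment_score(mk(e))
  expect_true(all(diff(s) <= 0))
})

test_that("SSN edges separate planted families at the canonical threshold", {
  p <- random_protein(177, seed = 61)
  twin <- build_ssn(seq_records(c("a", "b"), c(p, p), "protein"),
                    threshold = 70)
  expect_equal(nrow(twin$edges), 1L)

  # two families at ~95% within / ~40% between: no cross edges at 70,
  # complete graph at threshold 0
  anc2 <- mutate_family(family_spec(p, 1, 0.40, 62))$seq
  fam1 <- mutate_family(family_spec(p, 4, 0.95, 63), "u")
  fam2 <- mutate_family(family_spec(anc2, 4, 0.95, 64), "v")
  g <- build_ssn(rbind(fam1, fam2), threshold = 70)
  cross <- xor(grepl("^u", g$edges$a), grepl("^u", g$edges$b))
  expect_false(any(cross))

  g0 <- build_ssn(rbind(fam1, fam2), threshold = 0)
  expect_equal(nrow(g0$edges), choose(8, 2))

  expect_error(build_ssn(fam1[1, ]), "at least 2")
})

test_that("components partition nodes and recover planted families exactly", {
  # edgeless graph: all singletons
  lone <- structure(list(nodes = letters[1:5],
                         edges = data.frame(a = character(0),
                                            b = character(0),
                                            score = numeric(0)),
                         alignments = data.frame(), threshold = 70),
                    class = "ssn_graph")
  cl0 <- ssn_components(lone)
  expect_equal(nrow(cl0), 5L)
  expect_equal(max(cl0$cluster_id), 5L)

  fams <- planted_families(71)
  pool <- do.call(rbind, fams)
  g <- build_ssn(pool, threshold = 70)
  cl <- ssn_components(g, query_ids = fams$f1$id[1])
  # partition property
  expect_setequal(cl$member, pool$id)
  expect_equal(anyDuplicated(cl$member), 0L)
  # planted partition recovered exactly
  planted <- substr(pool$id, 1, 2)
  got <- cl$cluster_id[match(pool$id, cl$member)]
  expect_equal(rand_index(planted, got), 1.0)
  expect_true(all(cl$contains_query ==
                    (cl$cluster_id == got[match(fams$f1$id[1], pool$id)])))

  # raising the threshold refines, never merges
  g90 <- build_ssn(pool, threshold = 90)
  cl90 <- ssn_components(g90)
  got90 <- cl90$cluster_id[match(pool$id, cl90$member)]
  agree <- outer(got90, got90, "==")
  agree70 <- outer(got, got, "==")
  expect_true(all(agree70[agree])) # co-clustered at 90 => co-clustered at 70
})

test_that("cluster report matches a brute-force within-identity oracle", {
  fam <- mutate_family(family_spec(random_protein(177, seed = 81), 5, 0.93,
                                   82), "w")
  g <- build_ssn(fam, threshold = 70)
  cl <- ssn_components(g)
  rep <- cluster_report(cl, g)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$size, 5L)
  # brute-force minimum pairwise identity (no indels planted)
  ids <- combn(fam$seq, 2, function(p) hamming_identity(p[1], p[2]))
  expect_lt(abs(rep$min_within_identity - min(ids)), 3)

  same <- seq_records(c("x", "y", "z"), rep(fam$seq[1], 3), "protein")
  gs <- build_ssn(same, threshold = 70)
  rs <- cluster_report(ssn_components(gs), gs)
  expect_equal(rs$min_within_identity, 100)

  # report sorted by size descending
  mixed <- rbind(fam, seq_records("lonely", random_protein(177, seed = 83),
                                  "protein"))
  gm <- build_ssn(mixed, threshold = 70)
  rm_ <- cluster_report(ssn_components(gm), gm)
  expect_true(all(diff(rm_$size) <= 0))
  expect_equal(rm_$min_within_identity[rm_$size == 1], 100)
})

test_that("SSN exports are written and re-readable", {
  fam <- mutate_family(family_spec(random_protein(177, seed = 91), 3, 0.96,
                                   92), "e")
  g <- build_ssn(fam, threshold = 70)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ssn_edges(g, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(g$edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  doc <- xml2::read_xml(gml) # well-formed XML
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")),
               length(g$nodes))
})
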