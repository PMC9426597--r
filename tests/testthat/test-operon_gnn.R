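# shared fixture: canonical complete operon contig + annotation helper
local({
  protos <- bai_reference_proteins(501)
  ref <- bai_reference_set(proteins = protos)
  bc <- build_contig(table1_operon_spec(), protos, codon_seed = 502)

  annotate_contig <- function(contig, truth, ref) {
    orfs <- extract_orfs(contig)
    tr <- truth[truth$gene == "baiE", ][1, ]
    if (is.na(tr$gene)) tr <- truth[1, ] # no baiE: anchor on first gene
    anchor <- orfs$orf_id[orfs$start == tr$start & orfs$end == tr$end]
    annotate_neighborhood(contig, orfs, ref, anchor = anchor[1])
  }

  test_that("neighborhood annotation names every planted operon gene", {
    ann <- annotate_contig(bc$contig, bc$truth, ref)
    hit <- merge(bc$truth, ann, by = c("start", "end", "strand"))
    expect_equal(nrow(hit), 10L)
    expect_equal(hit$assignment, hit$gene)
    # spurious ORFs (if any) are unassigned, not mislabelled
    extra <- ann[!ann$start %in% bc$truth$start, ]
    if (nrow(extra)) expect_true(all(extra$assignment == "unassigned"))
    # anchor must exist
    orfs <- extract_orfs(bc$contig)
    expect_error(annotate_neighborhood(bc$contig, orfs, ref,
                                       anchor = "nope"), "anchor")
  })

  test_that("completeness verdict flips for each single required-gene deletion", {
    ann <- annotate_contig(bc$contig, bc$truth, ref)
    call <- classify_operon(bc$contig$id, ann, ref)
    expect_equal(call$verdict, "candidate")
    expect_length(call$missing_required, 0)

    lay <- bai_operon_layout()
    for (g in ref$required) {
      keep <- !(lay$gene == g)
      spec <- operon_spec(lay$gene[keep], lay$strand[keep], complete = FALSE)
      bdel <- build_contig(spec, protos, codon_seed = 502,
                           contig_id = paste0("del_", g))
      anndel <- annotate_contig(bdel$contig, bdel$truth, ref)
      cdel <- classify_operon(bdel$contig$id, anndel, ref)
      expect_equal(cdel$verdict, "non-candidate", label = g)
      expect_equal(cdel$missing_required, g)
    }
  })

  test_that("verdicts are invariant under contig reverse-complement", {
    rc <- bc$contig
    rc$seq <- revcomp(rc$seq)
    L <- nchar(rc$seq)
    tr_rc <- bc$truth
    tr_rc$start <- L - bc$truth$end
    tr_rc$end <- L - bc$truth$start
    tr_rc$strand <- ifelse(bc$truth$strand == "+", "-", "+")
    ann_rc <- annotate_contig(rc, tr_rc, ref)
    call_rc <- classify_operon(rc$id, ann_rc, ref)
    expect_equal(call_rc$verdict, "candidate")
    expect_setequal(call_rc$present,
                    classify_operon(bc$contig$id,
                                    annotate_contig(bc$contig, bc$truth, ref),
                                    ref)$present)
  })

  test_that("regulator-only contigs and short anchors classify sensibly", {
    # contig with only barA/barB: everything required is missing
    spec <- operon_spec(c("barA", "barB"), c("+", "+"), complete = FALSE)
    bb <- build_contig(spec, protos, codon_seed = 503, contig_id = "bars")
    orfs <- extract_orfs(bb$contig)
    anchor <- orfs$orf_id[orfs$start == bb$truth$start[1]]
    ann <- annotate_neighborhood(bb$contig, orfs, ref, anchor = anchor[1])
    cb <- classify_operon("bars", ann, ref)
    expect_equal(cb$verdict, "non-candidate")
    expect_setequal(cb$missing_required, ref$required)

    # anchor-only neighborhood is resolvable = FALSE -> indeterminate
    short <- build_contig(operon_spec("baiE", "-", intergenic_len = 30L,
                                      complete = FALSE),
                          protos, codon_seed = 504, contig_id = "shorty")
    anns <- annotate_contig(short$contig, short$truth, ref)
    cs <- classify_operon("shorty", anns, ref)
    expect_false(cs$resolvable)
    expect_equal(cluster_verdict(list(cs)), "indeterminate")

    # existential cluster rule
    cand <- classify_operon(bc$contig$id,
                            annotate_contig(bc$contig, bc$truth, ref), ref)
    expect_equal(cluster_verdict(list(cb, cand)), "candidate")
    expect_equal(cluster_verdict(list(cb)), "non-candidate")
  })
})
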