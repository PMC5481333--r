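test_that("intron retention candidates come from junction or boundary evidence", {
  idx <- toy_index()
  # fully spliced annotated intron: junction reads, no boundary reads
  j <- mk_junctions("chr1", 200, 300, count = 20)
  ev <- mk_evidence("chr1", 200, 300, "s1")
  ir <- detect_intron_retention(j, ev, idx)
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$gene_id, "A")
  # no annotated transcript retains this intron -> retention state is novel
  expect_true(ir$novel)

  # annotated retention: a transcript whose exon spans the intron
  ret <- rbind(as.data.frame(toy_models()), data.frame(
    gene_id = "A", gene_name = "A", transcript_id = "A.3", chrom = "chr1",
    strand = "+", start = 100, end = 400, stringsAsFactors = FALSE))
  idx_ret <- build_annotation_index(gene_models(ret))
  ir2 <- detect_intron_retention(j, ev, idx_ret)
  expect_false(ir2$novel[ir2$v_start == 200 & ir2$v_end == 300])

  # unannotated intron interval with boundary reads only -> novel event
  ev_nov <- mk_evidence("chr1", 410, 480, "s1", left = 3, right = 5)
  ir3 <- detect_intron_retention(mk_junctions("chr1", 1, 2, count = 0),
                                 ev_nov, idx)
  expect_equal(nrow(ir3), 1L)
  expect_true(ir3$novel)

  # evidence rows with neither junction nor boundary support yield no event
  ir4 <- detect_intron_retention(mk_junctions("chr1", 1, 2, count = 0),
                                 mk_evidence("chr1", 200, 300, "s1"), idx)
  expect_equal(nrow(ir4), 0L)
})

test_that("exon skipping requires the full junction triple", {
  idx <- toy_index()
  j3 <- mk_junctions("chr1", c(200, 400, 200), c(300, 500, 500), count = 5)
  es <- detect_exon_skipping(j3, idx)
  expect_equal(nrow(es), 1L)
  expect_equal(c(es$v_start, es$v_end), c(200, 500))
  expect_equal(c(es$c1_end, es$c2_start), c(300, 400))   # middle exon
  expect_false(es$novel)                                  # A.2 annotates it

  # annotation without the skip isoform and no observed skip -> no event
  no_skip <- toy_models()
  no_skip <- gene_models(no_skip[no_skip$transcript_id != "A.2", ])
  idx_ns <- build_annotation_index(no_skip)
  es2 <- detect_exon_skipping(
    mk_junctions("chr1", c(200, 400), c(300, 500), count = 5), idx_ns)
  expect_equal(nrow(es2), 0L)

  # observed but unannotated skip junction -> novel event
  es3 <- detect_exon_skipping(j3, idx_ns)
  expect_equal(nrow(es3), 1L)
  expect_true(es3$novel)

  # middle exons longer than the guard are not considered
  far <- mk_junctions("chr1", c(200, 90000, 200), c(300, 95000, 95000),
                      count = 5)
  es_far <- detect_exon_skipping(far, idx, max_middle_exon = 10000L)
  expect_false(any(es_far$v_end == 95000))
})

test_that("alternative splice sites pair junctions sharing one end", {
  idx <- plain_index()

  # shared acceptor 400, competing donors 200/250 (+ strand) -> one A5SS
  a5 <- detect_alt_ss(mk_junctions("chr1", c(200, 250), c(400, 400),
                                   count = c(10, 5)), idx, "5SS")
  expect_equal(nrow(a5), 1L)
  expect_equal(a5$type, "ALT_5SS")
  # neither junction annotated: canonical is the higher-count one
  expect_equal(c(a5$c1_start, a5$v_start), c(200, 250))

  # shared donor 1200 (outside any annotated structure), two acceptors
  a3 <- detect_alt_ss(mk_junctions("chr1", c(1200, 1200), c(1400, 1450),
                                   count = c(10, 5)), idx, "3SS")
  expect_equal(nrow(a3), 1L)
  expect_equal(a3$type, "ALT_3SS")

  # a single donor per acceptor yields nothing
  expect_equal(nrow(detect_alt_ss(mk_junctions("chr1", c(700, 1000),
                                               c(900, 1100), count = 5),
                                  idx, "5SS")), 0L)
  # strandless junctions are skipped
  expect_equal(nrow(detect_alt_ss(mk_junctions("chr9", c(200, 250),
                                               c(400, 400), strand = "*",
                                               count = 5), idx, "5SS")), 0L)
  # annotated junction wins the canonical slot regardless of counts
  a5b <- detect_alt_ss(mk_junctions("chr1", c(400, 430), c(500, 500),
                                    count = c(1, 50)), idx, "5SS")
  expect_equal(nrow(a5b), 1L)
  expect_equal(c(a5b$c1_start, a5b$c1_end), c(400, 500))
  expect_equal(c(a5b$v_start, a5b$v_end), c(430, 500))
})

test_that("alternative first exons compete per gene, including novel donors", {
  idx <- toy_index()
  jb <- mk_junctions("chr2", c(1100, 1250), c(1300, 1300), count = c(12, 8))
  afe <- detect_alt_first_exon(jb, idx)
  afe_b <- afe[afe$gene_id == "B", ]
  expect_equal(nrow(afe_b), 2L)           # one event per donor
  expect_false(any(afe_b$novel))
  # gene A's two isoforms start from the same exon via different donors,
  # so it competes too, independent of observed counts
  expect_equal(nrow(afe[afe$gene_id == "A", ]), 2L)

  # gene with a single first exon -> no events
  afe_c <- detect_alt_first_exon(
    mk_junctions("chr3", 10100, 10200, strand = "-", count = 9), idx)
  expect_equal(nrow(afe_c[afe_c$gene_id == "C", ]), 0L)

  # observed donor splicing into the known acceptor from outside all exons
  jn <- rbind(jb, mk_junctions("chr2", 1280, 1300, count = 6))
  afe2 <- detect_alt_first_exon(jn, idx)
  expect_equal(nrow(afe2[afe2$gene_id == "B", ]), 3L)
  nov <- afe2[afe2$v_start == 1280, ]
  expect_true(nov$novel)

  # first-exon donor pairs are not double-reported as alternative 5' sites
  expect_equal(nrow(detect_alt_ss(jb, idx, "5SS")[
    detect_alt_ss(jb, idx, "5SS")$chrom == "chr2", ]), 0L)
  a5n <- detect_alt_ss(jn, idx, "5SS")
  expect_equal(nrow(a5n[a5n$chrom == "chr2", ]), 0L)
})

test_that("event detection is deterministic and free of duplicates", {
  cfg <- sim_config(n_genes = 25,
                    event_plan = default_event_plan()[seq(1, 60, 6), ],
                    novel_fraction = 0, seed = 8)
  sim <- simulate_annotation(cfg)
  counts <- simulate_counts(sim)
  idx <- build_annotation_index(sim$models)
  e1 <- detect_events(counts$junctions, counts$evidence, idx,
                      control = "normoxia")
  e2 <- detect_events(counts$junctions, counts$evidence, idx,
                      control = "normoxia")
  expect_identical(e1, e2)
  expect_equal(anyDuplicated(e1$event_id), 0L)
  # completeness: every ground-truth event with supporting reads is found
  # (alternative splice sites may be reported in swapped orientation)
  expect_true(all(truth_ids_found(sim$events, e1$event_id)))
})
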