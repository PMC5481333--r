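test_that("reads classify into the three evidence groups", {
  idx <- toy_index()
  # gapped read over intron [200,300) of gene A, anchors 20/20
  expect_equal(classify_read(mk_reads("chr1", 180, "20M100N20M"), idx, 6),
               "EXON_EXON")
  # contiguous read across the exon|intron border at 200 (10 exon, 30 intron)
  expect_equal(classify_read(mk_reads("chr1", 190, "40M"), idx, 6),
               "EXON_INTRON")
  # fully inside the intron
  expect_equal(classify_read(mk_reads("chr1", 220, "40M"), idx, 6),
               "INTRONIC")
  # gap anchored by less than min_overhang on one side -> OTHER, no fallback
  expect_equal(classify_read(mk_reads("chr1", 196, "4M100N36M"), idx, 6),
               "OTHER")
  # exonic-only read
  expect_equal(classify_read(mk_reads("chr1", 110, "40M"), idx, 6), "OTHER")
  # unknown chromosome -> OTHER with a warning
  expect_warning(
    g <- classify_read(mk_reads("chrZ", 100, "40M"), idx, 6), "absent")
  expect_equal(g, "OTHER")
})

test_that("junction counts follow gap-and-anchor rules", {
  expect_equal(nrow(extract_junction_counts(mk_reads(character(0),
                                                     integer(0),
                                                     character(0)))), 0L)
  r3 <- mk_reads("chr1", c(180, 180, 180), "20M100N20M")
  jc <- extract_junction_counts(r3, 6)
  expect_equal(jc$count, 3L)
  expect_equal(c(jc$start, jc$end), c(200, 300))

  # a two-gap read increments both junctions once
  r2 <- mk_reads("chr1", 100, "10M50N10M30N10M")
  jc2 <- extract_junction_counts(r2, 6)
  expect_equal(nrow(jc2), 2L)
  expect_equal(jc2$start, c(110, 170))
  expect_equal(jc2$end, c(160, 200))
  expect_equal(jc2$count, c(1L, 1L))
})

test_that("intron evidence accumulates boundaries, intronic reads and depth", {
  idx <- toy_index()
  # no reads anywhere near gene C's intron [10100,10200)
  ev0 <- collect_intron_evidence(mk_reads("chr1", 110, "40M"), idx, 6)
  c0 <- ev0[ev0$chrom == "chr3", ]
  expect_true(all(c0$left_count == 0 & c0$intronic_count == 0 &
                  c0$covered_fraction == 0))

  # one 40M read fully inside the 100-nt intron
  ev1 <- collect_intron_evidence(mk_reads("chr3", 10120, "40M"), idx, 6)
  c1 <- ev1[ev1$chrom == "chr3", ]
  expect_equal(c1$intronic_count, 1L)
  expect_equal(c1$mean_depth, 0.4)
  expect_equal(c1$covered_fraction, 0.4)

  # 2 left-border and 4 right-border reads, none inside
  reads <- mk_reads("chr3", c(rep(10080, 2), rep(10180, 4)), "40M")
  ev2 <- collect_intron_evidence(reads, idx, 6)
  c2 <- ev2[ev2$chrom == "chr3", ]
  expect_equal(c2$left_count, 2L)
  expect_equal(c2$right_count, 4L)
  expect_equal(c2$intronic_count, 0L)
  expect_equal(c2$covered_fraction, 0.4)   # 20 nt at each border
})

test_that("STAR SJ.out.tab rows convert to 0-based half-open junctions", {
  p <- tempfile()
  writeLines("chr1\t201\t300\t1\t1\t1\t7\t0\t20", p)
  jc <- read_sj_tab(p, "s1")
  expect_equal(jc$start, 200)
  expect_equal(jc$end, 300)
  expect_equal(jc$strand, "+")
  expect_equal(jc$count, 7)

  writeLines(character(0), p)
  expect_equal(nrow(read_sj_tab(p, "s1")), 0L)

  writeLines("chr1\t201\t300\t0\t1\t1\t7\t0\t20", p)
  unk <- read_sj_tab(p, "s1")
  expect_equal(unk$strand, "*")
  res <- resolve_junction_strand(unk, toy_index())
  expect_equal(res$strand, "+")   # unique overlap with gene A

  writeLines("chr1\t201\t300\t1\t1", p)
  expect_error(read_sj_tab(p, "s1"), "9 columns")
})

test_that("classification conserves reads and counting is order-invariant", {
  idx <- toy_index()
  set.seed(99)
  pool <- mk_reads(
    "chr1",
    c(180, 180, 190, 220, 110, 196, 380, 460),
    c("20M100N20M", "20M100N20M", "40M", "40M", "40M", "4M100N36M",
      "20M100N20M", "30M"))
  grp <- classify_reads(pool, idx, 6)
  expect_equal(length(grp), nrow(pool))
  expect_equal(sum(table(factor(grp, spliceIndex:::read_group_levels))),
               nrow(pool))

  shuf <- pool[sample(nrow(pool)), ]
  expect_equal(extract_junction_counts(shuf, 6),
               extract_junction_counts(pool, 6))
  expect_equal(collect_intron_evidence(shuf, idx, 6),
               collect_intron_evidence(pool, idx, 6))

  # anchor monotonicity: larger min_overhang never increases any count
  prev <- Inf
  for (oh in c(2, 6, 10, 25)) {
    tot <- sum(extract_junction_counts(pool, oh)$count)
    expect_lte(tot, prev)
    prev <- tot
  }
})
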