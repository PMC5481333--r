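small_plan <- function() default_event_plan()[seq(1, 60, by = 4), ]

test_that("the generator is seed-deterministic down to the bytes", {
  cfg <- sim_config(n_genes = 20, event_plan = small_plan(), seed = 13)
  s1 <- simulate_annotation(cfg)
  s2 <- simulate_annotation(cfg)
  g1 <- tempfile(); g2 <- tempfile()
  write_gtf(s1$models, g1); write_gtf(s2$models, g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_identical(simulate_counts(s1), simulate_counts(s2))
})

test_that("planned events get the structure their type needs", {
  plan <- data.frame(type = rep("ALT_FIRST_EXON", 5), dsi = 0.2,
                     phase = "both", baseline = 0.3)
  cfg <- sim_config(n_genes = 10, event_plan = plan, novel_fraction = 0,
                    seed = 3)
  sim <- simulate_annotation(cfg)
  idx <- build_annotation_index(sim$models)
  fed <- idx$first_exon_donors
  hosts <- unique(sim$events$gene_id)
  expect_equal(length(hosts), 5L)
  for (g in hosts) expect_gte(nrow(fed[fed$gene_id == g, ]), 2L)
  expect_error(sim_config(n_genes = 3, event_plan = plan),
               "configuration error")
})

test_that("novel events are absent from the emitted annotation", {
  plan <- data.frame(type = rep("EXON_SKIPPING", 6), dsi = 0.2,
                     phase = "both", baseline = 0.3)
  cfg <- sim_config(n_genes = 8, event_plan = plan, novel_fraction = 1,
                    seed = 5)
  sim <- simulate_annotation(cfg)
  idx <- build_annotation_index(sim$models)
  known <- spliceIndex:::junction_id(idx$junctions$chrom,
                                     idx$junctions$start, idx$junctions$end)
  skips <- spliceIndex:::junction_id(sim$events$chrom, sim$events$v_start,
                                     sim$events$v_end)
  expect_false(any(skips %in% known))
  expect_true(all(sim$events$novel))
})

test_that("empirical SI converges to the truth at high depth", {
  cfg <- sim_config(n_genes = 20, event_plan = small_plan(), depth = 1e5,
                    seed = 21)
  sim <- simulate_annotation(cfg)
  counts <- simulate_counts(sim)
  idx <- build_annotation_index(sim$models)
  ev <- detect_events(counts$junctions, counts$evidence, idx,
                      control = "normoxia")
  for (ph in c("acute", "chronic")) {
    cl <- call_events(ev, counts$junctions, counts$evidence, "normoxia", ph)
    r <- evaluate_calls(cl, sim, ph)
    expect_true(all(r$found))
    expect_lt(max(abs(r$dsi_est - r$dsi_true)), 0.01)
  }
})

test_that("extraction reproduces the simulator's tables from SAM exactly", {
  cfg <- sim_config(n_genes = 20, event_plan = small_plan(), seed = 17)
  sim <- simulate_annotation(cfg)
  counts <- simulate_counts(sim)
  idx <- build_annotation_index(sim$models)
  sams <- simulate_alignments(sim, counts, tempfile())
  reads <- do.call(rbind, lapply(names(sams), function(s)
    read_alignments(sams[[s]], s)))
  jx <- resolve_junction_strand(extract_junction_counts(reads, 6), idx)
  expect_equal(jx, counts$junctions)
  ev <- collect_intron_evidence(reads, idx, 6)
  expect_equal(ev, counts$evidence)
})

test_that("ground truth round-trips through TSV and matches detector ids", {
  cfg <- sim_config(n_genes = 20, event_plan = small_plan(),
                    novel_fraction = 0, seed = 9)
  sim <- simulate_annotation(cfg)
  path <- tempfile(fileext = ".tsv")
  write_ground_truth(sim, path)
  back <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(back$event_id, sim$events$event_id)
  expect_equal(ncol(back), ncol(sim$events))

  counts <- simulate_counts(sim)
  idx <- build_annotation_index(sim$models)
  det <- detect_events(counts$junctions, counts$evidence, idx,
                       control = "normoxia")
  expect_true(all(truth_ids_found(sim$events, det$event_id)))
})
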