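test_that("type shares report two decimals and nearest-integer forms", {
  counts <- c(INTRON_RETENTION = 1042, EXON_SKIPPING = 247,
              ALT_5SS = 180, ALT_3SS = 164, ALT_FIRST_EXON = 51)
  # scale total to 1684 as a composition
  counts["ALT_5SS"] <- 1684 - sum(counts[-3])
  st <- summarize_event_types(counts)
  ir <- st[st$type == "INTRON_RETENTION", ]
  expect_equal(ir$share_pct, round(1042 / 1684 * 100, 2))
  expect_equal(ir$share_int, 62)
  expect_equal(sum(st$share_pct), 100, tolerance = 0.011)

  eq <- summarize_event_types(setNames(rep(10, 5), names(counts)))
  expect_true(all(eq$share_pct == 20))
  one <- summarize_event_types(c(EXON_SKIPPING = 7))
  expect_equal(one$share_pct, 100)
  z <- summarize_event_types(setNames(rep(0, 5), names(counts)))
  expect_true(attr(z, "empty"))
  expect_true(all(z$share_pct == 0))
})

test_that("direction fractions come from the delta-SI sign", {
  expect_equal(summarize_direction(c(up = 132, down = 115))$pct_up, 53.44)
  expect_equal(summarize_direction(c(up = 0, down = 8))$pct_up, 0)
  expect_equal(summarize_direction(c(up = 3, down = 1))$pct_up, 75)

  calls <- data.frame(event_id = paste0("e", 1:4), type = "EXON_SKIPPING",
                      delta_si = c(0.3, 0.2, -0.4, 0.25),
                      significant = c(TRUE, TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  d <- summarize_direction(calls, "EXON_SKIPPING")
  expect_equal(d$n_up, 2)
  expect_equal(d$n_down, 1)
  expect_equal(d$pct_up, 66.67)
})

test_that("phase overlap shares use the union denominator", {
  po <- summarize_phase_overlap(c(shared = 339, a_only = 700, b_only = 664))
  expect_equal(po$union, 1703)
  expect_equal(po$shared_pct, 19.91)

  a <- data.frame(event_id = c("x", "y"), significant = TRUE)
  b <- data.frame(event_id = c("y", "z"), significant = TRUE)
  po2 <- summarize_phase_overlap(a, b)
  expect_equal(po2$shared, 1)
  expect_equal(po2$union, 3)
  expect_equal(summarize_phase_overlap(a, a)$shared_pct, 100)
  expect_equal(summarize_phase_overlap(
    a, data.frame(event_id = "q", significant = TRUE))$shared, 0)
})

test_that("novelty summaries count labelled calls", {
  expect_equal(summarize_novelty(c(novel = 3, known = 1))$pct_novel, 75)
  calls <- data.frame(event_id = 1:4, novel = c(TRUE, TRUE, FALSE, TRUE),
                      significant = c(TRUE, TRUE, TRUE, FALSE))
  n <- summarize_novelty(calls)
  expect_equal(n$n_novel, 2)
  expect_equal(n$n_known, 1)
})

test_that("concordance is the squared Pearson correlation", {
  x <- c(-0.2, 0.1, 0.4)
  expect_equal(concordance(x, x), 1)
  expect_equal(concordance(x, -x), 1)
  expect_equal(concordance(c(1, 2, 3), c(1, 2, 4)), 27 / 28)
  expect_warning(r <- concordance(1, 2), "undefined")
  expect_true(is.na(r))
  expect_warning(concordance(c(1, 1, 1), c(1, 2, 3)), "undefined")
})

test_that("the pipeline validates thresholds and produces its artifacts", {
  cfg <- sim_config(n_genes = 12,
                    event_plan = default_event_plan()[seq(1, 60, 12), ],
                    seed = 2)
  expect_error(run_pipeline(cfg, tempfile(), dsi_min = 1.01), "dsi_min")
  out <- tempfile()
  res <- run_pipeline(cfg, out, use_sam = FALSE, quiet = TRUE)
  expect_true(all(file.exists(file.path(out, c(
    "annotation.gtf", "events.tsv", "junction_counts.tsv",
    "intron_evidence.tsv", "splicing_calls_acute.tsv",
    "splicing_calls_chronic.tsv", "expression_acute.tsv", "report.tsv",
    "ground_truth.tsv", "manifest.tsv")))))
  # reported percentages recompute from the underlying calls
  rep <- res$report
  st <- summarize_event_types(res$calls$acute)
  for (tt in st$type) {
    expect_equal(rep$value[rep$comparison == "acute" &
                           rep$metric == paste0("share_pct_", tt)],
                 st$share_pct[st$type == tt])
  }
})
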