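# End-to-end pipeline on a simulated fixture: simulate -> write annotation &
# alignments -> extract -> detect -> call -> expression -> report, all
# deterministic under the configuration seed.

#' Run the full pipeline on a simulated fixture
#'
#' Simulates annotation, counts and (optionally) SAM alignments, re-ingests
#' everything through the extraction module, detects candidate events, calls
#' differential splicing for every treated condition against the control,
#' makes fold-change expression calls, and writes all result tables plus a
#' run manifest to `out_dir`. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param use_sam Realise counts as SAM files and re-extract them (default
#'   `TRUE`); otherwise the simulated count tables are used directly.
#' @param dsi_min,fdr_max,min_support Significance parameters passed to
#'   [call_events()].
#' @param fc_min Expression fold-change gate.
#' @param min_overhang Junction/border anchor for extraction.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the index, count tables, events, per-phase
#'   calls and expression tables, summary report and file paths.
#' @export
run_pipeline <- function(config, out_dir, use_sam = TRUE,
                         dsi_min = 0.15, fdr_max = 0.01, min_support = 10L,
                         fc_min = 1.5, min_overhang = 6L, quiet = FALSE) {
  if (dsi_min < 0 || dsi_min > 1) stop("dsi_min out of range [0, 1]")
  if (fdr_max <= 0 || fdr_max > 1) stop("fdr_max out of range (0, 1]")
  if (fc_min < 1) stop("fc_min must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[spliceIndex] ", ...)
  control <- config$conditions[1]
  treated <- config$conditions[-1]

  say("simulating annotation and ground truth (seed ", config$seed, ")")
  sim <- simulate_annotation(config)
  gtf <- file.path(out_dir, "annotation.gtf")
  write_gtf(sim$models, gtf)
  counts <- simulate_counts(sim)
  write_ground_truth(sim, file.path(out_dir, "ground_truth.tsv"))

  say("building annotation index from ", gtf)
  index <- build_annotation_index(read_gtf(gtf))

  if (use_sam) {
    say("writing and re-extracting SAM alignments")
    sams <- simulate_alignments(sim, counts, file.path(out_dir, "alignments"))
    reads <- do.call(rbind, lapply(names(sams), function(s)
      read_alignments(sams[[s]], s)))
    junctions <- resolve_junction_strand(
      extract_junction_counts(reads, min_overhang), index)
    evidence <- collect_intron_evidence(reads, index, min_overhang)
  } else {
    junctions <- counts$junctions
    evidence <- counts$evidence
  }
  write_tsv(junctions, file.path(out_dir, "junction_counts.tsv"))
  write_tsv(evidence, file.path(out_dir, "intron_evidence.tsv"))

  say("detecting candidate events")
  events <- detect_events(junctions, evidence, index, control = control)
  write_tsv(events, file.path(out_dir, "events.tsv"))

  calls <- list()
  expression <- list()
  gene_counts <- normalize_cpm(counts$gene_counts)
  for (tr in treated) {
    say("calling ", tr, " vs ", control)
    calls[[tr]] <- call_events(events, junctions, evidence, control, tr,
                               dsi_min, fdr_max, min_support)
    write_tsv(as.data.frame(calls[[tr]]),
              file.path(out_dir, paste0("splicing_calls_", tr, ".tsv")))
    expression[[tr]] <- call_differential(gene_counts, control, tr, fc_min)
    write_tsv(expression[[tr]],
              file.path(out_dir, paste0("expression_", tr, ".tsv")))
  }

  say("summarising")
  report <- list()
  for (tr in treated) {
    cl <- calls[[tr]]
    types <- summarize_event_types(cl)
    nov <- summarize_novelty(cl)
    ex <- expression[[tr]]
    de_up <- ex$gene_id[ex$call == "up"]
    de_down <- ex$gene_id[ex$call == "down"]
    spliced <- unique(cl$gene_id[cl$significant & !is.na(cl$gene_id)])
    ovl <- expression_splicing_overlap(de_up, de_down, spliced)
    rows <- rbind(
      data.frame(comparison = tr, metric = "significant_events",
                 value = sum(cl$significant)),
      data.frame(comparison = tr,
                 metric = paste0("share_pct_", types$type),
                 value = types$share_pct),
      data.frame(comparison = tr, metric = "pct_novel",
                 value = nov$pct_novel),
      data.frame(comparison = tr, metric = "de_up", value = length(de_up)),
      data.frame(comparison = tr, metric = "de_down",
                 value = length(de_down)),
      data.frame(comparison = tr, metric = "pct_up_and_spliced_of_union",
                 value = round(100 *
                   attr(ovl, "up_and_spliced_fraction"), 2))
    )
    for (tt in event_types) {
      d <- summarize_direction(cl, tt)
      rows <- rbind(rows, data.frame(
        comparison = tr, metric = paste0("pct_up_", tt), value = d$pct_up))
    }
    report[[tr]] <- rows
  }
  if (length(treated) >= 2L) {
    for (tt in event_types) {
      po <- summarize_phase_overlap(calls[[treated[1]]], calls[[treated[2]]],
                                    type = tt)
      report$overlap <- rbind(report$overlap, data.frame(
        comparison = paste(treated[1], treated[2], sep = "+"),
        metric = paste0("phase_shared_pct_", tt), value = po$shared_pct))
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  write_tsv(report, file.path(out_dir, "report.tsv"))

  manifest <- data.frame(
    key = c("package", "version", "seed", "n_genes", "conditions", "depth",
            "noise", "dsi_min", "fdr_max", "min_support", "fc_min",
            "min_overhang", "use_sam", "gtf_md5"),
    value = c("spliceIndex", as.character(packageVersion("spliceIndex")),
              config$seed, config$n_genes,
              paste(config$conditions, collapse = ","), config$depth,
              config$noise, dsi_min, fdr_max, min_support, fc_min,
              min_overhang, use_sam, unname(tools::md5sum(gtf))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  say("done: ", out_dir)

  invisible(list(sim = sim, counts = counts, index = index,
                 junctions = junctions, evidence = evidence, events = events,
                 calls = calls, expression = expression, report = report,
                 out_dir = out_dir))
}
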