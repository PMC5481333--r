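# Seeded synthetic-data generator: multi-isoform gene models, ground-truth
# splicing events of all five classes, per-sample junction / intron-evidence /
# gene count tables with Poisson (or negative binomial) noise, and SAM
# alignments that realise the count tables read for read.
#
# Geometry conventions (read length L, anchors L/2):
#   junction read    (L/2)M <gap>N (L/2)M        starting L/2 nt before the gap
#   boundary read    LM spanning an exon-intron border with L/2 nt each side
#   intronic read    LM fully inside the intron, deterministically tiled
#   expression read  LM fully inside a "safe" exon (one that overlaps no
#                    annotated intron interval, so it can never be classified
#                    as intronic or boundary evidence)

#' Simulation configuration
#'
#' Defaults describe the desk-scale fixture: 200 genes on synthetic
#' chromosomes, three conditions (normoxia control, acute and chronic
#' treatment, one library each), 60 planned events across the five classes
#' with true delta-SI in {0, +-0.2, +-0.4}, an expected 200 informative reads
#' per event, Poisson count noise, log-normal gene expression, and half of
#' the planned events left out of the emitted annotation (novel).
#'
#' @param n_genes Number of genes.
#' @param conditions Sample/condition names; the first is the control.
#' @param exon_length,intron_length Length ranges in nt.
#' @param exons_per_transcript Exon-count range (event hosts are raised to
#'   the structural minimum their event type needs).
#' @param expr_meanlog,expr_sdlog Log-normal parameters of expected gene
#'   expression (reads per library).
#' @param depth Expected informative reads per event and condition.
#' @param const_depth Expected reads on constitutive junctions.
#' @param noise `"poisson"` or `"nb"` (negative binomial).
#' @param nb_dispersion NB dispersion (size = 1/dispersion) when `noise="nb"`.
#' @param event_plan One row per planned event: `type`, `dsi` (true delta-SI),
#'   `phase` (`both`/`acute`/`chronic`), `baseline` SI in the control.
#' @param novel_fraction Probability that a planned event's variant form is
#'   omitted from the emitted GTF.
#' @param de_fraction,de_up_share,fc_range Gene-level differential-expression
#'   plan: fraction of genes DE per phase, share of those up, fold range.
#' @param read_length Simulated read length (nt).
#' @param seed Random seed fixing all draws.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       conditions = c("normoxia", "acute", "chronic"),
                       exon_length = c(100, 300),
                       intron_length = c(200, 800),
                       exons_per_transcript = c(4, 8),
                       expr_meanlog = log(100), expr_sdlog = 1,
                       depth = 200, const_depth = 50,
                       noise = c("poisson", "nb"), nb_dispersion = 0.05,
                       event_plan = default_event_plan(),
                       novel_fraction = 0.5,
                       de_fraction = 0.15, de_up_share = 0.7,
                       fc_range = c(1.6, 3.5),
                       read_length = 80, seed = 1) {
  noise <- match.arg(noise)
  cfg <- list(n_genes = n_genes, conditions = conditions,
              exon_length = exon_length, intron_length = intron_length,
              exons_per_transcript = exons_per_transcript,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              depth = depth, const_depth = const_depth, noise = noise,
              nb_dispersion = nb_dispersion, event_plan = event_plan,
              novel_fraction = novel_fraction, de_fraction = de_fraction,
              de_up_share = de_up_share, fc_range = fc_range,
              read_length = read_length, seed = seed)
  if (any(c(exon_length, intron_length, depth, read_length) <= 0))
    stop("configuration error: all sizes must be positive")
  if (min(exon_length) < read_length + 20)
    stop("configuration error: exons must fit a read plus margin")
  if (min(intron_length) < read_length + 120)
    stop("configuration error: introns must fit an intronic read plus borders")
  if (nrow(event_plan) > n_genes)
    stop("configuration error: more planned events than genes")
  if (!all(event_plan$type %in% event_types))
    stop("configuration error: unknown event type in plan")
  bad <- event_plan$baseline < 0 | event_plan$baseline > 1 |
    event_plan$baseline + event_plan$dsi < 0 |
    event_plan$baseline + event_plan$dsi > 1
  if (any(bad)) stop("configuration error: baseline or baseline+dsi outside",
                     " [0,1]")
  structure(cfg, class = "sim_config")
}

#' Default event plan: 12 events per class
#'
#' Per class: two null events and ten with true delta-SI +-0.2 / +-0.4,
#' phases cycling both / acute-only / chronic-only. Baseline SI is 0.3 for
#' non-negative effects and 0.5 for negative ones (so the variant form always
#' has room to fall).
#'
#' @return `data.frame` with columns `type`, `dsi`, `phase`, `baseline`.
#' @export
default_event_plan <- function() {
  dsi <- c(0, 0, 0.2, 0.2, 0.2, -0.2, -0.2, 0.4, 0.4, 0.4, -0.4, -0.4)
  plan <- do.call(rbind, lapply(event_types, function(tt) data.frame(
    type = tt, dsi = dsi,
    phase = rep(c("both", "acute", "chronic"), length.out = length(dsi)),
    stringsAsFactors = FALSE
  )))
  plan$baseline <- ifelse(plan$dsi < 0, 0.5, 0.3)
  plan
}

sim_noise_fun <- function(config) {
  if (config$noise == "poisson") {
    function(n, mu) rpois(n, mu)
  } else {
    size <- 1 / config$nb_dispersion
    function(n, mu) stats::rnbinom(n, mu = mu, size = size)
  }
}

# structural minimum exon count per hosted event type (keeps the altered
# region away from both strands' first exons)
min_exons_for <- function(type) {
  switch(type, EXON_SKIPPING = 5L, 4L)
}

#' Simulate annotation and ground truth
#'
#' Builds gene models hosting every planned event (the variant isoform is
#' annotated only for non-novel events), assigns true per-condition SI values
#' and per-gene expression/fold-change truth, and lays the genes out on
#' synthetic chromosomes.
#'
#' @param config A `sim_config`.
#' @return A `sim_truth` list: `models` (the emitted annotation as
#'   [gene_models()]), `events` (ground-truth event table with per-condition
#'   true SI), `genes` (expression truth), `chrom_lengths`, `config`.
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  plan <- config$event_plan
  n_events <- nrow(plan)
  L <- config$read_length
  half <- L %/% 2L
  shift <- half                                   # alt splice-site offset

  genes_per_chrom <- 50L
  gene_rows <- vector("list", config$n_genes)
  exon_rows <- vector("list", config$n_genes)
  event_rows <- vector("list", n_events)
  offset <- 0L
  chrom_len <- integer(0)

  for (g in seq_len(config$n_genes)) {
    chrom <- paste0("chrS", (g - 1L) %/% genes_per_chrom + 1L)
    if (g %% genes_per_chrom == 1L) offset <- 0L
    gid <- sprintf("G%04d", g)
    strand <- if (g %% 2L == 0L) "-" else "+"
    ev <- if (g <= n_events) plan[g, ] else NULL

    n_ex <- sample(seq(config$exons_per_transcript[1],
                       config$exons_per_transcript[2]), 1L)
    if (!is.null(ev)) n_ex <- max(n_ex, min_exons_for(ev$type))
    elen <- sample(seq(config$exon_length[1], config$exon_length[2]),
                   n_ex, replace = TRUE)
    ilen <- sample(seq(config$intron_length[1], config$intron_length[2]),
                   max(n_ex - 1L, 0L), replace = TRUE)
    if (!is.null(ev) && ev$type == "ALT_FIRST_EXON") {
      k <- if (strand == "+") 1L else n_ex - 1L
      ilen[k] <- max(ilen[k], 3L * config$exon_length[1])
    }
    start <- offset + 10000L
    ex_s <- integer(n_ex); ex_e <- integer(n_ex)
    pos <- start
    for (i in seq_len(n_ex)) {
      ex_s[i] <- pos; ex_e[i] <- pos + elen[i]
      pos <- ex_e[i] + if (i < n_ex) ilen[i] else 0L
    }
    offset <- pos
    chrom_len[chrom] <- max(chrom_len[chrom] %||% 0L, pos + 10000L)

    tx <- list(data.frame(s = ex_s, e = ex_e))       # isoform 1 (canonical)
    names(tx) <- paste0(gid, ".1")
    ev_row <- NULL
    if (!is.null(ev)) {
      novel <- runif(1) < config$novel_fraction
      type <- ev$type
      if (type == "INTRON_RETENTION") {
        v <- c(ex_e[2], ex_s[3])
        c1 <- v
        iso2 <- data.frame(s = c(ex_s[1], ex_s[2], ex_s[seq(4, n_ex)]),
                           e = c(ex_e[1], ex_e[3], ex_e[seq(4, n_ex)]))
        other <- ""
        c2 <- c(NA_integer_, NA_integer_)
      } else if (type == "EXON_SKIPPING") {
        c1 <- c(ex_e[2], ex_s[3])                    # upstream junction
        c2 <- c(ex_e[3], ex_s[4])                    # downstream junction
        v <- c(ex_e[2], ex_s[4])                     # skip junction
        iso2 <- data.frame(s = ex_s[-3], e = ex_e[-3])
        other <- ""
      } else if (type %in% c("ALT_5SS", "ALT_3SS")) {
        c1 <- c(ex_e[2], ex_s[3])                    # canonical junction
        left_shift <- (type == "ALT_5SS") == (strand == "+")
        if (left_shift) {                            # move the exon-2 end
          v <- c(ex_e[2] - shift, ex_s[3])
          iso2 <- data.frame(s = ex_s, e = replace(ex_e, 2L, ex_e[2] - shift))
        } else {                                     # move the exon-3 start
          v <- c(ex_e[2], ex_s[3] + shift)
          iso2 <- data.frame(s = replace(ex_s, 3L, ex_s[3] + shift), e = ex_e)
        }
        other <- ""
        c2 <- c(NA_integer_, NA_integer_)
      } else {                                       # ALT_FIRST_EXON
        if (strand == "+") {
          alt_s <- ex_e[1] + 50L
          alt_e <- alt_s + config$exon_length[1]
          v <- c(alt_e, ex_s[2])                     # variant donor junction
          can <- c(ex_e[1], ex_s[2])                 # canonical donor
          iso2 <- data.frame(s = c(alt_s, ex_s[-1]), e = c(alt_e, ex_e[-1]))
        } else {
          alt_s <- ex_e[n_ex - 1L] + 50L
          alt_e <- alt_s + config$exon_length[1]
          v <- c(ex_e[n_ex - 1L], alt_s)
          can <- c(ex_e[n_ex - 1L], ex_s[n_ex])
          iso2 <- data.frame(s = c(ex_s[-n_ex], alt_s),
                             e = c(ex_e[-n_ex], alt_e))
        }
        c1 <- can
        c2 <- c(NA_integer_, NA_integer_)
        other <- paste0(can[1], "-", can[2])
      }
      if (!novel) tx[[paste0(gid, ".2")]] <- iso2

      si0 <- ev$baseline
      si_a <- si0 + if (ev$phase %in% c("both", "acute")) ev$dsi else 0
      si_c <- si0 + if (ev$phase %in% c("both", "chronic")) ev$dsi else 0
      ev_row <- data.frame(
        event_id = "", type = type, gene_id = gid, chrom = chrom,
        strand = strand, v_start = v[1], v_end = v[2],
        c1_start = c1[1], c1_end = c1[2], c2_start = c2[1], c2_end = c2[2],
        other = other, novel = novel, phase = ev$phase,
        si_normoxia = si0, si_acute = si_a, si_chronic = si_c,
        dsi = ev$dsi, stringsAsFactors = FALSE
      )
      ev_row$event_id <- make_event_ids(ev_row)
      event_rows[[g]] <- ev_row
    }
    # occasional duplicate-structure isoform on non-event genes
    if (is.null(ev) && runif(1) < 0.3) {
      tx[[paste0(gid, ".dup")]] <- tx[[1]]
    }
    exon_rows[[g]] <- do.call(rbind, lapply(names(tx), function(tid) {
      data.frame(gene_id = gid, gene_name = gid, transcript_id = tid,
                 chrom = chrom, strand = strand,
                 start = tx[[tid]]$s, end = tx[[tid]]$e,
                 stringsAsFactors = FALSE)
    }))
    gene_rows[[g]] <- data.frame(gene_id = gid, chrom = chrom,
                                 strand = strand,
                                 start = ex_s[1], end = ex_e[n_ex],
                                 stringsAsFactors = FALSE)
  }

  genes <- do.call(rbind, gene_rows)
  genes$expr <- rlnorm(nrow(genes), config$expr_meanlog, config$expr_sdlog)
  fc_draw <- function(n) {
    de <- runif(n) < config$de_fraction
    up <- runif(n) < config$de_up_share
    fc <- runif(n, config$fc_range[1], config$fc_range[2])
    ifelse(de, ifelse(up, fc, 1 / fc), 1)
  }
  genes$fc_acute <- fc_draw(nrow(genes))
  genes$fc_chronic <- fc_draw(nrow(genes))

  events <- do.call(rbind, event_rows[!vapply(event_rows, is.null,
                                              logical(1))])
  if (is.null(events)) events <- data.frame()
  rownames(events) <- NULL

  structure(list(
    models = gene_models(do.call(rbind, exon_rows)),
    events = events,
    genes = genes,
    chrom_lengths = chrom_len,
    config = config
  ), class = "sim_truth")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# deterministic tiling offsets for n intronic reads in an intron of ilen nt
intronic_offsets <- function(n, ilen, rlen) {
  if (n == 0L) return(integer(0))
  if (n == 1L) return(0L)
  as.integer(floor((ilen - rlen) * (seq_len(n) - 1) / (n - 1)))
}

# coverage summary over intronic bases given boundary counts, tiled intronic
# reads, intron length and read length (mirrors the extraction definition)
ir_depth_summary <- function(l, r, n_intronic, ilen, rlen) {
  cov <- numeric(ilen)
  half <- rlen %/% 2L
  if (l > 0) cov[seq_len(half)] <- cov[seq_len(half)] + l
  if (r > 0) cov[seq(ilen - half + 1L, ilen)] <-
      cov[seq(ilen - half + 1L, ilen)] + r
  for (o in intronic_offsets(n_intronic, ilen, rlen)) {
    cov[seq(o + 1L, o + rlen)] <- cov[seq(o + 1L, o + rlen)] + 1
  }
  c(mean_depth = sum(cov) / ilen, covered_fraction = mean(cov > 0))
}

# introns of the canonical isoform of one gene, from the truth models
gene_isoform1_introns <- function(models, gid) {
  ex <- models[models$gene_id == gid &
               models$transcript_id == paste0(gid, ".1"), , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) < 2L) return(NULL)
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
}

#' Simulate per-sample count tables from ground truth
#'
#' For each event and sample the informative total is the configured depth;
#' variant support is drawn as `noise(depth * SI_true)` and canonical support
#' as `noise(depth * (1 - SI_true))`. Retention boundary reads are split
#' binomially between the two borders and intronic reads/depth scale with the
#' retention level. Constitutive junctions receive `noise(const_depth)` and
#' gene read counts `noise(expr * fold_change)`.
#'
#' @param sim A `sim_truth` from [simulate_annotation()].
#' @return List with `junctions` (junction count table), `evidence` (intron
#'   evidence table on the emitted annotation's intron grid) and
#'   `gene_counts` (`gene_id`, `sample_id`, `count`).
#' @export
simulate_counts <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 1L)
  draw <- sim_noise_fun(config)
  samples <- config$conditions
  L <- config$read_length
  ev <- sim$events

  index <- build_annotation_index(sim$models)
  it <- intron_table(index)

  jrows <- list()
  add_j <- function(chrom, start, end, strand, sample, count) {
    jrows[[length(jrows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, strand = strand,
      sample_id = sample, count = as.integer(count),
      stringsAsFactors = FALSE)
  }

  # evidence grid over the emitted annotation's intron intervals
  grid <- expand.grid(i = seq_len(nrow(it)), sample_id = samples,
                      stringsAsFactors = FALSE)
  evd <- data.frame(chrom = it$chrom[grid$i], start = it$start[grid$i],
                    end = it$end[grid$i], sample_id = grid$sample_id,
                    left_count = 0L, right_count = 0L, intronic_count = 0L,
                    mean_depth = 0, covered_fraction = 0,
                    stringsAsFactors = FALSE)
  evkey <- paste(evd$chrom, evd$start, evd$end, evd$sample_id)

  si_of <- function(e, s) {
    switch(s, normoxia = e$si_normoxia, acute = e$si_acute,
           chronic = e$si_chronic,
           if (s == samples[1]) e$si_normoxia else e$si_acute)
  }

  managed <- character(0)
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      T <- config$depth
      for (s in samples) {
        si <- si_of(e, s)
        a <- draw(1, T * si)
        b <- draw(1, T * (1 - si))
        if (e$type == "INTRON_RETENTION") {
          if (b > 0) add_j(e$chrom, e$v_start, e$v_end, e$strand, s, b)
          l <- rbinom(1, 2L * a, 0.5); r <- 2L * a - l
          n_i <- draw(1, T * si)
          m <- match(paste(e$chrom, e$v_start, e$v_end, s), evkey)
          evd$left_count[m] <- l; evd$right_count[m] <- r
          evd$intronic_count[m] <- n_i
          if (l + r + n_i > 0) {
            d <- ir_depth_summary(l, r, n_i, e$v_end - e$v_start, L)
            evd$mean_depth[m] <- d[["mean_depth"]]
            evd$covered_fraction[m] <- d[["covered_fraction"]]
          }
        } else if (e$type == "EXON_SKIPPING") {
          u <- draw(1, T * (1 - si)); d2 <- draw(1, T * (1 - si))
          if (a > 0) add_j(e$chrom, e$v_start, e$v_end, e$strand, s, a)
          if (u > 0) add_j(e$chrom, e$c1_start, e$c1_end, e$strand, s, u)
          if (d2 > 0) add_j(e$chrom, e$c2_start, e$c2_end, e$strand, s, d2)
        } else {                      # ALT_5SS / ALT_3SS / ALT_FIRST_EXON
          if (a > 0) add_j(e$chrom, e$v_start, e$v_end, e$strand, s, a)
          if (b > 0) add_j(e$chrom, e$c1_start, e$c1_end, e$strand, s, b)
        }
      }
      managed <- c(managed,
                   junction_id(e$chrom, e$v_start, e$v_end),
                   junction_id(e$chrom, e$c1_start, e$c1_end),
                   if (!is.na(e$c2_start))
                     junction_id(e$chrom, e$c2_start, e$c2_end))
    }
  }

  # constitutive junctions of every gene's canonical isoform
  for (g in seq_len(nrow(sim$genes))) {
    gid <- sim$genes$gene_id[g]
    intr <- gene_isoform1_introns(sim$models, gid)
    if (is.null(intr)) next
    keep <- !junction_id(sim$genes$chrom[g], intr$start, intr$end) %in%
      managed
    intr <- intr[keep, , drop = FALSE]
    if (nrow(intr) == 0L) next
    for (s in samples) {
      cnt <- draw(nrow(intr), config$const_depth)
      nz <- cnt > 0
      if (any(nz)) {
        add_j(sim$genes$chrom[g], intr$start[nz], intr$end[nz],
              sim$genes$strand[g], s, cnt[nz])
      }
    }
  }

  junctions <- do.call(rbind, jrows)
  if (is.null(junctions)) junctions <- empty_junction_counts()
  junctions <- junctions[order(junctions$chrom, junctions$start,
                               junctions$end, junctions$sample_id), ,
                         drop = FALSE]
  rownames(junctions) <- NULL

  evd <- evd[order(evd$chrom, evd$start, evd$end, evd$sample_id), ,
             drop = FALSE]
  rownames(evd) <- NULL

  fc_of <- function(s) {
    if (s == "acute") sim$genes$fc_acute
    else if (s == "chronic") sim$genes$fc_chronic
    else rep(1, nrow(sim$genes))
  }
  gc <- do.call(rbind, lapply(samples, function(s) data.frame(
    gene_id = sim$genes$gene_id, sample_id = s,
    count = draw(nrow(sim$genes), sim$genes$expr * fc_of(s)),
    stringsAsFactors = FALSE)))
  gc <- gc[order(gc$gene_id, gc$sample_id), , drop = FALSE]
  rownames(gc) <- NULL

  list(junctions = junctions, evidence = evd, gene_counts = gc)
}

# exons usable for expression reads: exons of the emitted annotation that do
# not intersect any annotated intron interval (so reads placed inside can
# never become boundary or intronic evidence)
safe_exons <- function(models, it, read_length = 80L) {
  ex <- unique(models[, c("gene_id", "chrom", "start", "end")])
  ex <- ex[ex$end - ex$start >= read_length, , drop = FALSE]
  if (nrow(it) == 0L) return(ex)
  egr <- GenomicRanges::GRanges(ex$chrom,
                                IRanges::IRanges(ex$start + 1L, ex$end))
  igr <- GenomicRanges::GRanges(it$chrom,
                                IRanges::IRanges(it$start + 1L, it$end))
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(egr, igr)))
  ex[setdiff(seq_len(nrow(ex)), hit), , drop = FALSE]
}

#' Realise count tables as SAM alignments
#'
#' Writes one SAM file per sample in which every junction count appears as
#' exactly that many gapped reads (anchors of half a read length), boundary
#' counts as border-spanning contiguous reads, intronic counts as reads tiled
#' across the intron, and gene counts as reads inside exons that carry no
#' splice evidence. Running the extraction module on these files reproduces
#' the emitted junction and intron-evidence tables exactly.
#'
#' @param sim A `sim_truth`.
#' @param counts Output of [simulate_counts()].
#' @param dir Output directory.
#' @return Named character vector of SAM paths (one per sample).
#' @export
simulate_alignments <- function(sim, counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- sim$config
  L <- config$read_length
  half <- L %/% 2L
  index <- build_annotation_index(sim$models)
  safe <- safe_exons(sim$models, intron_table(index), L)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(sim$chrom_lengths),
                     "\tLN:", sim$chrom_lengths))
  paths <- character(0)
  for (s in config$conditions) {
    recs <- list()
    j <- counts$junctions[counts$junctions$sample_id == s, , drop = FALSE]
    if (nrow(j) > 0L) {
      n <- j$count
      ri <- rep.int(seq_len(nrow(j)), n)
      gap <- j$end[ri] - j$start[ri]
      recs$junction <- data.frame(
        chrom = j$chrom[ri], pos = j$start[ri] - half,
        cigar = paste0(half, "M", gap, "N", half, "M"),
        stringsAsFactors = FALSE)
    }
    e <- counts$evidence[counts$evidence$sample_id == s &
                         (counts$evidence$left_count > 0 |
                          counts$evidence$right_count > 0 |
                          counts$evidence$intronic_count > 0), ,
                         drop = FALSE]
    if (nrow(e) > 0L) {
      brows <- list()
      for (k in seq_len(nrow(e))) {
        l <- e$left_count[k]; r <- e$right_count[k]
        ni <- e$intronic_count[k]
        ilen <- e$end[k] - e$start[k]
        pos <- c(rep(e$start[k] - half, l), rep(e$end[k] - half, r),
                 e$start[k] + intronic_offsets(ni, ilen, L))
        if (length(pos)) {
          brows[[k]] <- data.frame(chrom = e$chrom[k], pos = pos,
                                   cigar = paste0(L, "M"),
                                   stringsAsFactors = FALSE)
        }
      }
      recs$evidence <- do.call(rbind, brows)
    }
    g <- counts$gene_counts[counts$gene_counts$sample_id == s, , drop = FALSE]
    g <- g[g$count > 0, , drop = FALSE]
    if (nrow(g) > 0L) {
      grows <- vector("list", nrow(g))
      for (k in seq_len(nrow(g))) {
        sx <- safe[safe$gene_id == g$gene_id[k], , drop = FALSE]
        if (nrow(sx) == 0L) next
        n <- g$count[k]
        exi <- ((seq_len(n) - 1L) %% nrow(sx)) + 1L
        room <- sx$end[exi] - sx$start[exi] - L
        pos <- sx$start[exi] + ((seq_len(n) - 1L) * 53L) %% (room + 1L)
        grows[[k]] <- data.frame(chrom = sx$chrom[exi], pos = pos,
                                 cigar = paste0(L, "M"),
                                 stringsAsFactors = FALSE)
      }
      recs$gene <- do.call(rbind, grows)
    }
    all <- do.call(rbind, recs)
    path <- file.path(dir, paste0(s, ".sam"))
    if (is.null(all) || nrow(all) == 0L) {
      writeLines(header, path)
    } else {
      lines <- paste(sprintf("%s:%07d", s, seq_len(nrow(all))), 0L,
                     all$chrom, all$pos + 1L, 60L, all$cigar,
                     "*", 0L, 0L, "*", "*", sep = "\t")
      writeLines(c(header, lines), path)
    }
    paths[s] <- path
  }
  paths
}

#' Write ground truth to TSV
#'
#' Dumps the event truth table to `path` and the gene-level expression truth
#' alongside it (suffix `_genes.tsv`).
#'
#' @param sim A `sim_truth`.
#' @param path Output TSV path for the event table.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  write_tsv(sim$events, path)
  write_tsv(sim$genes, sub("\\.tsv$", "_genes.tsv", path))
  invisible(path)
}

#' Match splicing calls against simulator ground truth
#'
#' Events are matched by deterministic event id; for alternative splice sites
#' the variant/canonical orientation can flip when both junctions are
#' annotated and counts are close, so the swapped id is also tried with the
#' sign of the estimated delta-SI reversed.
#'
#' @param calls A `splicing_calls` table.
#' @param sim A `sim_truth`.
#' @param phase `"acute"` or `"chronic"` — which comparison `calls` represents.
#' @return `data.frame` with per-truth-event `dsi_true`, `dsi_est`,
#'   `significant` and `found`.
#' @export
evaluate_calls <- function(calls, sim, phase = c("acute", "chronic")) {
  phase <- match.arg(phase)
  ev <- sim$events
  si_t <- if (phase == "acute") ev$si_acute else ev$si_chronic
  dsi_true <- si_t - ev$si_normoxia
  m <- match(ev$event_id, calls$event_id)
  dsi_est <- calls$delta_si[m]
  sig <- calls$significant[m]
  swap <- is.na(m) & ev$type %in% c("ALT_5SS", "ALT_3SS")
  if (any(swap)) {
    sw <- ev[swap, ]
    tmp <- sw
    tmp$v_start <- sw$c1_start; tmp$v_end <- sw$c1_end
    tmp$c1_start <- sw$v_start; tmp$c1_end <- sw$v_end
    sid <- make_event_ids(tmp)
    m2 <- match(sid, calls$event_id)
    dsi_est[swap] <- -calls$delta_si[m2]
    sig[swap] <- calls$significant[m2]
    m[swap] <- m2
  }
  data.frame(event_id = ev$event_id, type = ev$type, novel = ev$novel,
             dsi_true = dsi_true, dsi_est = dsi_est,
             significant = ifelse(is.na(sig), FALSE, sig),
             found = !is.na(m), stringsAsFactors = FALSE)
}
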