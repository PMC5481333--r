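# Three-group read classification and junction / intron-evidence tabulation.
#
# Group 1 (EXON_EXON): reads with at least one splice gap (CIGAR N) anchored
#   by >= min_overhang aligned nt on each side.
# Group 2 (EXON_INTRON): contiguous reads bridging an annotated exon-intron
#   border with >= min_overhang nt on each side of the border.
# Group 3 (INTRONIC): contiguous reads fully inside an annotated intron.
# Everything else is OTHER. A read belongs to exactly one group, with
# precedence EXON_EXON > EXON_INTRON > INTRONIC: gap evidence is the
# strongest signal.

read_group_levels <- c("EXON_EXON", "EXON_INTRON", "INTRONIC", "OTHER")

# intron interval table used for classification: the annotated introns plus
# any caller-supplied novel intron intervals (chrom/start/end)
intron_table <- function(index, extra_introns = NULL) {
  it <- unique(index$junctions[, c("chrom", "start", "end")])
  if (!is.null(extra_introns) && nrow(extra_introns) > 0L) {
    it <- unique(rbind(it, extra_introns[, c("chrom", "start", "end")]))
  }
  it <- it[order(it$chrom, it$start, it$end), , drop = FALSE]
  rownames(it) <- NULL
  it
}

#' Classify aligned reads into the three splice-evidence groups
#'
#' @param reads Alignment `data.frame` from [read_alignments()].
#' @param index An `annotation_index`.
#' @param min_overhang Minimum aligned nt required on each side of a splice
#'   gap or of an exon-intron border (default 6).
#' @param extra_introns Optional `data.frame` (`chrom`, `start`, `end`) of
#'   additional (e.g. novel, junction-derived) intron intervals to classify
#'   against.
#' @return Character vector, one of `EXON_EXON`, `EXON_INTRON`, `INTRONIC`,
#'   `OTHER` per read.
#' @export
classify_reads <- function(reads, index, min_overhang = 6L,
                           extra_introns = NULL) {
  n <- nrow(reads)
  out <- rep("OTHER", n)
  if (n == 0L) return(out)
  known_chroms <- unique(c(index$genes$chrom,
                           if (!is.null(extra_introns)) extra_introns$chrom))
  unknown <- !(reads$chrom %in% known_chroms)
  if (any(unknown)) {
    warning(sum(unknown), " reads on chromosomes absent from the annotation",
            " were skipped")
  }

  gaps <- read_gaps(reads)
  has_good_gap <- unique(gaps$read[gaps$left_anchor >= min_overhang &
                                   gaps$right_anchor >= min_overhang])
  out[has_good_gap] <- "EXON_EXON"
  gapped <- unique(gaps$read)                  # any-gap reads never fall back
  contiguous <- setdiff(which(!unknown), gapped)
  if (length(contiguous) == 0L) {
    out[unknown] <- "OTHER"
    return(out)
  }

  it <- intron_table(index, extra_introns)
  blocks <- read_blocks(reads)
  cb <- blocks[blocks$read %in% contiguous, , drop = FALSE]
  if (nrow(it) > 0L && nrow(cb) > 0L) {
    # border bridging: border position p in [start+overhang, end-overhang]
    borders <- data.frame(chrom = rep(it$chrom, 2L),
                          pos = c(it$start, it$end))
    borders <- unique(borders)
    bgr <- GenomicRanges::GRanges(
      borders$chrom, IRanges::IRanges(borders$pos, width = 1L))
    ok <- (cb$end - cb$start) >= 2L * min_overhang
    qb <- cb[ok, , drop = FALSE]
    if (nrow(qb) > 0L) {
      qgr <- GenomicRanges::GRanges(
        reads$chrom[qb$read],
        IRanges::IRanges(qb$start + min_overhang + 1L,
                         qb$end - min_overhang))
      hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(qgr, bgr))
      out[unique(qb$read[hit])] <- "EXON_INTRON"
    }
    # fully intronic
    igr <- GenomicRanges::GRanges(
      it$chrom, IRanges::IRanges(it$start + 1L, it$end))
    left <- setdiff(contiguous, which(out != "OTHER"))
    lb <- cb[cb$read %in% left, , drop = FALSE]
    if (nrow(lb) > 0L) {
      lgr <- GenomicRanges::GRanges(
        reads$chrom[lb$read],
        IRanges::IRanges(lb$start + 1L, lb$end))
      win <- S4Vectors::queryHits(
        GenomicRanges::findOverlaps(lgr, igr, type = "within"))
      out[unique(lb$read[win])] <- "INTRONIC"
    }
  }
  out[unknown] <- "OTHER"
  out
}

#' @rdname classify_reads
#' @param read A single-row alignment `data.frame`.
#' @export
classify_read <- function(read, index, min_overhang = 6L,
                          extra_introns = NULL) {
  classify_reads(read, index, min_overhang, extra_introns)[1]
}

#' Tabulate exon-exon junction read counts
#'
#' Each splice gap (CIGAR N) whose flanking aligned blocks both span at least
#' `min_overhang` nt increments the corresponding junction once; a read with
#' two gaps increments two junctions. The result is independent of read
#' order.
#'
#' @param reads Alignment `data.frame` (with `sample_id` column).
#' @param min_overhang Minimum anchor on each side of the gap (default 6).
#' @return `data.frame` (`chrom`, `start`, `end`, `strand`, `sample_id`,
#'   `count`) with strand `*` (resolve with [resolve_junction_strand()]).
#' @export
extract_junction_counts <- function(reads, min_overhang = 6L) {
  gaps <- read_gaps(reads)
  gaps <- gaps[gaps$left_anchor >= min_overhang &
               gaps$right_anchor >= min_overhang, , drop = FALSE]
  if (nrow(gaps) == 0L) return(empty_junction_counts())
  key <- data.frame(
    chrom = reads$chrom[gaps$read],
    start = gaps$gap_start,
    end = gaps$gap_end,
    strand = "*",
    sample_id = reads$sample_id[gaps$read],
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(list(count = rep(1L, nrow(key))),
                          by = key, FUN = sum)
  agg <- agg[order(agg$chrom, agg$start, agg$end, agg$sample_id), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

empty_junction_counts <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), sample_id = character(), count = integer(),
             stringsAsFactors = FALSE)
}

#' Resolve unknown-strand junctions by gene overlap
#'
#' A strand-`*` junction is assigned the strand of the unique gene whose span
#' contains it; junctions matching zero or more than one gene keep `*` (they
#' are excluded from alternative-first-exon detection only).
#'
#' @param junctions Junction count table.
#' @param index An `annotation_index`.
#' @return The table with `strand` filled in where resolvable.
#' @export
resolve_junction_strand <- function(junctions, index) {
  if (nrow(junctions) == 0L) return(junctions)
  unk <- which(junctions$strand == "*")
  if (length(unk) == 0L) return(junctions)
  g <- genes_overlapping(index, junctions$chrom[unk], junctions$start[unk],
                         junctions$end[unk])
  uniq <- vapply(g, length, integer(1)) == 1L
  gene_strand <- setNames(index$genes$strand, index$genes$gene_id)
  junctions$strand[unk[uniq]] <-
    unname(gene_strand[unlist(g[uniq], use.names = FALSE)])
  junctions
}

#' Collect intron-retention evidence per intron and sample
#'
#' Boundary counts come from Group 2 (exon-intron) reads bridging the intron's
#' 5' or 3' border; the intronic read count from Group 3 reads fully inside;
#' depth and covered fraction are computed over intronic bases only, from
#' Group 3 reads plus the intron-side segments of boundary reads.
#'
#' @param reads Alignment `data.frame`.
#' @param index An `annotation_index`.
#' @param min_overhang Border/gap anchor (default 6).
#' @param extra_introns Optional novel intron intervals to include
#'   (`chrom`, `start`, `end`).
#' @return `data.frame`: `chrom`, `start`, `end`, `sample_id`,
#'   `left_count`, `right_count`, `intronic_count`, `mean_depth`,
#'   `covered_fraction` — one row per (intron, sample) pair with samples taken
#'   from `reads`.
#' @export
collect_intron_evidence <- function(reads, index, min_overhang = 6L,
                                    extra_introns = NULL) {
  it <- intron_table(index, extra_introns)
  samples <- sort(unique(reads$sample_id))
  if (length(samples) == 0L) samples <- character(0)
  grid <- expand.grid(intron = seq_len(nrow(it)), sample_id = samples,
                      stringsAsFactors = FALSE)
  out <- data.frame(
    chrom = it$chrom[grid$intron],
    start = it$start[grid$intron],
    end = it$end[grid$intron],
    sample_id = grid$sample_id,
    left_count = 0L, right_count = 0L, intronic_count = 0L,
    mean_depth = 0, covered_fraction = 0,
    stringsAsFactors = FALSE
  )
  if (nrow(reads) == 0L || nrow(it) == 0L) return(out)

  grp <- classify_reads(reads, index, min_overhang, extra_introns)
  blocks <- read_blocks(reads)
  key <- function(i, s) paste(i, s, sep = "\r")
  rowk <- key(grid$intron, grid$sample_id)

  igr <- GenomicRanges::GRanges(it$chrom,
                                IRanges::IRanges(it$start + 1L, it$end))

  # Group 2: border bridging (>= min_overhang each side of the border)
  bi <- which(grp == "EXON_INTRON")
  bb <- blocks[blocks$read %in% bi, , drop = FALSE]
  bseg <- NULL
  if (nrow(bb) > 0L) {
    for (side in c("left", "right")) {
      p <- if (side == "left") it$start else it$end
      pgr <- GenomicRanges::GRanges(it$chrom, IRanges::IRanges(p, width = 1L))
      ok <- (bb$end - bb$start) >= 2L * min_overhang
      qb <- bb[ok, , drop = FALSE]
      if (nrow(qb) == 0L) next
      qgr <- GenomicRanges::GRanges(
        reads$chrom[qb$read],
        IRanges::IRanges(qb$start + min_overhang + 1L,
                         qb$end - min_overhang))
      h <- GenomicRanges::findOverlaps(qgr, pgr)
      qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
      if (length(qh) > 0L) {
        kk <- key(sh, reads$sample_id[qb$read[qh]])
        tab <- table(kk)
        m <- match(names(tab), rowk)
        col <- paste0(side, "_count")
        out[[col]][m] <- out[[col]][m] + as.integer(tab)
        # intron-side segment for depth: clip block to intron
        bseg <- rbind(bseg, data.frame(
          intron = sh,
          sample_id = reads$sample_id[qb$read[qh]],
          start = pmax(qb$start[qh], it$start[sh]),
          end = pmin(qb$end[qh], it$end[sh])
        ))
      }
    }
  }

  # Group 3: fully intronic reads
  iseg <- NULL
  ii <- which(grp == "INTRONIC")
  ib <- blocks[blocks$read %in% ii, , drop = FALSE]
  if (nrow(ib) > 0L) {
    rgr <- GenomicRanges::GRanges(
      reads$chrom[ib$read], IRanges::IRanges(ib$start + 1L, ib$end))
    h <- GenomicRanges::findOverlaps(rgr, igr, type = "within")
    qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
    if (length(qh) > 0L) {
      kk <- key(sh, reads$sample_id[ib$read[qh]])
      tab <- table(kk)
      m <- match(names(tab), rowk)
      out$intronic_count[m] <- out$intronic_count[m] + as.integer(tab)
      iseg <- data.frame(
        intron = sh,
        sample_id = reads$sample_id[ib$read[qh]],
        start = ib$start[qh],
        end = ib$end[qh]
      )
    }
  }

  seg <- rbind(bseg, iseg)
  if (!is.null(seg) && nrow(seg) > 0L) {
    seg <- seg[seg$end > seg$start, , drop = FALSE]
    sk <- key(seg$intron, seg$sample_id)
    for (k in unique(sk)) {
      s <- seg[sk == k, , drop = FALSE]
      intr <- s$intron[1]
      ilen <- it$end[intr] - it$start[intr]
      cov <- IRanges::coverage(
        IRanges::IRanges(s$start - it$start[intr] + 1L,
                         s$end - it$start[intr]),
        width = ilen)
      m <- match(k, rowk)
      out$mean_depth[m] <- sum(as.numeric(S4Vectors::runValue(cov)) *
                               S4Vectors::runLength(cov)) / ilen
      out$covered_fraction[m] <- sum(S4Vectors::runLength(cov)[
        S4Vectors::runValue(cov) > 0]) / ilen
    }
  }
  out <- out[order(out$chrom, out$start, out$end, out$sample_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a STAR SJ.out.tab splice-junction table
#'
#' Converts the 1-based inclusive intron coordinates of the STAR dialect to
#' the package's 0-based half-open convention; unique-mapping counts are used;
#' strand code 0 becomes `*` (resolvable via [resolve_junction_strand()]).
#'
#' @param path Path to an SJ.out.tab file.
#' @param sample_id Sample label.
#' @return Junction count table as in [extract_junction_counts()].
#' @export
read_sj_tab <- function(path, sample_id) {
  if (file.size(path) == 0L) return(empty_junction_counts())
  x <- read.table(path, sep = "", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 9L) {
    stop("SJ.out.tab parse error: expected 9 columns, got ", ncol(x))
  }
  strand <- c("*", "+", "-")[x[[4]] + 1L]
  out <- data.frame(
    chrom = as.character(x[[1]]),
    start = x[[2]] - 1L,
    end = x[[3]],
    strand = strand,
    sample_id = sample_id,
    count = x[[7]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
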