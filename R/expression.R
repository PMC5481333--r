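# Gene-level counting, CPM normalisation, fold-change calls and set overlaps.

#' Count reads per gene
#'
#' A read is assigned to a gene when any of its aligned blocks overlaps the
#' gene's exonic union; reads touching the exons of more than one gene are
#' dropped as ambiguous, and intronic-only reads are not counted.
#'
#' @param reads Alignment `data.frame`.
#' @param index An `annotation_index`.
#' @return `data.frame` (`gene_id`, `sample_id`, `count`) covering every
#'   (gene, sample) pair with samples taken from `reads`.
#' @export
count_gene_reads <- function(reads, index) {
  samples <- sort(unique(reads$sample_id))
  grid <- expand.grid(gene_id = index$genes$gene_id, sample_id = samples,
                      stringsAsFactors = FALSE)
  out <- data.frame(grid, count = 0L, stringsAsFactors = FALSE)
  if (nrow(reads) == 0L || nrow(index$exons) == 0L) return(out)
  ex <- index$exons
  egr <- GenomicRanges::GRanges(ex$chrom,
                                IRanges::IRanges(ex$start + 1L, ex$end))
  b <- read_blocks(reads)
  bgr <- GenomicRanges::GRanges(reads$chrom[b$read],
                                IRanges::IRanges(b$start + 1L, b$end))
  h <- GenomicRanges::findOverlaps(bgr, egr)
  gene_of_block <- ex$gene_id[S4Vectors::subjectHits(h)]
  read_of_block <- b$read[S4Vectors::queryHits(h)]
  if (length(read_of_block) == 0L) return(out)
  per_read <- tapply(gene_of_block, read_of_block,
                     function(g) unique(g), simplify = FALSE)
  ngenes <- lengths(per_read)
  keep <- ngenes == 1L
  if (!any(keep)) return(out)
  gid <- unlist(per_read[keep], use.names = FALSE)
  rid <- as.integer(names(per_read))[keep]
  tab <- table(paste(gid, reads$sample_id[rid], sep = "\r"))
  m <- match(names(tab), paste(out$gene_id, out$sample_id, sep = "\r"))
  out$count[m] <- as.integer(tab)
  out
}

#' CPM normalisation and fold change
#'
#' `value = (count + pseudocount) / total-assigned-reads * 1e6` per sample;
#' the fold change of a comparison is the ratio of treated to control values.
#'
#' @param counts Gene count table (`gene_id`, `sample_id`, `count`).
#' @param pseudocount Stabiliser added to each count (default 0.5).
#' @return The table with an added `cpm` column.
#' @export
normalize_cpm <- function(counts, pseudocount = 0.5) {
  totals <- tapply(counts$count, counts$sample_id, sum)
  if (any(totals == 0)) {
    stop("sample with zero assigned reads: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  counts$cpm <- (counts$count + pseudocount) /
    as.numeric(totals[counts$sample_id]) * 1e6
  counts
}

#' Fold-change differential-expression calls
#'
#' With a single library per condition only the fold gate is applied:
#' `up` when fold >= `fc_min`, `down` when fold <= 1/`fc_min` (both
#' boundaries inclusive), otherwise `unchanged`.
#'
#' @param counts Normalised gene count table (see [normalize_cpm()]).
#' @param control,treated Sample ids.
#' @param fc_min Fold-change gate (default 1.5).
#' @return `data.frame` (`gene_id`, `count_control`, `count_treated`,
#'   `cpm_control`, `cpm_treated`, `fold_change`, `call`).
#' @export
call_differential <- function(counts, control, treated, fc_min = 1.5) {
  if (is.null(counts$cpm)) counts <- normalize_cpm(counts)
  cc <- counts[counts$sample_id == control, , drop = FALSE]
  ct <- counts[counts$sample_id == treated, , drop = FALSE]
  m <- match(cc$gene_id, ct$gene_id)
  fc <- ct$cpm[m] / cc$cpm
  out <- data.frame(
    gene_id = cc$gene_id,
    count_control = cc$count, count_treated = ct$count[m],
    cpm_control = cc$cpm, cpm_treated = ct$cpm[m],
    fold_change = fc,
    call = ifelse(fc >= fc_min, "up",
                  ifelse(fc <= 1 / fc_min, "down", "unchanged")),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact Venn-cell partition of 2-4 named sets
#'
#' @param sets Named list of 2-4 character vectors (duplicates within a set
#'   are dropped with a warning).
#' @param denominator Optional denominator for fractions; defaults to the
#'   union size.
#' @return An `overlap_partition` data.frame: one row per non-empty-signature
#'   cell (`cell`, e.g. `"A&B"`), `count`, `fraction`.
#' @export
overlap_partition <- function(sets, denominator = NULL) {
  stopifnot(length(sets) >= 2L, length(sets) <= 4L, !is.null(names(sets)))
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning("duplicate identifiers deduplicated in set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL,
                                                               names(sets)))
  k <- length(sets)
  if (is.null(denominator)) denominator <- length(universe)
  cells <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(cells) <- names(sets)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sig <- unlist(cells[i, ])
    inside <- if (length(universe)) {
      rowSums(member[, sig, drop = FALSE] == TRUE) == sum(sig) &
        rowSums(member[, !sig, drop = FALSE]) == 0
    } else logical(0)
    data.frame(cell = paste(names(sets)[sig], collapse = "&"),
               count = sum(inside), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fraction <- if (denominator > 0) out$count / denominator else 0
  attr(out, "union_size") <- length(universe)
  attr(out, "denominator") <- denominator
  class(out) <- c("overlap_partition", "data.frame")
  out
}

#' Overlap between differential expression and differential splicing
#'
#' Partition of the up-regulated, down-regulated and spliced gene sets, with
#' fractions over the union of all three (the denominator behind ratios such
#' as 39/2518): genes with at least one significant splicing event that are
#' also >= fold-gate up or down.
#'
#' @param de_up,de_down Character vectors of up-/down-regulated gene ids.
#' @param spliced_genes Character vector of genes carrying >= 1 significant
#'   splicing event (events collapsed to genes).
#' @return An `overlap_partition` with an `up_and_spliced` /
#'   `down_and_spliced` summary in its attributes.
#' @export
expression_splicing_overlap <- function(de_up, de_down, spliced_genes) {
  part <- overlap_partition(list(up = de_up, down = de_down,
                                 spliced = spliced_genes))
  union_n <- attr(part, "union_size")
  up_spliced <- length(intersect(de_up, spliced_genes))
  down_spliced <- length(intersect(de_down, spliced_genes))
  attr(part, "up_and_spliced") <- up_spliced
  attr(part, "down_and_spliced") <- down_spliced
  attr(part, "up_and_spliced_fraction") <-
    if (union_n > 0) up_spliced / union_n else 0
  attr(part, "down_and_spliced_fraction") <-
    if (union_n > 0) down_spliced / union_n else 0
  part
}
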