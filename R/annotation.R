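#' @importFrom stats rbinom rlnorm rnorm rpois runif setNames fisher.test
#'   p.adjust cor complete.cases
#' @importFrom utils read.table write.table packageVersion head
NULL

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# GTF (1-based inclusive) is converted at the read/write boundary only.

#' Read gene models from a GTF file
#'
#' Parses exon records of an Ensembl-style GTF into a flat exon table with
#' 0-based half-open coordinates, grouped by transcript and gene, and
#' validated (exons of one transcript must be non-overlapping and share
#' chromosome and strand).
#'
#' @param path Path to a GTF file (1-based inclusive coordinates, attributes
#'   containing `gene_id` and `transcript_id`).
#' @return A `gene_models` object: a `data.frame` with columns `gene_id`,
#'   `gene_name`, `transcript_id`, `chrom`, `strand`, `start`, `end`
#'   (one row per exon, 0-based half-open), ordered by chromosome, start and
#'   transcript id.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(body)[which(nfield < 9)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    return(empty_gene_models())
  }
  if (any(is.na(gr$transcript_id))) {
    stop("exon record lacking transcript_id in ", path)
  }
  gene_name <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  gene_name[is.na(gene_name)] <- gr$gene_id[is.na(gene_name)]
  ex <- data.frame(
    gene_id = gr$gene_id,
    gene_name = gene_name,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  gene_models(ex)
}

empty_gene_models <- function() {
  gene_models(data.frame(
    gene_id = character(), gene_name = character(),
    transcript_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), stringsAsFactors = FALSE
  ))
}

#' Construct and validate a gene-model exon table
#'
#' @param exons `data.frame` with one row per exon: `gene_id`, `gene_name`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end` (0-based half-open).
#' @return The validated, deterministically ordered `gene_models` object.
#' @export
gene_models <- function(exons) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end") %in% names(exons)))
  if (is.null(exons$gene_name)) exons$gene_name <- exons$gene_id
  exons$strand[!exons$strand %in% c("+", "-")] <- "*"
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  o <- order(exons$chrom, exons$start, exons$transcript_id, exons$end)
  exons <- exons[o, , drop = FALSE]
  rownames(exons) <- NULL
  # per-transcript validation
  for (tx in split(seq_len(nrow(exons)), exons$transcript_id)) {
    if (length(unique(exons$chrom[tx])) > 1L ||
        length(unique(exons$strand[tx])) > 1L) {
      stop("transcript ", exons$transcript_id[tx[1]],
           " spans multiple chromosomes or strands")
    }
    if (length(unique(exons$gene_id[tx])) > 1L) {
      stop("transcript ", exons$transcript_id[tx[1]],
           " assigned to multiple genes")
    }
    s <- exons$start[tx]; e <- exons$end[tx]
    if (length(tx) > 1L && any(s[-1] < e[-length(e)])) {
      stop("overlapping exons in transcript ", exons$transcript_id[tx[1]])
    }
  }
  structure(exons, class = c("gene_models", "data.frame"))
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()]: emits one `exon` line per row, converting the
#' internal 0-based half-open coordinates back to 1-based inclusive GTF.
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                   models$gene_id, models$transcript_id, models$gene_name)
  lines <- paste(models$chrom, "spliceIndex", "exon",
                 models$start + 1L, models$end, ".", models$strand, ".",
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# introns of one transcript = gaps between consecutive exons (exon table
# is sorted by start within transcript)
transcript_introns <- function(models) {
  idx <- split(seq_len(nrow(models)), models$transcript_id)
  out <- lapply(idx, function(i) {
    if (length(i) < 2L) return(NULL)
    i <- i[order(models$start[i])]
    data.frame(
      gene_id = models$gene_id[i[1]],
      transcript_id = models$transcript_id[i[1]],
      chrom = models$chrom[i[1]],
      strand = models$strand[i[1]],
      start = models$end[i[-length(i)]],
      end = models$start[i[-1]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# first exon of each transcript (5'-most respecting strand) and the donor
# junction leaving it, if any
first_exon_donors_tbl <- function(models) {
  idx <- split(seq_len(nrow(models)), models$transcript_id)
  rows <- lapply(idx, function(i) {
    if (length(i) < 2L) return(NULL)   # single-exon: no donor junction
    i <- i[order(models$start[i])]
    minus <- models$strand[i[1]] == "-"
    if (minus) {
      fe <- i[length(i)]                       # 5'-most = rightmost
      j_start <- models$end[i[length(i) - 1L]] # intron left of first exon
      j_end <- models$start[fe]
    } else {
      fe <- i[1]
      j_start <- models$end[fe]
      j_end <- models$start[i[2]]
    }
    data.frame(
      gene_id = models$gene_id[fe],
      chrom = models$chrom[fe],
      strand = models$strand[fe],
      first_exon_start = models$start[fe],
      first_exon_end = models$end[fe],
      donor_start = j_start,
      donor_end = j_end,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), first_exon_start = integer(),
                      first_exon_end = integer(), donor_start = integer(),
                      donor_end = integer(), stringsAsFactors = FALSE)
  }
  out <- unique(out)
  out <- out[order(out$gene_id, out$first_exon_start, out$donor_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the annotation index used for event detection and novelty labelling
#'
#' Derives, from validated gene models, the set of known splice junctions
#' (one per distinct consecutive-exon gap over all transcripts), the
#' first-exon donor junctions per gene, gene spans, and an interval index
#' from genomic position to gene.
#'
#' @param models A `gene_models` object (see [read_gtf()]).
#' @return An `annotation_index` list with elements `junctions`,
#'   `first_exon_donors`, `genes`, `exons`, `models` and the GRanges
#'   `gene_ranges` used for interval queries. Known introns equal known
#'   junctions as interval sets.
#' @export
build_annotation_index <- function(models) {
  introns <- transcript_introns(models)
  junctions <- unique(introns[, c("chrom", "start", "end", "strand",
                                  "gene_id")])
  junctions <- junctions[order(junctions$chrom, junctions$start,
                               junctions$end, junctions$gene_id), ,
                         drop = FALSE]
  rownames(junctions) <- NULL

  if (nrow(models) > 0L) {
    gs <- split(seq_len(nrow(models)), models$gene_id)
    genes <- do.call(rbind, lapply(gs, function(i) data.frame(
      gene_id = models$gene_id[i[1]],
      chrom = models$chrom[i[1]],
      strand = models$strand[i[1]],
      start = min(models$start[i]),
      end = max(models$end[i]),
      stringsAsFactors = FALSE
    )))
    genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  }
  gene_ranges <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  names(gene_ranges) <- genes$gene_id

  structure(list(
    junctions = junctions,
    first_exon_donors = first_exon_donors_tbl(models),
    genes = genes,
    gene_ranges = gene_ranges,
    exons = models,
    introns = introns
  ), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", nrow(x$genes), "genes,",
      nrow(x$junctions), "known junctions,",
      nrow(x$first_exon_donors), "first-exon donors\n")
  invisible(x)
}

junction_id <- function(chrom, start, end) {
  if (length(chrom) == 0L) return(character(0))
  paste0(chrom, ":", start, "-", end)
}

# membership of (chrom,start,end) intervals in the known-junction set
is_known_junction <- function(index, chrom, start, end) {
  junction_id(chrom, start, end) %in%
    junction_id(index$junctions$chrom, index$junctions$start,
                index$junctions$end)
}

# a retained intron is annotated iff some transcript has an exon spanning
# the whole intron
is_annotated_retention <- function(index, chrom, start, end) {
  ex <- index$exons
  vapply(seq_along(chrom), function(i) {
    any(ex$chrom == chrom[i] & ex$start <= start[i] & ex$end >= end[i])
  }, logical(1))
}

# map intervals to overlapping gene ids; returns list of character vectors
genes_overlapping <- function(index, chrom, start, end, strand = NULL) {
  if (length(chrom) == 0L) return(list())
  q <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = pmax(end, start + 1L)),
    strand = if (is.null(strand)) "*" else strand
  )
  hits <- GenomicRanges::findOverlaps(q, index$gene_ranges)
  out <- vector("list", length(chrom))
  for (i in seq_along(out)) out[[i]] <- character()
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    out[[qh[k]]] <- c(out[[qh[k]]], names(index$gene_ranges)[sh[k]])
  }
  lapply(out, unique)
}

#' Dump the junction index as a TSV
#'
#' One row per known junction: chrom, intron_start, intron_end, strand,
#' gene_id, known flag (always TRUE for the annotation index itself).
#'
#' @param index An `annotation_index`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_junction_index <- function(index, path) {
  j <- index$junctions
  j$known <- TRUE
  write_tsv(j[, c("chrom", "start", "end", "strand", "gene_id", "known")],
            path)
}
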