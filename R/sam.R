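# Alignment ingestion and CIGAR arithmetic.
#
# Alignments are held as a plain data.frame (read_id, chrom, pos, cigar,
# mapq, sample_id) with pos 0-based. Reference-aligned blocks are derived
# from the CIGAR: M and D consume reference within a block, N splits blocks
# (a splice gap), I and S consume nothing on the reference.

#' Read aligned reads from a SAM or BAM file
#'
#' Loads mapped reads via Rsamtools (SAM files are converted to BAM in a
#' temporary location first). Multi-position details beyond what junction and
#' coverage counting need are dropped.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param sample_id Sample label attached to every read.
#' @param min_mapq Minimum mapping quality; reads strictly below are dropped
#'   (default 1, i.e. uniquely mapping reads under the common convention that
#'   multimappers get MAPQ 0).
#' @return `data.frame` with columns `read_id`, `chrom`, `pos` (0-based
#'   leftmost aligned base), `cigar`, `mapq`, `sample_id`.
#' @export
read_alignments <- function(path, sample_id, min_mapq = 1L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "mapq", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- is.na(x$mapq) | x$mapq >= min_mapq
  data.frame(
    read_id = x$qname[keep],
    chrom = as.character(x$rname)[keep],
    pos = x$pos[keep] - 1L,
    cigar = x$cigar[keep],
    mapq = x$mapq[keep],
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

# Parse CIGAR strings into op/length vectors. Returns a list (one entry per
# unique input) of list(op=character, len=integer); computed once per unique
# CIGAR for speed.
parse_cigar <- function(cigars) {
  u <- unique(cigars)
  m <- gregexpr("[0-9]+[MIDNSHP=X]", u)
  parsed <- lapply(regmatches(u, m), function(tok) {
    len <- as.integer(sub("[A-Z=]$", "", tok))
    op <- sub("^[0-9]+", "", tok)
    list(op = op, len = len)
  })
  names(parsed) <- u
  parsed[cigars]
}

# For one parsed CIGAR: reference-aligned blocks RELATIVE to pos, as a matrix
# with columns start, end (0-based half-open offsets) -- one row per block
# between N gaps. M/D/=/X consume reference within a block; N ends a block.
cigar_rel_blocks <- function(pc) {
  op <- pc$op; len <- pc$len
  consumes <- op %in% c("M", "D", "=", "X")
  starts <- integer(0); ends <- integer(0)
  cur_start <- 0L; cur <- 0L; open <- FALSE
  for (i in seq_along(op)) {
    if (op[i] == "N") {
      if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
      cur <- cur + len[i]
      cur_start <- cur
      open <- FALSE
    } else if (consumes[i]) {
      if (!open) { cur_start <- cur; open <- TRUE }
      cur <- cur + len[i]
    }
    # I, S, H, P: no reference consumption, block continuity preserved
  }
  if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
  cbind(start = starts, end = ends)
}

# Per-read reference blocks (absolute coordinates). Returns a data.frame
# with one row per block: read index, block start/end, block ordinal,
# n_blocks for the read.
read_blocks <- function(reads) {
  pcs <- parse_cigar(reads$cigar)
  rel <- lapply(pcs, cigar_rel_blocks)
  # memoise by cigar string
  nb <- vapply(rel, nrow, integer(1))
  ri <- rep.int(seq_len(nrow(reads)), nb)
  relm <- do.call(rbind, rel)
  data.frame(
    read = ri,
    start = reads$pos[ri] + relm[, "start"],
    end = reads$pos[ri] + relm[, "end"],
    ordinal = sequence(nb),
    n_blocks = nb[ri]
  )
}

# Splice gaps per read with their flanking aligned-block lengths.
# One row per N gap: read index, gap start/end (absolute), left/right anchor.
read_gaps <- function(reads) {
  b <- read_blocks(reads)
  multi <- b$n_blocks > 1L
  b <- b[multi, , drop = FALSE]
  if (nrow(b) == 0L) {
    return(data.frame(read = integer(), gap_start = integer(),
                      gap_end = integer(), left_anchor = integer(),
                      right_anchor = integer()))
  }
  left <- b[b$ordinal < b$n_blocks, , drop = FALSE]
  right <- b[b$ordinal > 1L, , drop = FALSE]
  data.frame(
    read = left$read,
    gap_start = left$end,
    gap_end = right$start,
    left_anchor = left$end - left$start,
    right_anchor = right$end - right$start
  )
}
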