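# Hand-built fixtures and independent oracles shared across the suite.

# Toy annotation (0-based half-open):
#   gene A (+, chr1): A.1 exons [100,200) [300,400) [500,600)
#                     A.2 exons [100,200) [500,600)   (cassette exon skipped)
#   gene B (+, chr2): B.1 exons [1000,1100) [1300,1400)
#                     B.2 exons [1150,1250) [1300,1400)  (alternative first exon)
#   gene C (-, chr3): C.1 exons [10000,10100) [10200,10300)
toy_models <- function() {
  gene_models(data.frame(
    gene_id = c(rep("A", 5), rep("B", 4), rep("C", 2)),
    gene_name = c(rep("A", 5), rep("B", 4), rep("C", 2)),
    transcript_id = c("A.1", "A.1", "A.1", "A.2", "A.2",
                      "B.1", "B.1", "B.2", "B.2", "C.1", "C.1"),
    chrom = c(rep("chr1", 5), rep("chr2", 4), rep("chr3", 2)),
    strand = c(rep("+", 9), rep("-", 2)),
    start = c(100, 300, 500, 100, 500, 1000, 1300, 1150, 1300, 10000, 10200),
    end = c(200, 400, 600, 200, 600, 1100, 1400, 1250, 1400, 10100, 10300),
    stringsAsFactors = FALSE
  ))
}

toy_index <- function() build_annotation_index(toy_models())

# single-isoform annotation: no alternative structure of its own
plain_index <- function() {
  m <- toy_models()
  build_annotation_index(gene_models(m[m$transcript_id %in%
                                         c("A.1", "C.1"), ]))
}

mk_reads <- function(chrom, pos, cigar, sample_id = "s1",
                     read_id = NULL, mapq = 60L) {
  n <- max(length(chrom), length(pos), length(cigar))
  data.frame(
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    cigar = rep_len(cigar, n), mapq = rep_len(mapq, n),
    sample_id = rep_len(sample_id, n),
    stringsAsFactors = FALSE
  )
}

mk_junctions <- function(chrom, start, end, strand = "+", sample_id = "s1",
                         count = 1L) {
  n <- max(length(chrom), length(start), length(end), length(count),
           length(sample_id))
  data.frame(chrom = rep_len(chrom, n), start = rep_len(start, n),
             end = rep_len(end, n), strand = rep_len(strand, n),
             sample_id = rep_len(sample_id, n),
             count = rep_len(as.integer(count), n), stringsAsFactors = FALSE)
}

empty_evidence <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             sample_id = character(), left_count = integer(),
             right_count = integer(), intronic_count = integer(),
             mean_depth = numeric(), covered_fraction = numeric(),
             stringsAsFactors = FALSE)
}

mk_evidence <- function(chrom, start, end, sample_id, left = 0L, right = 0L,
                        intronic = 0L, mean_depth = 0, covered = 0) {
  n <- max(length(chrom), length(start), length(end), length(sample_id),
           length(left), length(right))
  data.frame(chrom = rep_len(chrom, n), start = rep_len(start, n),
             end = rep_len(end, n), sample_id = rep_len(sample_id, n),
             left_count = rep_len(as.integer(left), n),
             right_count = rep_len(as.integer(right), n),
             intronic_count = rep_len(as.integer(intronic), n),
             mean_depth = rep_len(mean_depth, n),
             covered_fraction = rep_len(covered, n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ground-truth ids found among detected ids, allowing the variant/canonical
# orientation of alternative splice sites to be swapped
truth_ids_found <- function(truth, ids) {
  found <- truth$event_id %in% ids
  swap <- !found & truth$type %in% c("ALT_5SS", "ALT_3SS")
  if (any(swap)) {
    tmp <- truth[swap, ]
    tmp[, c("v_start", "v_end", "c1_start", "c1_end")] <-
      tmp[, c("c1_start", "c1_end", "v_start", "v_end")]
    found[swap] <- spliceIndex:::make_event_ids(tmp) %in% ids
  }
  found
}

# Independent oracle: two-sided Fisher exact p by exhaustive hypergeometric
# point-probability summation (conventional floating-point tie guard).
oracle_fisher <- function(at, bt, ac, bc) {
  m <- at + ac; n0 <- bt + bc; k <- at + bt
  if (m == 0 || n0 == 0 || k == 0 || k == m + n0) return(1)
  xs <- max(0, k - n0):min(k, m)
  probs <- stats::dhyper(xs, m, n0, k)
  p0 <- stats::dhyper(at, m, n0, k)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

# Independent oracle: naive quadratic Benjamini-Hochberg definition,
# q at sorted rank j = min over l >= j of m * p_(l) / l, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (j in seq_len(m)) qs[j] <- min(1, min(m * ps[j:m] / (j:m)))
  out <- numeric(m)
  out[o] <- qs
  out
}
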