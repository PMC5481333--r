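# Candidate-event enumeration for the five splicing classes.
#
# An event table has one row per candidate with typed coordinate slots:
#   v_start/v_end      variant-form key (IR: the intron; ES: the skip
#                      junction; A5SS/A3SS: the variant junction; AFE: this
#                      first-exon donor junction)
#   c1_*, c2_*         canonical-form keys (IR: the spliced junction == the
#                      intron interval; ES: upstream and downstream
#                      junctions; A5SS/A3SS: the canonical junction)
#   other              AFE only: semicolon-joined other donor junctions
# event_id is a deterministic function of type and coordinates.

event_types <- c("INTRON_RETENTION", "EXON_SKIPPING", "ALT_FIRST_EXON",
                 "ALT_5SS", "ALT_3SS")

empty_events <- function() {
  data.frame(event_id = character(), type = character(), gene_id = character(),
             chrom = character(), strand = character(),
             v_start = integer(), v_end = integer(),
             c1_start = integer(), c1_end = integer(),
             c2_start = integer(), c2_end = integer(),
             other = character(), ambiguous = logical(), novel = logical(),
             stringsAsFactors = FALSE)
}

make_event_ids <- function(ev) {
  ifelse(ev$type == "EXON_SKIPPING",
         paste0("ES@", ev$chrom, ":", ev$v_start, "-", ev$v_end,
                "[", ev$c1_end, "-", ev$c2_start, "]"),
  ifelse(ev$type == "INTRON_RETENTION",
         paste0("IR@", ev$chrom, ":", ev$v_start, "-", ev$v_end),
  ifelse(ev$type == "ALT_5SS",
         paste0("A5SS@", ev$chrom, ":", ev$v_start, "-", ev$v_end,
                "|", ev$c1_start, "-", ev$c1_end),
  ifelse(ev$type == "ALT_3SS",
         paste0("A3SS@", ev$chrom, ":", ev$v_start, "-", ev$v_end,
                "|", ev$c1_start, "-", ev$c1_end),
         paste0("AFE@", ev$chrom, ":", ev$gene_id, ":",
                ev$v_start, "-", ev$v_end)))))
}

# unique gene containing all event keys; NA + ambiguous flag otherwise
assign_event_gene <- function(index, chrom, start, end) {
  g <- genes_overlapping(index, chrom, start, end)
  n <- vapply(g, length, integer(1))
  gid <- rep(NA_character_, length(n))
  gid[n == 1L] <- unlist(g[n == 1L], use.names = FALSE)
  list(gene_id = gid, ambiguous = n > 1L)
}

finish_events <- function(ev, index) {
  if (nrow(ev) == 0L) return(empty_events())
  ev$event_id <- make_event_ids(ev)
  ev$novel <- label_novel(ev, index)
  ev <- ev[order(ev$type, ev$chrom, ev$v_start, ev$v_end, ev$event_id), ,
           drop = FALSE]
  ev <- ev[!duplicated(ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev[, names(empty_events())]
}

merged_junction_set <- function(junctions) {
  unique(junctions[junctions$count > 0, c("chrom", "start", "end", "strand"),
                   drop = FALSE])
}

#' Detect intron-retention candidates
#'
#' One candidate per intron (annotated introns plus any interval present in
#' the evidence table) that has spliced-junction reads or boundary reads in
#' at least one sample. The variant form is retention (evidenced by the two
#' exon-intron boundaries), the canonical form the spliced junction.
#'
#' @param junctions Junction count table.
#' @param evidence Intron evidence table from [collect_intron_evidence()].
#' @param index An `annotation_index`.
#' @return Event `data.frame` (see package overview).
#' @export
detect_intron_retention <- function(junctions, evidence, index) {
  introns <- unique(evidence[, c("chrom", "start", "end")])
  if (nrow(introns) == 0L) return(empty_events())
  jid <- junction_id(junctions$chrom[junctions$count > 0],
                     junctions$start[junctions$count > 0],
                     junctions$end[junctions$count > 0])
  bnd <- evidence$left_count + evidence$right_count > 0
  bid <- unique(junction_id(evidence$chrom[bnd], evidence$start[bnd],
                            evidence$end[bnd]))
  iid <- junction_id(introns$chrom, introns$start, introns$end)
  keep <- iid %in% jid | iid %in% bid
  introns <- introns[keep, , drop = FALSE]
  if (nrow(introns) == 0L) return(empty_events())
  ga <- assign_event_gene(index, introns$chrom, introns$start, introns$end)
  strand <- setNames(index$genes$strand, index$genes$gene_id)[ga$gene_id]
  strand[is.na(strand)] <- "*"
  ev <- data.frame(
    event_id = "", type = "INTRON_RETENTION", gene_id = ga$gene_id,
    chrom = introns$chrom, strand = unname(strand),
    v_start = introns$start, v_end = introns$end,
    c1_start = introns$start, c1_end = introns$end,
    c2_start = NA_integer_, c2_end = NA_integer_,
    other = "", ambiguous = ga$ambiguous, novel = NA,
    stringsAsFactors = FALSE
  )
  finish_events(ev, index)
}

#' Detect exon-skipping candidates
#'
#' Enumerates junction triples (upstream `u`, downstream `d`, skip `s`) with
#' `s` spanning exactly from `u`'s donor to `d`'s acceptor and a middle
#' (cassette) exon between them; all three junctions must be observed or
#' annotated. The variant form is the skip junction, the canonical form the
#' two inclusion junctions.
#'
#' @param junctions Junction count table (merged across samples).
#' @param index An `annotation_index`.
#' @param max_middle_exon Maximum cassette-exon length in nt (default 10000);
#'   guards against chimera-like triples.
#' @return Event `data.frame`.
#' @export
detect_exon_skipping <- function(junctions, index, max_middle_exon = 10000L) {
  J <- unique(rbind(
    merged_junction_set(junctions)[, c("chrom", "start", "end")],
    index$junctions[, c("chrom", "start", "end")]
  ))
  if (nrow(J) < 3L) return(empty_events())
  ks <- paste(J$chrom, J$start)
  ke <- paste(J$chrom, J$end)
  gs <- split(seq_len(nrow(J)), ks)
  gd <- split(seq_len(nrow(J)), ke)
  cand <- which(lengths(gs)[ks] >= 2L & lengths(gd)[ke] >= 2L)
  rows <- vector("list", 0L)
  for (k in cand) {
    us <- gs[[ks[k]]]
    us <- us[J$end[us] < J$end[k]]
    ds <- gd[[ke[k]]]
    ds <- ds[J$start[ds] > J$start[k]]
    if (length(us) == 0L || length(ds) == 0L) next
    for (i in us) {
      dd <- ds[J$start[ds] > J$end[i] &
               J$start[ds] - J$end[i] <= max_middle_exon]
      if (length(dd) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = J$chrom[k], v_start = J$start[k], v_end = J$end[k],
        c1_start = J$start[i], c1_end = J$end[i],
        c2_start = J$start[dd], c2_end = J$end[dd],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_events())
  r <- do.call(rbind, rows)
  ga <- assign_event_gene(index, r$chrom, r$v_start, r$v_end)
  strand <- setNames(index$genes$strand, index$genes$gene_id)[ga$gene_id]
  strand[is.na(strand)] <- "*"
  ev <- data.frame(
    event_id = "", type = "EXON_SKIPPING", gene_id = ga$gene_id,
    chrom = r$chrom, strand = unname(strand),
    v_start = r$v_start, v_end = r$v_end,
    c1_start = r$c1_start, c1_end = r$c1_end,
    c2_start = r$c2_start, c2_end = r$c2_end,
    other = "", ambiguous = ga$ambiguous, novel = NA,
    stringsAsFactors = FALSE
  )
  finish_events(ev, index)
}

#' Detect alternative 5' / 3' splice-site candidates
#'
#' Junctions sharing an acceptor but differing in donor (5' side) or sharing
#' a donor but differing in acceptor (3' side), strand-aware. The canonical
#' junction is the annotated one; if both or neither junction of a pair is
#' annotated, the one with the higher control-sample count wins, ties going
#' to the longer intron. With three or more competitors, each non-canonical
#' junction is paired against the canonical.
#'
#' @param junctions Junction count table with resolved strands.
#' @param index An `annotation_index`.
#' @param side `"5SS"` or `"3SS"`.
#' @param control Optional control sample id whose counts break canonical
#'   ties (defaults to summing all samples).
#' @return Event `data.frame`. Strandless junction groups are skipped.
#' @export
detect_alt_ss <- function(junctions, index, side = c("5SS", "3SS"),
                          control = NULL) {
  side <- match.arg(side)
  obs <- merged_junction_set(junctions)
  ann <- index$junctions[, c("chrom", "start", "end", "strand")]
  J <- unique(rbind(obs, ann))
  J <- J[J$strand %in% c("+", "-"), , drop = FALSE]
  if (nrow(J) < 2L) return(empty_events())

  cc <- junctions
  if (!is.null(control)) cc <- cc[cc$sample_id == control, , drop = FALSE]
  ckey <- junction_id(cc$chrom, cc$start, cc$end)
  csum <- tapply(cc$count, ckey, sum)
  jcount <- as.numeric(csum[junction_id(J$chrom, J$start, J$end)])
  jcount[is.na(jcount)] <- 0
  annotated <- is_known_junction(index, J$chrom, J$start, J$end)

  # shared end: donor = intron 5' end (start on +, end on -);
  # acceptor = intron 3' end (end on +, start on -)
  share_acceptor <- side == "5SS"
  shared <- ifelse((J$strand == "+") == share_acceptor, J$end, J$start)
  grp <- paste(J$chrom, J$strand, shared)
  rows <- vector("list", 0L)
  for (g in unique(grp[duplicated(grp)])) {
    i <- which(grp == g)
    if (length(unique(junction_id(J$chrom[i], J$start[i], J$end[i]))) < 2L)
      next
    # canonical preference: annotated, then control count, then intron length
    o <- order(-annotated[i], -jcount[i], -(J$end[i] - J$start[i]))
    can <- i[o[1]]
    for (v in setdiff(i, can)) {
      if (share_acceptor &&
          is_afe_pair(index, J$chrom[v], J$strand[v],
                      c(J$start[v], J$end[v]), c(J$start[can], J$end[can])))
        next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = J$chrom[v], strand = J$strand[v],
        v_start = J$start[v], v_end = J$end[v],
        c1_start = J$start[can], c1_end = J$end[can],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_events())
  r <- do.call(rbind, rows)
  ga <- assign_event_gene(index, r$chrom,
                          pmin(r$v_start, r$c1_start),
                          pmax(r$v_end, r$c1_end))
  ev <- data.frame(
    event_id = "", type = if (side == "5SS") "ALT_5SS" else "ALT_3SS",
    gene_id = ga$gene_id, chrom = r$chrom, strand = r$strand,
    v_start = r$v_start, v_end = r$v_end,
    c1_start = r$c1_start, c1_end = r$c1_end,
    c2_start = NA_integer_, c2_end = NA_integer_,
    other = "", ambiguous = ga$ambiguous, novel = NA,
    stringsAsFactors = FALSE
  )
  finish_events(ev, index)
}

# Competing first-exon donor junctions masquerade as alternative-5'-site
# pairs (they share the acceptor). A donor-sharing pair is treated as AFE --
# and skipped by detect_alt_ss -- when both junctions are annotated
# first-exon donors of one gene, or when one is and the other's donor end
# lies outside every annotated exon of that gene (a novel first exon).
is_afe_pair <- function(index, chrom, strand, v, can) {
  fed <- index$first_exon_donors
  if (nrow(fed) == 0L) return(FALSE)
  did <- junction_id(fed$chrom, fed$donor_start, fed$donor_end)
  vin <- match(junction_id(chrom, v[1], v[2]), did)
  cin <- match(junction_id(chrom, can[1], can[2]), did)
  if (!is.na(vin) && !is.na(cin)) {
    return(fed$gene_id[vin] == fed$gene_id[cin])
  }
  one <- if (!is.na(vin)) vin else if (!is.na(cin)) cin else return(FALSE)
  other <- if (!is.na(vin)) can else v
  g <- fed$gene_id[one]
  ex <- index$exons[index$exons$gene_id == g, , drop = FALSE]
  donor_probe <- if (strand == "+") other[1] - 1L else other[2]
  !any(ex$start <= donor_probe & donor_probe < ex$end)
}

# annotated acceptor coordinates per gene: the acceptor end of each known
# junction (end on +, start on -)
gene_acceptors <- function(index, gene_id) {
  j <- index$junctions[index$junctions$gene_id == gene_id, , drop = FALSE]
  if (nrow(j) == 0L) return(integer(0))
  ifelse(j$strand == "+", j$end, j$start)
}

#' Detect alternative-first-exon candidates
#'
#' Per gene, competing first-exon donor junctions come from the annotation
#' (one donor per distinct annotated first exon) plus observed novel donors:
#' junctions whose acceptor matches an annotated acceptor of the gene while
#' the donor end lies outside every annotated exon of the gene. Genes with at
#' least two distinct donors yield one event per donor; the canonical form is
#' the set of all other donors.
#'
#' @param junctions Junction count table with resolved strands.
#' @param index An `annotation_index`.
#' @return Event `data.frame`.
#' @export
detect_alt_first_exon <- function(junctions, index) {
  fed <- index$first_exon_donors
  obs <- merged_junction_set(junctions)
  rows <- vector("list", 0L)
  for (g in unique(index$genes$gene_id)) {
    gene <- index$genes[index$genes$gene_id == g, ]
    donors <- unique(fed[fed$gene_id == g,
                         c("chrom", "donor_start", "donor_end", "strand")])
    names(donors) <- c("chrom", "start", "end", "strand")
    # novel first-exon donors among observed junctions of this gene
    cand <- obs[obs$chrom == gene$chrom & obs$strand == gene$strand &
                obs$start >= gene$start - 100000L &
                obs$end <= gene$end + 100000L, , drop = FALSE]
    if (nrow(cand) > 0L) {
      acc <- gene_acceptors(index, g)
      cand_acc <- ifelse(cand$strand == "+", cand$end, cand$start)
      cand_don <- ifelse(cand$strand == "+", cand$start, cand$end)
      ex <- index$exons[index$exons$gene_id == g, , drop = FALSE]
      # donor end outside all annotated exons (position just inside the
      # putative novel first exon, i.e. the base left/right of the junction)
      probe <- ifelse(cand$strand == "+", cand_don - 1L, cand_don)
      inside <- vapply(probe, function(p)
        any(ex$start <= p & p < ex$end), logical(1))
      novel_d <- cand[cand_acc %in% acc & !inside, , drop = FALSE]
      if (nrow(novel_d) > 0L) {
        donors <- unique(rbind(donors, novel_d))
      }
    }
    if (nrow(donors) < 2L) next
    for (i in seq_len(nrow(donors))) {
      others <- donors[-i, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, chrom = donors$chrom[i], strand = donors$strand[i],
        v_start = donors$start[i], v_end = donors$end[i],
        other = paste(paste0(others$start, "-", others$end), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_events())
  r <- do.call(rbind, rows)
  ev <- data.frame(
    event_id = "", type = "ALT_FIRST_EXON", gene_id = r$gene_id,
    chrom = r$chrom, strand = r$strand,
    v_start = r$v_start, v_end = r$v_end,
    c1_start = NA_integer_, c1_end = NA_integer_,
    c2_start = NA_integer_, c2_end = NA_integer_,
    other = r$other, ambiguous = FALSE, novel = NA,
    stringsAsFactors = FALSE
  )
  finish_events(ev, index)
}

#' Label events as known or novel
#'
#' An event is novel iff any key of its variant or canonical form is absent
#' from the annotation's known junctions. Intron retention is special-cased:
#' retention is "known" only if some annotated transcript contains an exon
#' spanning the whole intron (an annotated retained intron); otherwise the
#' event is novel even when the spliced junction itself is annotated.
#'
#' @param events Event `data.frame`.
#' @param index An `annotation_index`.
#' @return Logical vector.
#' @export
label_novel <- function(events, index) {
  if (nrow(events) == 0L) return(logical(0))
  out <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$type == "INTRON_RETENTION") {
      out[i] <- !(is_known_junction(index, e$chrom, e$v_start, e$v_end) &&
                  is_annotated_retention(index, e$chrom, e$v_start, e$v_end))
    } else {
      keys <- rbind(
        c(e$v_start, e$v_end),
        if (!is.na(e$c1_start)) c(e$c1_start, e$c1_end),
        if (!is.na(e$c2_start)) c(e$c2_start, e$c2_end)
      )
      if (nzchar(e$other)) {
        oth <- strsplit(e$other, ";", fixed = TRUE)[[1]]
        om <- do.call(rbind, lapply(strsplit(oth, "-", fixed = TRUE),
                                    as.integer))
        keys <- rbind(keys, om)
      }
      out[i] <- !all(is_known_junction(index, rep(e$chrom, nrow(keys)),
                                       keys[, 1], keys[, 2]))
    }
  }
  out
}

#' Detect all candidate events of the five classes
#'
#' @param junctions Junction count table (strands resolved where possible).
#' @param evidence Intron evidence table.
#' @param index An `annotation_index`.
#' @param control Optional control sample id (canonical tie-break for
#'   alternative splice sites).
#' @param max_middle_exon Cassette-exon length guard for skipping detection.
#' @return Combined event `data.frame`, deterministic order.
#' @export
detect_events <- function(junctions, evidence, index, control = NULL,
                          max_middle_exon = 10000L) {
  ev <- rbind(
    detect_intron_retention(junctions, evidence, index),
    detect_exon_skipping(junctions, index, max_middle_exon),
    detect_alt_ss(junctions, index, "5SS", control),
    detect_alt_ss(junctions, index, "3SS", control),
    detect_alt_first_exon(junctions, index)
  )
  ev <- ev[order(ev$type, ev$chrom, ev$v_start, ev$v_end, ev$event_id), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}
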