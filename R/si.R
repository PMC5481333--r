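# Splicing index, delta-SI and significance calling.
#
# For each event the informative evidence is reduced to a variant-support
# count a and a canonical-support count b, type by type:
#   intron retention   a = round(mean(left boundary, right boundary))
#                      b = spliced-junction count
#   exon skipping      a = skip-junction count
#                      b = round(mean(upstream, downstream junction counts))
#   alt 5'/3' site     a = variant-junction count, b = canonical-junction count
#   alt first exon     a = this donor's count, b = sum of the gene's other
#                      first-exon donor counts
# Rounding is half away from zero so Fisher's exact test sees integers.
# SI = a/(a+b) when a+b reaches min_support, undefined otherwise.

junction_count_lookup <- function(junctions, sample_id) {
  j <- junctions[junctions$sample_id == sample_id, , drop = FALSE]
  if (nrow(j) == 0L) return(setNames(integer(0), character(0)))
  tapply(j$count, junction_id(j$chrom, j$start, j$end), sum)
}

lookup0 <- function(tbl, id) {
  v <- as.numeric(tbl[id])
  v[is.na(v)] <- 0
  v
}

#' Variant/canonical support counts for events in one sample
#'
#' @param events Event `data.frame` from [detect_events()].
#' @param junctions Junction count table.
#' @param evidence Intron evidence table.
#' @param sample_id Sample to extract.
#' @return `data.frame` with columns `event_id`, `a` (variant support) and
#'   `b` (canonical support), in the events' order.
#' @export
event_support <- function(events, junctions, evidence, sample_id) {
  n <- nrow(events)
  a <- numeric(n); b <- numeric(n)
  jc <- junction_count_lookup(junctions, sample_id)
  ev_s <- evidence[evidence$sample_id == sample_id, , drop = FALSE]
  eid <- junction_id(ev_s$chrom, ev_s$start, ev_s$end)
  left <- setNames(ev_s$left_count, eid)
  right <- setNames(ev_s$right_count, eid)

  vid <- junction_id(events$chrom, events$v_start, events$v_end)
  c1id <- junction_id(events$chrom, events$c1_start, events$c1_end)
  c2id <- junction_id(events$chrom, events$c2_start, events$c2_end)

  ir <- events$type == "INTRON_RETENTION"
  a[ir] <- round_half_away((lookup0(left, vid[ir]) +
                            lookup0(right, vid[ir])) / 2)
  b[ir] <- lookup0(jc, vid[ir])

  es <- events$type == "EXON_SKIPPING"
  a[es] <- lookup0(jc, vid[es])
  b[es] <- round_half_away((lookup0(jc, c1id[es]) + lookup0(jc, c2id[es])) / 2)

  ass <- events$type %in% c("ALT_5SS", "ALT_3SS")
  a[ass] <- lookup0(jc, vid[ass])
  b[ass] <- lookup0(jc, c1id[ass])

  afe <- events$type == "ALT_FIRST_EXON"
  if (any(afe)) {
    for (i in which(afe)) {
      a[i] <- lookup0(jc, vid[i])
      oth <- strsplit(events$other[i], ";", fixed = TRUE)[[1]]
      oid <- paste0(events$chrom[i], ":", oth)   # "chrom:start-end" keys
      b[i] <- sum(lookup0(jc, oid))
    }
  }
  data.frame(event_id = events$event_id, a = as.integer(a), b = as.integer(b),
             stringsAsFactors = FALSE)
}

#' Splicing index
#'
#' `SI = a / (a + b)`, the fraction of informative reads supporting the
#' variant form; `NA` (undefined) when the informative total falls short of
#' `min_support`.
#'
#' @param a Variant support counts.
#' @param b Canonical support counts.
#' @param min_support Minimum informative reads `a + b` (default 10).
#' @return Numeric vector in `[0, 1]`, `NA` where undefined.
#' @export
compute_si <- function(a, b, min_support = 10L) {
  ifelse(a + b >= min_support, a / (a + b), NA_real_)
}

#' Difference in splicing index
#'
#' @param si_treated,si_control Per-condition SI values.
#' @return `si_treated - si_control`; `NA` when either side is undefined.
#' @export
compute_delta_si <- function(si_treated, si_control) {
  si_treated - si_control
}

#' Two-sided Fisher exact p-value for one event
#'
#' Tests the 2x2 table `[[a_t, b_t], [a_c, b_c]]` of variant vs canonical
#' support in treated vs control. A zero row or column margin gives p = 1.
#'
#' @param a_treated,b_treated,a_control,b_control Non-negative counts
#'   (vectorised).
#' @return p-values in `(0, 1]`.
#' @export
test_event <- function(a_treated, b_treated, a_control, b_control) {
  mapply(function(at, bt, ac, bc) {
    if ((at + bt) == 0 || (ac + bc) == 0 || (at + ac) == 0 || (bt + bc) == 0)
      return(1)
    stats::fisher.test(matrix(c(at, ac, bt, bc), nrow = 2))$p.value
  }, a_treated, b_treated, a_control, b_control)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment `q_i = min_{j >= rank(i)} m p_(j) / j`, capped at 1 and
#' returned in input order.
#'
#' @param p p-values in `(0, 1]`.
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Call differentially spliced events between two conditions
#'
#' Computes per-event SI in the control and treated samples, the delta-SI,
#' a two-sided Fisher exact p-value on the support counts, and BH q-values
#' pooled across all testable events of the five classes; an event is
#' significant when `|delta-SI| >= dsi_min` and `q < fdr_max`. Events whose
#' SI is undefined in either condition (informative reads below
#' `min_support`) are excluded from the FDR pool and never significant.
#'
#' @param events Event `data.frame` from [detect_events()].
#' @param junctions Junction count table.
#' @param evidence Intron evidence table.
#' @param control,treated Sample ids of the compared conditions.
#' @param dsi_min Minimum absolute delta-SI (default 0.15).
#' @param fdr_max FDR cutoff (default 0.01).
#' @param min_support Minimum informative reads per condition (default 10).
#' @return A `splicing_calls` data.frame: `event_id`, `type`, `gene_id`,
#'   `novel`, `a_control`, `b_control`, `a_treated`, `b_treated`,
#'   `si_control`, `si_treated`, `delta_si`, `p_value`, `q_value`,
#'   `significant`, `direction` (`up`/`down`/`NA`).
#' @export
call_events <- function(events, junctions, evidence, control, treated,
                        dsi_min = 0.15, fdr_max = 0.01, min_support = 10L) {
  if (!is.character(control) || !is.character(treated))
    stop("control and treated must be sample ids")
  if (dsi_min < 0 || dsi_min > 1) stop("dsi_min out of range [0, 1]")
  if (fdr_max <= 0 || fdr_max > 1) stop("fdr_max out of range (0, 1]")
  samples_seen <- unique(c(junctions$sample_id, evidence$sample_id))
  if (!control %in% samples_seen)
    stop("control sample '", control, "' absent from the count tables")

  sc <- event_support(events, junctions, evidence, control)
  st <- event_support(events, junctions, evidence, treated)
  si_c <- compute_si(sc$a, sc$b, min_support)
  si_t <- compute_si(st$a, st$b, min_support)
  dsi <- compute_delta_si(si_t, si_c)

  testable <- !is.na(dsi)
  p <- rep(NA_real_, nrow(events))
  p[testable] <- test_event(st$a[testable], st$b[testable],
                            sc$a[testable], sc$b[testable])
  q <- rep(NA_real_, nrow(events))
  q[testable] <- adjust_fdr(p[testable])

  sig <- !is.na(dsi) & abs(dsi) >= dsi_min & !is.na(q) & q < fdr_max
  dir <- ifelse(is.na(dsi) | dsi == 0, NA_character_,
                ifelse(dsi > 0, "up", "down"))
  out <- data.frame(
    event_id = events$event_id, type = events$type,
    gene_id = events$gene_id, novel = events$novel,
    a_control = sc$a, b_control = sc$b,
    a_treated = st$a, b_treated = st$b,
    si_control = si_c, si_treated = si_t, delta_si = dsi,
    p_value = p, q_value = q, significant = sig, direction = dir,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("splicing_calls", "data.frame"),
            control = control, treated = treated,
            dsi_min = dsi_min, fdr_max = fdr_max, min_support = min_support)
}

#' @export
print.splicing_calls <- function(x, ...) {
  cat("splicing_calls:", nrow(x), "candidate events,",
      attr(x, "treated"), "vs", attr(x, "control"), "\n")
  cat("  significant (|dSI| >=", attr(x, "dsi_min"), ", FDR <",
      attr(x, "fdr_max"), "):", sum(x$significant), "\n")
  invisible(x)
}

#' @export
summary.splicing_calls <- function(object, ...) {
  sig <- object[object$significant, , drop = FALSE]
  list(
    comparison = paste(attr(object, "treated"), "vs", attr(object, "control")),
    n_candidates = nrow(object),
    n_testable = sum(!is.na(object$delta_si)),
    n_significant = nrow(sig),
    by_type = if (nrow(sig)) table(sig$type) else table(character(0)),
    n_novel = sum(sig$novel),
    n_up = sum(sig$direction == "up", na.rm = TRUE),
    n_down = sum(sig$direction == "down", na.rm = TRUE)
  )
}
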