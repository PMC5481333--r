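# Summary accounting: event-type composition, direction fractions, phase
# overlaps, novelty and concordance. Every operation accepts either a calls
# table or pre-tabulated counts, so the same arithmetic serves pipeline
# output and externally printed tallies.

sig_calls <- function(calls) {
  if (!is.null(calls$significant)) calls[calls$significant, , drop = FALSE]
  else calls
}

#' Event-type composition of significant calls
#'
#' @param calls A `splicing_calls` table (its significant rows are used), or
#'   a named numeric vector of per-type counts.
#' @return `data.frame` with `type`, `count`, `share_pct` (two decimals) and
#'   `share_int` (nearest integer). With zero events all shares are 0 and the
#'   attribute `empty` is set.
#' @export
summarize_event_types <- function(calls) {
  counts <- if (is.data.frame(calls)) {
    s <- sig_calls(calls)
    tab <- table(factor(s$type, levels = event_types))
    setNames(as.numeric(tab), names(tab))
  } else {
    calls
  }
  total <- sum(counts)
  share <- if (total > 0) counts / total * 100 else counts * 0
  out <- data.frame(type = names(counts), count = as.numeric(counts),
                    share_pct = round(share, 2),
                    share_int = round(share),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "empty") <- total == 0
  out
}

#' Up/down direction split
#'
#' The fraction of events whose delta-SI is positive, at two decimals.
#'
#' @param calls A calls table, or a numeric vector `c(up = , down = )`.
#' @param type Optional event type to restrict a calls table to.
#' @return List with `n_up`, `n_down`, `total`, `pct_up`, `pct_down`.
#' @export
summarize_direction <- function(calls, type = NULL) {
  if (is.data.frame(calls)) {
    s <- sig_calls(calls)
    if (!is.null(type)) s <- s[s$type == type, , drop = FALSE]
    n_up <- sum(s$delta_si > 0, na.rm = TRUE)
    n_down <- sum(s$delta_si < 0, na.rm = TRUE)
  } else {
    n_up <- calls[["up"]]
    n_down <- calls[["down"]]
  }
  total <- n_up + n_down
  list(n_up = n_up, n_down = n_down, total = total,
       pct_up = if (total > 0) round(n_up / total * 100, 2) else 0,
       pct_down = if (total > 0) round(n_down / total * 100, 2) else 0)
}

#' Overlap of significant events between two comparisons
#'
#' Events are matched across comparisons by their deterministic event id.
#' The shared share is reported against the union of both call sets.
#'
#' @param calls_a,calls_b Calls tables (significant rows used), or a numeric
#'   vector `c(shared = , a_only = , b_only = )` in place of `calls_a` with
#'   `calls_b = NULL`.
#' @param type Optional event type restriction.
#' @return List with `shared`, `a_only`, `b_only`, `union`, `shared_pct`
#'   (share of union, two decimals) plus per-set shares.
#' @export
summarize_phase_overlap <- function(calls_a, calls_b = NULL, type = NULL) {
  if (is.data.frame(calls_a)) {
    a <- sig_calls(calls_a); b <- sig_calls(calls_b)
    if (!is.null(type)) {
      a <- a[a$type == type, , drop = FALSE]
      b <- b[b$type == type, , drop = FALSE]
    }
    shared <- length(intersect(a$event_id, b$event_id))
    a_only <- length(setdiff(a$event_id, b$event_id))
    b_only <- length(setdiff(b$event_id, a$event_id))
  } else {
    shared <- calls_a[["shared"]]
    a_only <- calls_a[["a_only"]]
    b_only <- calls_a[["b_only"]]
  }
  un <- shared + a_only + b_only
  list(shared = shared, a_only = a_only, b_only = b_only, union = un,
       shared_pct = if (un > 0) round(shared / un * 100, 2) else 0,
       shared_pct_of_a = if (shared + a_only > 0)
         round(shared / (shared + a_only) * 100, 2) else 0,
       shared_pct_of_b = if (shared + b_only > 0)
         round(shared / (shared + b_only) * 100, 2) else 0)
}

#' Known/novel composition of significant calls
#'
#' @param calls A calls table (significant rows used), or a numeric vector
#'   `c(novel = , known = )`.
#' @return List with `n_novel`, `n_known`, `total`, `pct_novel`.
#' @export
summarize_novelty <- function(calls) {
  if (is.data.frame(calls)) {
    s <- sig_calls(calls)
    n_novel <- sum(s$novel, na.rm = TRUE)
    n_known <- sum(!s$novel, na.rm = TRUE)
  } else {
    n_novel <- calls[["novel"]]
    n_known <- calls[["known"]]
  }
  total <- n_novel + n_known
  list(n_novel = n_novel, n_known = n_known, total = total,
       pct_novel = if (total > 0) round(n_novel / total * 100, 2) else 0)
}

#' Concordance between two paired sets of delta-SI estimates
#'
#' The squared Pearson correlation of the pairs (sign-blind: `y = -x` also
#' gives R-squared 1).
#'
#' @param x,y Paired numeric vectors (e.g. sequencing-derived vs
#'   validation-derived delta-SI).
#' @return R-squared, or `NA` with a warning when fewer than two complete
#'   pairs remain or either side has zero variance.
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::var(x) == 0 || stats::var(y) == 0) {
    warning("concordance undefined: need >= 2 pairs with non-zero variance")
    return(NA_real_)
  }
  unname(cor(x, y)^2)
}
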