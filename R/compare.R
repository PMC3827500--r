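#' Fisher's exact test on inclusion/exclusion junction counts
#'
#' Two-sided Fisher's exact test of the 2 x 2 table
#' `[[inc_a, exc_a], [inc_b, exc_b]]` against the null hypothesis that the
#' two samples have equal inclusion/exclusion proportions. Counts must be
#' non-negative integers (the test is defined on integer counts); a
#' degenerate table (a zero row or zero column margin) returns p = 1 by
#' convention so downstream FDR correction sees a stable input length.
#'
#' @param inc_a,exc_a,inc_b,exc_b total junction read counts of the
#'   inclusion and exclusion paths in samples A and B (vectorized)
#' @return two-sided p-value(s)
#' @export
fet_event <- function(inc_a, exc_a, inc_b, exc_b) {
  x <- cbind(inc_a, exc_a, inc_b, exc_b)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop_format("fet_event requires non-negative integer counts")
  vapply(seq_len(nrow(x)), function(i) {
    m <- matrix(x[i, ], 2L, 2L, byrow = TRUE)
    if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) return(1)
    stats::fisher.test(m)$p.value
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; output order
#' matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Compare event quantifications between two samples
#'
#' Joins per-event PSI quantifications of two samples, tests each event
#' with Fisher's exact test on the inclusion/exclusion junction count
#' table, adjusts p-values by Benjamini-Hochberg, and applies the
#' conservative differential-splicing call gates: adjusted p below `alpha`,
#' more than `min_reads` junction reads in each path in both samples,
#' `|delta PSI|` above `min_dpsi`, and — when replicate comparisons are
#' supplied — a raw between-sample p-value smaller than the smallest raw
#' between-replicate p-value for that event. Only events with inclusion
#' coverage detected in either sample and exclusion coverage detected in
#' either sample are testable; others are reported untested. All component
#' verdicts are returned so the gates are auditable.
#'
#' @param quants_a,quants_b [quantify_events()] tables of the two samples
#'   (same event universe)
#' @param replicates optional list of [quantify_events()] table pairs
#'   (`list(list(a_rep1, a_rep2), ...)`); per event, the replicate gate uses
#'   the minimum FET p across pairs
#' @param alpha adjusted-p threshold (default 0.01)
#' @param min_reads per-path read-count gate: each path must exceed this in
#'   both samples (default 10, i.e. the gate is `> 10`)
#' @param min_dpsi minimum `|delta PSI|` (default 0.20)
#' @return data.frame, one row per event, with counts, `psi_a`, `psi_b`,
#'   `delta_psi` (= `psi_b - psi_a`), `p_raw`, `p_adj`, `replicate_p_raw`,
#'   the per-gate verdicts (`testable`, `gate_p`, `gate_reads`,
#'   `gate_dpsi`, `gate_replicate`) and the final `call`
#' @export
compare_events <- function(quants_a, quants_b, replicates = NULL,
                           alpha = 0.01, min_reads = 10L, min_dpsi = 0.20) {
  if (!identical(quants_a$event_id, quants_b$event_id)) {
    miss <- c(setdiff(quants_a$event_id, quants_b$event_id),
              setdiff(quants_b$event_id, quants_a$event_id))
    if (length(miss))
      stop_format("event universes differ between samples: %s",
                  paste(head(miss, 5L), collapse = ", "))
    quants_b <- quants_b[match(quants_a$event_id, quants_b$event_id), ]
  }
  ev <- quants_a[, c("event_id", "gene_id", "chrom", "strand", "event_type",
                     "structure_code")]
  ev$inc_a <- quants_a$inc_total; ev$exc_a <- quants_a$exc_total
  ev$inc_b <- quants_b$inc_total; ev$exc_b <- quants_b$exc_total
  ev$psi_a <- quants_a$psi; ev$psi_b <- quants_b$psi
  ev$delta_psi <- ev$psi_b - ev$psi_a

  ev$testable <- (ev$inc_a > 0L | ev$inc_b > 0L) &
                 (ev$exc_a > 0L | ev$exc_b > 0L) &
                 quants_a$quantifiable & quants_b$quantifiable
  ev$p_raw <- NA_real_
  t_idx <- which(ev$testable)
  if (length(t_idx))
    ev$p_raw[t_idx] <- fet_event(ev$inc_a[t_idx], ev$exc_a[t_idx],
                                 ev$inc_b[t_idx], ev$exc_b[t_idx])
  ev$p_adj <- NA_real_
  ev$p_adj[t_idx] <- bh_adjust(ev$p_raw[t_idx])

  ev$replicate_p_raw <- NA_real_
  if (!is.null(replicates) && length(replicates)) {
    rep_p <- rep(Inf, nrow(ev))
    for (pair in replicates) {
      ra <- pair[[1L]]; rb <- pair[[2L]]
      stopifnot(identical(ra$event_id, ev$event_id),
                identical(rb$event_id, ev$event_id))
      ok <- (ra$inc_total > 0L | rb$inc_total > 0L) &
            (ra$exc_total > 0L | rb$exc_total > 0L)
      pr <- rep(NA_real_, nrow(ev))
      pr[ok] <- fet_event(ra$inc_total[ok], ra$exc_total[ok],
                          rb$inc_total[ok], rb$exc_total[ok])
      rep_p <- pmin(rep_p, ifelse(is.na(pr), Inf, pr))
    }
    ev$replicate_p_raw <- ifelse(is.finite(rep_p), rep_p, NA_real_)
  }

  min_path <- pmin(ev$inc_a, ev$exc_a, ev$inc_b, ev$exc_b)
  ev$gate_p <- !is.na(ev$p_adj) & ev$p_adj < alpha
  ev$gate_reads <- min_path > min_reads
  ev$gate_dpsi <- !is.na(ev$delta_psi) & abs(ev$delta_psi) > min_dpsi
  ev$gate_replicate <- is.na(ev$replicate_p_raw) |
    (!is.na(ev$p_raw) & ev$p_raw < ev$replicate_p_raw)
  ev$call <- ev$testable & ev$gate_p & ev$gate_reads & ev$gate_dpsi &
    ev$gate_replicate
  ev
}

#' Volcano table (delta PSI vs -log10 p)
#'
#' @param comparisons a [compare_events()] table
#' @param plot draw a base-graphics volcano plot?
#' @return data.frame with `event_id`, `delta_psi`, `neg_log10_p` (raw p;
#'   zero p-values are floored at the smallest positive double), `call`
#' @export
volcano_table <- function(comparisons, plot = FALSE) {
  p <- comparisons$p_raw
  p[!is.na(p) & p <= 0] <- .Machine$double.xmin
  out <- data.frame(event_id = comparisons$event_id,
                    delta_psi = comparisons$delta_psi,
                    neg_log10_p = -log10(p),
                    call = comparisons$call)
  if (plot && nrow(out)) {
    graphics::plot(out$delta_psi, out$neg_log10_p,
                   xlab = expression(Delta * "PSI"),
                   ylab = expression(-log[10] ~ "p"),
                   pch = 20, col = ifelse(out$call, "red", "grey40"),
                   xlim = c(-1, 1))
    graphics::abline(v = 0, lty = 2, col = "grey70")
  }
  out
}
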