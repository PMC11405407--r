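#' Differential intron retention between two conditions
#'
#' Pools intron-retention and junction reads within each group, estimates
#' per-group PSI from the pooled counts, and tests the retention-proportion
#' difference per event with a two-sided Fisher exact test on the 2x2 table
#' \code{[(ir_A, sj_A), (ir_B, sj_B)]}.  P values are Benjamini-Hochberg
#' adjusted across all tested events; an event is called significant when
#' \code{fdr < fdr_threshold} and \code{|delta_psi| > dpsi_threshold}
#' (both retention gains and losses are reported).  The difference sign
#' convention is \code{group_b - group_a}.
#'
#' Events where one group has zero total counts cannot be tested; they are
#' skipped and recorded in the \code{"skipped"} attribute.
#'
#' @param counts long-format count table with columns \code{event_id},
#'   \code{sample}, \code{condition}, \code{ir_reads}, \code{sj_reads}
#'   (as produced by \code{\link{simulate_ir_counts}} or
#'   \code{\link{read_counts_tsv}}).
#' @param group_a,group_b condition labels; \code{group_a} is the baseline.
#' @param fdr_threshold,dpsi_threshold significance gates (defaults
#'   \code{0.05} and \code{0.02}).
#' @return A data frame of class \code{"splice_event_table"}, one row per
#'   event: pooled counts, \code{psi_a}, \code{psi_b}, \code{delta_psi},
#'   \code{p_value}, \code{fdr}, \code{significant}.  Thresholds are stored
#'   as attributes.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 8, depth = 150)
#' counts <- simulate_ir_counts(simulate_annotation(cfg), cfg)
#' res <- diff_ir(counts, "control", "knockdown")
#' summary(res)
#' @export
diff_ir <- function(counts, group_a, group_b,
                    fdr_threshold = 0.05, dpsi_threshold = 0.02) {
  need <- c("event_id", "condition", "ir_reads", "sj_reads")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  groups <- unique(counts$condition)
  for (g in c(group_a, group_b))
    if (!g %in% groups) stop("unknown group label: ", g)
  pool <- function(g, col) {
    sub <- counts[counts$condition == g, ]
    tapply(sub[[col]], sub$event_id, sum)
  }
  ir_a <- pool(group_a, "ir_reads"); sj_a <- pool(group_a, "sj_reads")
  ir_b <- pool(group_b, "ir_reads"); sj_b <- pool(group_b, "sj_reads")
  events <- sort(union(names(ir_a), names(ir_b)))
  get0n <- function(v, e) ifelse(e %in% names(v), v[e], 0)
  tab <- data.frame(
    event_id = events,
    ir_a = as.numeric(get0n(ir_a, events)), sj_a = as.numeric(get0n(sj_a, events)),
    ir_b = as.numeric(get0n(ir_b, events)), sj_b = as.numeric(get0n(sj_b, events)),
    stringsAsFactors = FALSE)
  testable <- (tab$ir_a + tab$sj_a) > 0 & (tab$ir_b + tab$sj_b) > 0
  skipped <- tab$event_id[!testable]
  tab <- tab[testable, , drop = FALSE]
  tab$psi_a <- compute_psi(tab$ir_a, tab$sj_a)
  tab$psi_b <- compute_psi(tab$ir_b, tab$sj_b)
  tab$delta_psi <- tab$psi_b - tab$psi_a
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i) {
    m <- matrix(c(tab$ir_a[i], tab$sj_a[i], tab$ir_b[i], tab$sj_b[i]),
                nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  tab$fdr <- stats::p.adjust(tab$p_value, method = "BH")
  tab$significant <- tab$fdr < fdr_threshold &
    abs(tab$delta_psi) > dpsi_threshold
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  attr(tab, "fdr_threshold") <- fdr_threshold
  attr(tab, "dpsi_threshold") <- dpsi_threshold
  class(tab) <- c("splice_event_table", "data.frame")
  tab
}

#' @export
print.splice_event_table <- function(x, ...) {
  cat(sprintf("Splice event table: %d events, %d significant (FDR < %g, |dPSI| > %g)\n",
              nrow(x), sum(x$significant), attr(x, "fdr_threshold"),
              attr(x, "dpsi_threshold")))
  if (length(attr(x, "skipped")))
    cat("  skipped (zero counts in a group):", length(attr(x, "skipped")), "\n")
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.splice_event_table <- function(object, ...) {
  sig <- object[object$significant, , drop = FALSE]
  out <- list(n_events = nrow(object), n_significant = nrow(sig),
              n_up = sum(sig$delta_psi > 0), n_down = sum(sig$delta_psi < 0),
              skipped = length(attr(object, "skipped")),
              fdr_threshold = attr(object, "fdr_threshold"),
              dpsi_threshold = attr(object, "dpsi_threshold"))
  class(out) <- "summary.splice_event_table"
  out
}

#' @export
print.summary.splice_event_table <- function(x, ...) {
  cat(sprintf(
    "%d events tested (%d skipped); %d significant at FDR < %g and |dPSI| > %g (%d up, %d down)\n",
    x$n_events, x$skipped, x$n_significant, x$fdr_threshold,
    x$dpsi_threshold, x$n_up, x$n_down))
  invisible(x)
}
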