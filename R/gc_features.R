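#' Trimmed intron/exon GC ratio
#'
#' Compares an intron's GC content with that of its flanking exons after
#' removing splice-signal nucleotides: 20 nt from either end of the intron
#' and 3 nt from either end of each exon.  The ratio is
#' \code{GC(trimmed intron) / mean(GC(trimmed upstream exon),
#' GC(trimmed downstream exon))}.  Cores that are empty after trimming make
#' the ratio undefined (\code{NA}, with the reason in the \code{"reason"}
#' attribute).
#'
#' @param intron_seq,exon_up_seq,exon_down_seq nucleotide sequences
#'   (transcript orientation; the computation is invariant to
#'   reverse-complementing all three together).
#' @param intron_trim,exon_trim nucleotides removed from each intron end /
#'   each exon end.
#' @return The GC ratio (positive for non-degenerate sequences), or
#'   \code{NA} with a \code{"reason"} attribute.
#' @examples
#' relative_gc(strrep("G", 100), strrep("G", 50), strrep("G", 50))  # 1
#' @export
relative_gc <- function(intron_seq, exon_up_seq, exon_down_seq,
                        intron_trim = 20L, exon_trim = 3L) {
  core <- function(s, left, right) {
    n <- nchar(s)
    if (n - left - right < 1L) return(NULL)
    substr(s, left + 1L, n - right)
  }
  gc <- function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    mean(ch %in% c("G", "C"))
  }
  ic <- core(intron_seq, intron_trim, intron_trim)
  eu <- core(exon_up_seq, exon_trim, exon_trim)
  ed <- core(exon_down_seq, exon_trim, exon_trim)
  if (is.null(ic) || is.null(eu) || is.null(ed)) {
    out <- NA_real_
    attr(out, "reason") <- "empty core after trimming"
    return(out)
  }
  gc(ic) / mean(c(gc(eu), gc(ed)))
}

#' Per-intron sequence features for RI vs NRI comparison
#'
#' For every intron of every gene in the annotation, extracts the donor and
#' acceptor windows (strand-aware), scores them against the given models,
#' computes the trimmed GC ratio, and flags introns as retained (RI) when
#' their event id is in \code{retained_events}.  Following the comparison
#' design, the non-retained set is restricted to introns of genes that
#' harbor at least one retained intron (set \code{same_genes_only = FALSE}
#' to keep all genes).
#'
#' @param txs a \code{"transcript_set"}.
#' @param retained_events character vector of retained event ids
#'   (\code{gene:I<k>}), e.g. significant events from \code{\link{diff_ir}}.
#' @param donor_model,acceptor_model site models used for scoring.
#' @param same_genes_only restrict NRIs to genes harboring an RI.
#' @return Data frame: \code{event_id}, \code{gene_id}, \code{donor_score},
#'   \code{acceptor_score}, \code{gc_ratio}, \code{retained}.
#' @export
intron_features <- function(txs, retained_events,
                            donor_model = consensus_donor_model(),
                            acceptor_model = consensus_acceptor_model(),
                            same_genes_only = TRUE) {
  stopifnot(inherits(txs, "transcript_set"))
  rows <- list()
  for (tx in txs$transcripts) {
    introns <- tx_introns(tx)
    ex <- tx_exons_oriented(tx)
    for (k in seq_len(nrow(introns))) {
      ev <- sprintf("%s:I%d", tx$gene_id, k)
      iseq <- genome_subseq(txs$genome, tx$chrom, introns[k, "start"],
                            introns[k, "end"], tx$strand)
      eu <- genome_subseq(txs$genome, tx$chrom, ex[k, "start"],
                          ex[k, "end"], tx$strand)
      ed <- genome_subseq(txs$genome, tx$chrom, ex[k + 1L, "start"],
                          ex[k + 1L, "end"], tx$strand)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev, gene_id = tx$gene_id,
        donor_score = score_splice_site(
          site_window(tx, txs$genome, k, "donor"), donor_model),
        acceptor_score = score_splice_site(
          site_window(tx, txs$genome, k, "acceptor"), acceptor_model),
        gc_ratio = relative_gc(iseq, eu, ed),
        retained = ev %in% retained_events,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (same_genes_only) {
    ri_genes <- unique(out$gene_id[out$retained])
    out <- out[out$gene_id %in% ri_genes, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Rank-sum comparison of retained vs non-retained introns
#'
#' Two-sided (by default) Wilcoxon rank-sum / Mann-Whitney U test between
#' two feature-value groups (e.g. donor scores of RIs vs NRIs).  Uses the
#' exact distribution when both groups have at most 10 observations and no
#' ties, otherwise the tie-corrected normal approximation.
#'
#' @param values_ri,values_nri numeric vectors, each with >= 2 observations.
#' @param alternative test alternative (\code{"two.sided"}, \code{"less"},
#'   \code{"greater"}).
#' @return List with \code{statistic} (U, first group vs second), \code{p},
#'   \code{n_ri}, \code{n_nri}, \code{exact}.
#' @export
compare_ri_nri <- function(values_ri, values_nri,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  values_ri <- values_ri[!is.na(values_ri)]
  values_nri <- values_nri[!is.na(values_nri)]
  if (length(values_ri) < 2L || length(values_nri) < 2L)
    stop("both groups need at least 2 observations")
  ties <- anyDuplicated(c(values_ri, values_nri)) > 0
  exact <- length(values_ri) <= 10L && length(values_nri) <= 10L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    values_ri, values_nri, alternative = alternative,
    exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_ri = length(values_ri), n_nri = length(values_nri), exact = exact)
}
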