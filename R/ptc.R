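#' Coding consequence of a retained intron
#'
#' Splices the transcript with the named intron retained, translates from
#' the coding start (synthetic convention: transcript nucleotide 1), and
#' reports whether the intron disrupts the reading frame
#' (\code{length mod 3 != 0}), the first in-frame stop codon at or after the
#' intron, and whether that stop precedes the normal transcript's stop
#' (a premature termination codon truncating the protein).
#'
#' @param txs a \code{"transcript_set"}.
#' @param gene_id gene whose transcript is analyzed.
#' @param intron_index which intron is retained (1-based, transcript order).
#' @return A one-row data frame: \code{event_id}, \code{intron_length},
#'   \code{frameshift}, \code{ptc_offset} (1-based codon index counted from
#'   the first codon touching the retained intron; \code{NA} if no stop is
#'   found), \code{truncation_flag}.
#' @examples
#' txs <- simulate_annotation(sim_config(seed = 2, n_genes = 2))
#' detect_ptc(txs, "G0001", 1)
#' @export
detect_ptc <- function(txs, gene_id, intron_index = 1L) {
  stopifnot(inherits(txs, "transcript_set"))
  tx <- NULL
  for (t in txs$transcripts) if (t$gene_id == gene_id) { tx <- t; break }
  if (is.null(tx)) stop("unknown gene: ", gene_id)
  introns <- tx_introns(tx)
  if (intron_index < 1L || intron_index > nrow(introns))
    stop("intron index out of range for ", gene_id)
  ilen <- unname(introns[intron_index, "end"] - introns[intron_index, "start"] + 1L)
  ex <- tx_exons_oriented(tx)
  exon_lens <- ex[, "end"] - ex[, "start"] + 1L
  # transcript position (1-based) of the retained intron's first base
  intron_tx_start <- sum(exon_lens[seq_len(intron_index)]) + 1L

  retained <- tx_sequence(tx, txs$genome, retain_intron = intron_index)
  normal <- tx_sequence(tx, txs$genome)
  stop_nt <- function(seq) first_stop_codon(seq)  # codon index or NA

  # codon containing the intron's first nucleotide
  c0 <- (intron_tx_start - 1L) %/% 3L + 1L
  ret_stop <- first_stop_codon(retained, from_codon = c0)
  ptc_offset <- if (is.na(ret_stop)) NA_integer_ else ret_stop - c0 + 1L

  norm_stop <- stop_nt(normal)
  truncation <- FALSE
  if (!is.na(ret_stop)) {
    if (is.na(norm_stop)) {
      truncation <- TRUE
    } else {
      # map the normal stop's first nucleotide into retained coordinates
      norm_nt <- (norm_stop - 1L) * 3L + 1L
      norm_nt_mapped <- norm_nt + if (norm_nt >= intron_tx_start) ilen else 0L
      ret_nt <- (ret_stop - 1L) * 3L + 1L
      truncation <- ret_nt < norm_nt_mapped
    }
  }
  data.frame(event_id = sprintf("%s:I%d", gene_id, intron_index),
             intron_length = as.integer(ilen),
             frameshift = (ilen %% 3L) != 0L,
             ptc_offset = ptc_offset,
             truncation_flag = truncation,
             stringsAsFactors = FALSE)
}

# Index (1-based, from the coding start at nucleotide 1) of the first stop
# codon at or after `from_codon`; NA if none.
first_stop_codon <- function(seq, from_codon = 1L) {
  n_codons <- nchar(seq) %/% 3L
  if (from_codon > n_codons) return(NA_integer_)
  for (c in seq(from_codon, n_codons)) {
    codon <- substr(seq, (c - 1L) * 3L + 1L, c * 3L)
    if (codon %in% c("TAA", "TAG", "TGA")) return(c)
  }
  NA_integer_
}
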