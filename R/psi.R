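#' Percent spliced in (PSI) from read counts
#'
#' For a retained-intron event, PSI is the fraction of reads supporting
#' retention: \code{ir_reads / (ir_reads + sj_reads)}.  Events with no
#' reads at all are undefined and return \code{NA}, never 0.
#'
#' @param ir_reads nonnegative intron-retention read counts.
#' @param sj_reads nonnegative splice-junction read counts.
#' @return Numeric vector of PSI values in \code{[0, 1]} (or \code{NA}).
#' @examples
#' compute_psi(c(0, 30, 10), c(50, 30, 30))
#' @export
compute_psi <- function(ir_reads, sj_reads) {
  stopifnot(length(ir_reads) == length(sj_reads))
  if (any(ir_reads < 0 | sj_reads < 0, na.rm = TRUE))
    stop("read counts must be nonnegative")
  total <- ir_reads + sj_reads
  ifelse(total > 0, ir_reads / total, NA_real_)
}

#' PSI from qPCR cycle thresholds
#'
#' Inverts the exponential amplification of qPCR: with one assay spanning
#' the adjacent exons (all transcripts, \code{ct_all}) and one inside the
#' retained intron (retaining transcripts, \code{ct_in}), the retained
#' fraction is \code{PSI = 2^(ct_all - ct_in)}.  Measurement noise can push
#' estimates above 1; such values are returned as computed and flagged in
#' the \code{"out_of_range"} attribute.
#'
#' @param ct_all,ct_in finite positive cycle thresholds.
#' @return Numeric PSI estimates with a logical \code{"out_of_range"}
#'   attribute marking values > 1.
#' @examples
#' qpcr_psi(20, 25)    # 2^-5
#' qpcr_psi(25, 20)    # 32, flagged
#' @export
qpcr_psi <- function(ct_all, ct_in) {
  if (!all(is.finite(ct_all)) || !all(is.finite(ct_in)))
    stop("cycle thresholds must be finite")
  psi <- 2^(ct_all - ct_in)
  attr(psi, "out_of_range") <- psi > 1
  psi
}
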