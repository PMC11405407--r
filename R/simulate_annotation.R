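# Synthetic gene models: three exons, two introns per gene; the first intron
# is the measured retention event.  Donor/acceptor consensus sequences are
# implanted at every junction except the first-intron donor of "weak" genes,
# which carries a fixed degenerate 9-mer (3 consensus positions mutated).

DONOR_CONSENSUS    <- "CAGGTAAGT"                 # 3 exonic + 6 intronic
DONOR_WEAK         <- "CAGGTCGGA"                 # positions 6, 7, 9 mutated
ACCEPTOR_CONSENSUS <- "TTTTTTTTTTTTTTTTTCAGGTC"  # 20 intronic + 3 exonic

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

# stop-free coding sequence: random non-stop codons, truncated to n nt, so
# exon chains (with exon lengths divisible by 3) read as an open frame and
# premature stops can only come from retained introns
random_orf <- function(n) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  substr(paste(sample(codons, ceiling(n / 3), replace = TRUE), collapse = ""),
         1L, n)
}

#' Generate a synthetic annotation and genome
#'
#' Builds \code{n_genes} three-exon gene models with consensus splice sites,
#' except that a \code{weak_fraction} subset carries a degenerate donor at
#' its first intron (three consensus positions mutated).  Genes alternate
#' between the plus and minus strand; each gene lives on its own contig so
#' coordinates and sequences are trivially consistent.  Intron lengths vary
#' deterministically around \code{intron_length} and are checked against the
#' 70-nt minimum required for trimmed GC cores.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{"transcript_set"}: a list with elements
#'   \code{transcripts} (list of gene models: \code{gene_id},
#'   \code{transcript_id}, \code{chrom}, \code{strand}, \code{exons} --
#'   a two-column matrix of 1-based closed genome-forward intervals sorted
#'   ascending), \code{genome} (a \code{DNAStringSet}), and
#'   \code{ground_truth} (per-gene data frame with the weak-donor flag and
#'   event ids).
#' @examples
#' txs <- simulate_annotation(sim_config(seed = 1, n_genes = 4))
#' txs
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 1L), {
    n <- config$n_genes
    n_weak <- round(config$weak_fraction * n)
    weak <- rep(FALSE, n)
    if (n_weak > 0) weak[sample.int(n, n_weak)] <- TRUE
    flank <- 100L
    transcripts <- vector("list", n)
    seqs <- character(n)
    gt <- vector("list", n)
    for (i in seq_len(n)) {
      gene_id <- sprintf("G%04d", i)
      strand <- if (i %% 2L == 1L) "+" else "-"
      ex_len <- config$exon_length
      i1_len <- config$intron_length + (i - 1L) %% 7L
      i2_len <- config$intron_length + (i * 3L) %% 11L
      if (min(i1_len, i2_len) < 70L)
        stop("intron shorter than 70 nt in gene ", gene_id)
      # sense-orientation layout
      exon_s <- cumsum(c(flank + 1L, ex_len + i1_len, ex_len + i2_len))
      exon_e <- exon_s + ex_len - 1L
      total <- exon_e[3] + flank
      seq <- strsplit(random_dna(total), "", fixed = TRUE)[[1]]
      implant <- function(seq, at, motif) {
        m <- strsplit(motif, "", fixed = TRUE)[[1]]
        seq[at:(at + length(m) - 1L)] <- m
        seq
      }
      for (k in 1:3)  # exons read as an open frame (coding start = nt 1)
        seq <- implant(seq, exon_s[k], random_orf(ex_len))
      donor1 <- if (weak[i]) DONOR_WEAK else DONOR_CONSENSUS
      seq <- implant(seq, exon_e[1] - 2L, donor1)             # exon1|intron1
      seq <- implant(seq, exon_s[2] - 20L, ACCEPTOR_CONSENSUS)
      seq <- implant(seq, exon_e[2] - 2L, DONOR_CONSENSUS)    # exon2|intron2
      seq <- implant(seq, exon_s[3] - 20L, ACCEPTOR_CONSENSUS)
      sense <- paste(seq, collapse = "")
      if (strand == "+") {
        chrom_seq <- sense
        exons <- cbind(start = exon_s, end = exon_e)
      } else {
        chrom_seq <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(sense)))
        exons <- cbind(start = total - exon_e + 1L, end = total - exon_s + 1L)
        exons <- exons[order(exons[, 1]), , drop = FALSE]
      }
      chrom <- sprintf("chr_%s", gene_id)
      transcripts[[i]] <- list(gene_id = gene_id,
                               transcript_id = paste0(gene_id, ".t1"),
                               chrom = chrom, strand = strand, exons = exons)
      seqs[i] <- chrom_seq
      names(seqs)[i] <- chrom
      gt[[i]] <- data.frame(gene_id = gene_id, weak_donor = weak[i],
                            strand = strand, intron1_length = i1_len,
                            intron2_length = i2_len,
                            event_id = paste0(gene_id, ":I1"),
                            stringsAsFactors = FALSE)
    }
    out <- list(transcripts = transcripts,
                genome = Biostrings::DNAStringSet(seqs),
                ground_truth = do.call(rbind, gt))
    class(out) <- "transcript_set"
    out
  })
}

#' @export
print.transcript_set <- function(x, ...) {
  n <- length(x$transcripts)
  cat("Transcript set:", n, "gene models on", length(x$genome), "contigs\n")
  if (!is.null(x$ground_truth))
    cat("  weak-donor genes:", sum(x$ground_truth$weak_donor), "\n")
  invisible(x)
}

# exons ordered 5' -> 3' along the transcript
tx_exons_oriented <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

# introns as genome-forward intervals, ordered 5' -> 3' along the transcript
tx_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(ex[0, , drop = FALSE])
  introns <- cbind(start = ex[-nrow(ex), "end"] + 1L,
                   end = ex[-1L, "start"] - 1L)
  if (tx$strand == "-") introns <- introns[rev(seq_len(nrow(introns))), ,
                                           drop = FALSE]
  introns
}

genome_subseq <- function(genome, chrom, start, end, strand = "+") {
  s <- Biostrings::subseq(genome[[chrom]], start = start, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# Mature (or intron-retaining) transcript sequence in coding orientation.
tx_sequence <- function(tx, genome, retain_intron = NULL) {
  ex <- tx_exons_oriented(tx)
  introns <- tx_introns(tx)
  if (!is.null(retain_intron) &&
      (retain_intron < 1L || retain_intron > nrow(introns)))
    stop("intron index out of range for ", tx$gene_id)
  pieces <- character(0)
  for (k in seq_len(nrow(ex))) {
    pieces <- c(pieces, genome_subseq(genome, tx$chrom,
                                      ex[k, "start"], ex[k, "end"], tx$strand))
    if (!is.null(retain_intron) && k == retain_intron)
      pieces <- c(pieces, genome_subseq(genome, tx$chrom,
                                        introns[k, "start"], introns[k, "end"],
                                        tx$strand))
  }
  paste(pieces, collapse = "")
}

#' Extract splice-site window sequences
#'
#' Pulls the donor (3 exonic + 6 intronic nt) or acceptor (20 intronic +
#' 3 exonic nt) window of an intron, strand-aware: minus-strand windows are
#' reverse-complemented so every returned sequence reads 5' to 3' on the
#' transcript.
#'
#' @param txs a \code{"transcript_set"} (or a single transcript model).
#' @param site_kind \code{"donor"} or \code{"acceptor"}.
#' @param intron_index which intron (1-based, transcript order); vectorized
#'   over transcripts, recycled.
#' @return Named character vector of window sequences (names are
#'   \code{gene:I<k>} event ids).
#' @export
extract_site_sequences <- function(txs, site_kind = c("donor", "acceptor"),
                                   intron_index = 1L) {
  site_kind <- match.arg(site_kind)
  stopifnot(inherits(txs, "transcript_set"))
  idx <- rep_len(as.integer(intron_index), length(txs$transcripts))
  out <- character(length(txs$transcripts))
  nm <- character(length(out))
  for (i in seq_along(txs$transcripts)) {
    tx <- txs$transcripts[[i]]
    out[i] <- site_window(tx, txs$genome, idx[i], site_kind)
    nm[i] <- sprintf("%s:I%d", tx$gene_id, idx[i])
  }
  setNames(out, nm)
}

site_window <- function(tx, genome, intron_index, site_kind) {
  introns <- tx_introns(tx)
  if (intron_index < 1L || intron_index > nrow(introns))
    stop("intron index out of range for ", tx$gene_id)
  it <- introns[intron_index, ]
  if (tx$strand == "+") {
    if (site_kind == "donor")
      genome_subseq(genome, tx$chrom, it["start"] - 3L, it["start"] + 5L, "+")
    else
      genome_subseq(genome, tx$chrom, it["end"] - 19L, it["end"] + 3L, "+")
  } else {
    # transcript 5' end of a minus-strand intron is its genome-forward end
    if (site_kind == "donor")
      genome_subseq(genome, tx$chrom, it["end"] - 5L, it["end"] + 3L, "-")
    else
      genome_subseq(genome, tx$chrom, it["start"] - 3L, it["start"] + 19L, "-")
  }
}

#' Write annotation as GTF + FASTA
#'
#' @param txs a \code{"transcript_set"}.
#' @param gtf_file,fasta_file output paths.  GTF uses 1-based closed
#'   intervals with \code{gene_id}/\code{transcript_id} attributes; FASTA is
#'   wrapped at 60 columns.
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(txs, gtf_file, fasta_file) {
  stopifnot(inherits(txs, "transcript_set"))
  lines <- character(0)
  for (tx in txs$transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id, tx$transcript_id)
    rng <- range(tx$exons)
    lines <- c(lines,
      paste(tx$chrom, "spliceometab", "transcript", rng[1], rng[2], ".",
            tx$strand, ".", attrs, sep = "\t"),
      paste(tx$chrom, "spliceometab", "exon", tx$exons[, "start"],
            tx$exons[, "end"], ".", tx$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, gtf_file)
  Biostrings::writeXStringSet(txs$genome, fasta_file, width = 60L)
  invisible(c(gtf = gtf_file, fasta = fasta_file))
}

#' Load an annotation from GTF + FASTA
#'
#' Reads exon features (via \pkg{rtracklayer}) and the genome sequence into
#' the same \code{"transcript_set"} structure the simulator produces, so all
#' downstream sequence operations work identically on external annotations.
#'
#' @param gtf_file,fasta_file input paths.
#' @return A \code{"transcript_set"} (without ground truth).
#' @export
load_annotation <- function(gtf_file, fasta_file) {
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  gr <- gr[gr$type == "exon"]
  genome <- Biostrings::readDNAStringSet(fasta_file)
  names(genome) <- sub("\\s.*$", "", names(genome))
  split_by <- as.character(gr$transcript_id)
  transcripts <- lapply(split(seq_along(gr), split_by), function(ii) {
    g <- gr[ii]
    ord <- order(GenomicRanges::start(g))
    list(gene_id = as.character(g$gene_id[1]),
         transcript_id = as.character(g$transcript_id[1]),
         chrom = as.character(GenomicRanges::seqnames(g)[1]),
         strand = as.character(GenomicRanges::strand(g)[1]),
         exons = cbind(start = GenomicRanges::start(g)[ord],
                       end = GenomicRanges::end(g)[ord]))
  })
  out <- list(transcripts = unname(transcripts), genome = genome,
              ground_truth = NULL)
  class(out) <- "transcript_set"
  out
}
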