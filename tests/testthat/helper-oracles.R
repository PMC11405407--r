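# Independent brute-force oracles used to cross-check the package's
# statistics, plus a builder for hand-made transcript sets.

# two-sided Mann-Whitney p by enumerating all group assignments
enum_wilcox_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  r <- rank(vals)
  combs <- utils::combn(length(vals), n1)
  U <- apply(combs, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * min(mean(U <= u_obs), mean(U >= u_obs), 0.5)
}

# two-sided Fisher p by summing hypergeometric probabilities of tables
# with the observed margins that are at most as likely as the observed one
enum_fisher_p <- function(ir_a, sj_a, ir_b, sj_b) {
  rs1 <- ir_a + sj_a
  cs1 <- ir_a + ir_b
  n <- ir_a + sj_a + ir_b + sj_b
  ks <- max(0, cs1 - (n - rs1)):min(rs1, cs1)
  probs <- stats::dhyper(ks, rs1, n - rs1, cs1)
  p_obs <- stats::dhyper(ir_a, rs1, n - rs1, cs1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided Spearman p over all n! permutations (n small)
enum_spearman_p <- function(x, y) {
  n <- length(x)
  perm_rows <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perm_rows(v[-i]))))
  }
  perms <- perm_rows(seq_len(n))
  r_obs <- stats::cor(x, y, method = "spearman")
  rs <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "spearman"))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# recovery-curve AUC by explicit step-curve integration
brute_auc <- function(expression, gene_set, top_fraction) {
  n <- length(expression)
  k <- as.integer(ceiling(top_fraction * n))
  ord <- order(-expression, names(expression))
  ranked <- names(expression)[ord]
  y <- numeric(k)
  hits <- 0
  for (x in seq_len(k)) {
    if (ranked[x] %in% gene_set) hits <- hits + 1
    y[x] <- hits
  }
  m <- min(sum(gene_set %in% names(expression)), k)
  best <- pmin(seq_len(k), m)
  sum(y) / sum(best)
}

# deterministic scramble of 1..n (no RNG involvement)
with_fixed_order <- function(n) order(sin(seq_len(n) * 12.9898))

# hand-made single-gene transcript set from explicit exon/intron sequences
toy_tx <- function(exon_seqs, intron_seqs, strand = "+", gene_id = "TOY1") {
  stopifnot(length(exon_seqs) == length(intron_seqs) + 1L)
  pieces <- character(0)
  for (i in seq_along(intron_seqs))
    pieces <- c(pieces, exon_seqs[i], intron_seqs[i])
  sense <- paste(c(pieces, exon_seqs[length(exon_seqs)]), collapse = "")
  lens_e <- nchar(exon_seqs)
  lens_i <- nchar(intron_seqs)
  starts <- cumsum(c(1L, head(lens_e, -1) + lens_i))
  ends <- starts + lens_e - 1L
  total <- nchar(sense)
  if (strand == "+") {
    chrom_seq <- sense
    exons <- cbind(start = starts, end = ends)
  } else {
    chrom_seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sense)))
    exons <- cbind(start = total - ends + 1L, end = total - starts + 1L)
    exons <- exons[order(exons[, 1]), , drop = FALSE]
  }
  out <- list(
    transcripts = list(list(gene_id = gene_id,
                            transcript_id = paste0(gene_id, ".t1"),
                            chrom = "toy_chr", strand = strand,
                            exons = exons)),
    genome = Biostrings::DNAStringSet(c(toy_chr = chrom_seq)),
    ground_truth = NULL)
  class(out) <- "transcript_set"
  out
}
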